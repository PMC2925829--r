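#' @title Conservation-law detection
#' @description Exact left-null-space computation on the stoichiometric
#'   matrix.  All elimination is done in integer/rational arithmetic so that
#'   returned law coefficients satisfy \eqn{c^T S = 0} exactly, not merely to
#'   floating tolerance.
#' @name conservation
NULL

## ---- exact integer/rational helpers ---------------------------------------

gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}
gcd_vec <- function(v) {
  g <- 0
  for (x in v) g <- gcd2(g, x)
  g
}

# Integer-preserving forward elimination (rows combined as
# a_pp*row_i - a_ip*row_p, then divided by the row gcd), returning the
# echelon matrix and pivot columns.  Entries stay exact in double storage;
# networks here are small integers so magnitudes remain far below 2^53.
int_echelon <- function(M, col_order = seq_len(ncol(M))) {
  M <- matrix(as.numeric(M), nrow = nrow(M))
  piv_rows <- integer(); piv_cols <- integer()
  r <- 1L
  for (cc in col_order) {
    if (r > nrow(M)) break
    nz <- which(M[r:nrow(M), cc] != 0)
    if (length(nz) == 0L) next
    i <- r + nz[[1L]] - 1L
    if (i != r) M[c(r, i), ] <- M[c(i, r), ]
    for (k in seq_len(nrow(M))[-r]) {
      if (M[k, cc] == 0) next
      M[k, ] <- M[r, cc] * M[k, ] - M[k, cc] * M[r, ]
      g <- gcd_vec(M[k, ])
      if (g > 1) M[k, ] <- M[k, ] / g
    }
    g <- gcd_vec(M[r, ])
    if (g > 1) M[r, ] <- M[r, ] / g
    piv_rows <- c(piv_rows, r); piv_cols <- c(piv_cols, cc)
    r <- r + 1L
  }
  list(M = M, pivot_rows = piv_rows, pivot_cols = piv_cols)
}

# Exact integer basis of the null space of M (solutions x with M x = 0),
# one column per basis vector, canonicalized to smallest integers with the
# first nonzero entry positive.
int_nullspace <- function(M) {
  n <- ncol(M)
  if (nrow(M) == 0L)
    return(diag(1, n))
  ech <- int_echelon(M)
  R <- ech$M; piv <- ech$pivot_cols
  free <- setdiff(seq_len(n), piv)
  if (length(free) == 0L) return(matrix(0, nrow = n, ncol = 0))
  basis <- matrix(0, nrow = n, ncol = length(free))
  for (b in seq_along(free)) {
    x <- numeric(n)
    x[free[[b]]] <- 1
    # back-substitute pivot rows bottom-up; keep x integral by scaling
    for (k in rev(seq_along(piv))) {
      row <- ech$pivot_rows[[k]]; pc <- piv[[k]]
      s <- sum(R[row, -pc] * x[-pc])
      if (s == 0) { x[pc] <- 0; next }
      p <- R[row, pc]
      g <- gcd2(s, p)
      scale <- abs(p) / g
      x <- x * scale
      x[pc] <- -(s * scale) / p        # exact: p | s*scale by construction
    }
    g <- gcd_vec(x)
    if (g > 1) x <- x / g
    fnz <- which(x != 0)[[1L]]
    if (x[fnz] < 0) x <- -x
    basis[, b] <- x
  }
  # lexicographic order over coefficient vectors for determinism
  ord <- do.call(order, as.data.frame(t(basis)))
  basis[, ord, drop = FALSE]
}

# Exact rank of an integer matrix.
int_rank <- function(M) {
  if (nrow(M) == 0L || ncol(M) == 0L) return(0L)
  length(int_echelon(M)$pivot_cols)
}

## ---- conservation laws -----------------------------------------------------

#' Find conservation laws of a stoichiometric matrix
#'
#' Returns a basis of the left null space of `S` (vectors `c` with
#' `t(c) %*% S == 0` exactly), each canonicalized to the smallest integer
#' vector with positive first nonzero entry, sorted lexicographically.
#' Each law carries a generated total symbol `Total_k`.
#'
#' @param S stoichiometric matrix with species row names (see
#'   [stoichiometric_matrix()])
#' @return list of `conservation_law` objects: `coefficients` (named
#'   integer vector over all species), `total_symbol`, `total_value`
#'   (`NA` until initial values are known)
#' @export
conservation_laws <- function(S) {
  basis <- int_nullspace(t(S))
  species <- rownames(S)
  lapply(seq_len(ncol(basis)), function(k) {
    structure(list(coefficients = stats::setNames(basis[, k], species),
                   total_symbol = paste0("Total_", k),
                   total_value = NA_real_),
              class = "conservation_law")
  })
}

#' @export
format.conservation_law <- function(x, ...) {
  co <- x$coefficients[x$coefficients != 0]
  terms <- ifelse(co == 1, names(co), paste0(format(co), "*", names(co)))
  paste0(x$total_symbol, " = ", paste(terms, collapse = " + "),
         if (!is.na(x$total_value)) paste0(" = ", format(x$total_value)) else "")
}

#' @export
print.conservation_law <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

# Re-eliminate the law matrix right-to-left so that each law has a distinct
# pivot equal to its *last* nonzero species column.  The pivot species are
# the dependent variables of the reduced system; the choice is deterministic.
reduction_pivots <- function(laws, species) {
  if (length(laws) == 0L)
    return(list(laws = list(), dependent = character()))
  L <- do.call(rbind, lapply(laws, function(l) l$coefficients[species]))
  ech <- int_echelon(L, col_order = rev(seq_len(ncol(L))))
  keep <- ech$pivot_rows
  Lred <- ech$M[keep, , drop = FALSE]
  dependent <- species[ech$pivot_cols]
  red_laws <- lapply(seq_len(nrow(Lred)), function(k) {
    v <- Lred[k, ]
    g <- gcd_vec(v); if (g > 1) v <- v / g
    if (v[ech$pivot_cols[[k]]] < 0) v <- -v
    stats::setNames(v, species)
  })
  list(laws = red_laws, dependent = dependent)
}
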