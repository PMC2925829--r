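#' @title Steady-state continuation and bifurcation analysis
#' @description One-parameter continuation of steady states by
#'   pseudo-arclength (tangent predictor, modified Newton corrector with
#'   adaptive step sizes and a tangent-angle guard against branch jumping),
#'   linear stability classification, detection and bisection refinement of
#'   fold, Hopf and focus-node points, and metabolic control analysis at a
#'   steady state.
#' @name continuation
NULL

# Extended residual and Jacobian of F(y, p) = reduced RHS with `parameter`
# rebound per call.
make_extended_system <- function(model, parameter) {
  if (!parameter %in% names(model$parameters))
    stop("unknown parameter: ", parameter)
  env <- model_env(model)
  S_ind <- model$S[model$independent, , drop = FALSE]
  n <- length(model$independent)
  F <- function(u) {                    # u = c(y, p)
    assign(parameter, u[[n + 1L]], env)
    st <- eval_model_state(model, u[seq_len(n)], t = 0, env = env)
    as.numeric(S_ind %*% st$fluxes)
  }
  # n x (n+1) Jacobian [dF/dy, dF/dp], forward differences
  DF <- function(u, f0 = NULL) {
    if (is.null(f0)) f0 <- F(u)
    J <- matrix(0, n, n + 1L)
    for (j in seq_len(n + 1L)) {
      h <- max(1e-7 * abs(u[[j]]), 1e-10)
      up <- u; up[[j]] <- up[[j]] + h
      J[, j] <- (F(up) - f0) / h
    }
    J
  }
  state_at <- function(u) {
    assign(parameter, u[[n + 1L]], env)
    eval_model_state(model, u[seq_len(n)], t = 0, env = env)
  }
  list(F = F, DF = DF, state_at = state_at, n = n)
}

# Unit tangent of the extended system at u, oriented along `prev`.
branch_tangent <- function(sys, u, prev) {
  J <- sys$DF(u)
  A <- rbind(J, prev)
  t_ <- tryCatch(solve(A, c(rep(0, sys$n), 1)), error = function(e) NULL)
  if (is.null(t_)) return(NULL)
  t_ <- t_ / sqrt(sum(t_^2))
  if (sum(t_ * prev) < 0) t_ <- -t_
  t_
}

# Newton corrector constrained to the hyperplane d . (u - u_ref) = 0.
correct_on_plane <- function(sys, u, d, u_ref, tol, max_iter = 8L) {
  for (it in seq_len(max_iter)) {
    f <- sys$F(u)
    if (any(!is.finite(f))) return(NULL)
    if (max(abs(f)) <= tol) return(list(u = u, iterations = it - 1L))
    J <- sys$DF(u, f)
    A <- rbind(J, d)
    g <- c(f, sum(d * (u - u_ref)))
    du <- tryCatch(solve(A, -g), error = function(e) NULL)
    if (is.null(du)) return(NULL)
    u <- u + du
  }
  f <- sys$F(u)
  if (all(is.finite(f)) && max(abs(f)) <= tol)
    return(list(u = u, iterations = max_iter))
  NULL
}

# Fixed-parameter Newton solve used to land exactly on interval boundaries.
correct_at_parameter <- function(sys, y, p, tol, max_iter = 30L) {
  d <- c(rep(0, sys$n), 1)
  correct_on_plane(sys, c(y, p), d, c(y, p), tol, max_iter)
}

#' Classify linear stability from eigenvalues
#'
#' @param eigenvalues complex (or numeric) vector of reduced-Jacobian
#'   eigenvalues
#' @return one of `"stable node"`, `"stable focus"`, `"unstable node"`,
#'   `"unstable focus"`, `"saddle"`
#' @export
classify_stability <- function(eigenvalues) {
  stopifnot(length(eigenvalues) > 0)
  re <- Re(eigenvalues); im <- Im(eigenvalues)
  if (any(re > 0) && any(re < 0)) return("saddle")
  focus <- any(abs(im) > 1e-9 * (1 + abs(re)))
  paste(if (all(re < 0)) "stable" else "unstable",
        if (focus) "focus" else "node")
}

#' Continue a branch of steady states over one parameter
#'
#' Pseudo-arclength predictor-corrector stepping starting from a converged
#' steady state at `parameter = lo`.  The step is halved when the corrector
#' fails or the angle between successive tangents exceeds 30 degrees
#' (branch-jump guard), and grown by a factor 1.3 after three consecutive
#' easy successes (at most 3 Newton iterations).  Traversal ends when the
#' parameter leaves `[lo, hi]` (a final point is corrected exactly onto the
#' boundary) or `max_points` is reached.
#'
#' @param model a `kinetic_model`
#' @param parameter parameter id to vary
#' @param lo,hi parameter interval; the branch starts at `lo`
#' @param initial_step initial arclength step (default `(hi - lo)/100`)
#' @param corrector_tol corrector residual tolerance (default 1e-9)
#' @param max_points maximum number of branch points (default 2000)
#' @param initial_guess optional named state guess for the starting steady
#'   state
#' @param start parameter value of the starting steady state (default `lo`;
#'   use `hi` to traverse a branch that exists only near the upper end)
#' @param direction initial sign of the parameter tangent (+1 toward `hi`)
#' @return tibble of class `kin_branch`: columns `step`, the parameter,
#'   species concentrations, reaction fluxes, `det_jacobian`, `stability`,
#'   and list-columns `eigenvalues`, `jacobian`, `independent_state`,
#'   `tangent_p`.  Attributes carry the model, parameter id and truncation
#'   flag.
#' @export
continue_branch <- function(model, parameter, lo, hi,
                            initial_step = (hi - lo) / 100,
                            corrector_tol = 1e-9, max_points = 2000L,
                            initial_guess = NULL, start = lo,
                            direction = if (start < (lo + hi) / 2) 1 else -1) {
  stopifnot(lo < hi, initial_step > 0, start >= lo, start <= hi)
  sys <- make_extended_system(model, parameter)
  n <- sys$n
  start_ss <- steady_state(set_parameters(model, stats::setNames(start, parameter)),
                           initial_guess = initial_guess, tol = corrector_tol)
  u <- c(start_ss$independent, start)
  prev_t <- c(rep(0, n), sign(direction))
  tan_u <- branch_tangent(sys, u, prev_t)
  if (is.null(tan_u)) stop("tangent computation failed at the start point")

  pts <- list(); tangents <- list()
  truncated <- FALSE
  record <- function(u, tp) {
    st <- sys$state_at(u)
    J <- sys$DF(u)[, seq_len(n), drop = FALSE]
    dimnames(J) <- list(model$independent, model$independent)
    ev <- if (n == 1L) as.complex(J[1, 1]) else eigen(J, only.values = TRUE)$values
    pts[[length(pts) + 1L]] <<- list(
      p = u[[n + 1L]], y = u[seq_len(n)], species = st$species,
      fluxes = st$fluxes, jacobian = J, eigenvalues = ev,
      det = det(J), stability = classify_stability(ev), tangent_p = tp)
  }
  record(u, tan_u[[n + 1L]])

  h <- initial_step
  min_step <- initial_step * 1e-6
  max_step <- initial_step * 10
  easy <- 0L
  cos_guard <- cos(30 * pi / 180)
  while (length(pts) < max_points) {
    pred <- u + h * tan_u
    res <- correct_on_plane(sys, pred, tan_u, pred, corrector_tol)
    new_t <- if (!is.null(res)) branch_tangent(sys, res$u, tan_u) else NULL
    ok <- !is.null(res) && !is.null(new_t) &&
      sum(new_t * tan_u) >= cos_guard
    if (!ok) {
      h <- h / 2; easy <- 0L
      if (h < min_step) { truncated <- TRUE; break }
      next
    }
    u_new <- res$u
    p_new <- u_new[[n + 1L]]
    if (p_new > hi + 1e-12 || p_new < lo - 1e-12) {
      bound <- if (p_new > hi) hi else lo
      fin <- correct_at_parameter(sys, u_new[seq_len(n)], bound, corrector_tol)
      if (!is.null(fin)) {
        tb <- branch_tangent(sys, fin$u, tan_u)
        record(fin$u, if (is.null(tb)) NA_real_ else tb[[n + 1L]])
      }
      break
    }
    u <- u_new; tan_u <- new_t
    record(u, tan_u[[n + 1L]])
    if (res$iterations <= 3L) {
      easy <- easy + 1L
      if (easy >= 3L) { h <- min(h * 1.3, max_step); easy <- 0L }
    } else easy <- 0L
  }

  conc <- do.call(rbind, lapply(pts, function(q) q$species[model$species]))
  flux <- do.call(rbind, lapply(pts, function(q) q$fluxes))
  res <- tibble::tibble(step = seq_along(pts))
  res[[parameter]] <- vapply(pts, function(q) q$p, 0)
  res <- tibble::as_tibble(cbind(res, conc, flux))
  res$det_jacobian <- vapply(pts, function(q) q$det, 0)
  res$stability <- vapply(pts, function(q) q$stability, "")
  res$tangent_p <- vapply(pts, function(q) q$tangent_p, 0)
  res$eigenvalues <- lapply(pts, function(q) q$eigenvalues)
  res$jacobian <- lapply(pts, function(q) q$jacobian)
  res$independent_state <- lapply(pts, function(q) q$y)
  attr(res, "parameter") <- parameter
  attr(res, "species") <- model$species
  attr(res, "reactions") <- colnames(flux)
  attr(res, "model") <- model
  attr(res, "corrector_tol") <- corrector_tol
  attr(res, "truncated") <- truncated
  attr(res, "independent_label") <- parameter
  class(res) <- c("kin_branch", class(res))
  res
}

## ---- bifurcation detection ----------------------------------------------------

# Test functions from an eigenvalue spectrum.
test_fold <- function(point) point$det
test_hopf <- function(point) {
  ev <- point$eigenvalues
  cplx <- ev[Im(ev) > 1e-9 * (1 + abs(Re(ev)))]   # one per conjugate pair
  if (length(cplx) == 0L) return(NA_real_)
  max(Re(cplx))
}
test_focus_node <- function(point) {
  ev <- point$eigenvalues
  if (length(ev) < 2L) return(NA_real_)
  best <- Inf
  for (i in seq_along(ev)[-length(ev)])
    for (j in seq((i + 1L), length(ev)))
      best <- min(best, (Re(ev[[i]]) - Re(ev[[j]]))^2 -
                        (Im(ev[[i]]) - Im(ev[[j]]))^2)
  best
}

point_info <- function(sys, u, n) {
  J <- sys$DF(u)[, seq_len(n), drop = FALSE]
  ev <- if (n == 1L) as.complex(J[1, 1]) else eigen(J, only.values = TRUE)$values
  list(u = u, p = u[[n + 1L]], det = det(J), eigenvalues = ev, jacobian = J)
}

critical_eigenvector <- function(J, type) {
  es <- eigen(J)
  ev <- es$values
  idx <- switch(type,
    fold = which.min(abs(Re(ev)) + abs(Im(ev))),
    hopf = {
      c_ <- which(abs(Im(ev)) > 1e-9 * (1 + abs(Re(ev))))
      if (length(c_)) c_[[which.min(abs(Re(ev[c_])))]] else which.min(abs(Re(ev)))
    },
    focus_node = which.min(abs(Im(ev))))
  es$vectors[, idx]
}

#' Detect and refine bifurcation points along a branch
#'
#' Test functions are evaluated at every branch point: fold, the determinant
#' of the reduced Jacobian (its sign change is cross-checked against a
#' parameter-direction reversal of the branch); Hopf, the largest real part
#' over complex-conjugate eigenvalue pairs; focus-node, the sign of the
#' paired-eigenvalue discriminant (squared real-part difference minus
#' squared imaginary-part difference).  Each sign change is refined by
#' bisection along the secant between the bracketing branch points, with a
#' pseudo-arclength Newton corrector at every trial, until the test function
#' magnitude is at most `tol`.
#'
#' @param branch a `kin_branch` from [continue_branch()]
#' @param tol refinement tolerance on the test function (default 1e-8)
#' @return tibble of class `kin_bifurcations`: columns `type`, parameter
#'   value, `test_value`, `refined`, plus list-columns `state` (all species)
#'   and `eigenvector` (critical eigenvector)
#' @export
detect_bifurcations <- function(branch, tol = 1e-8) {
  model <- attr(branch, "model")
  parameter <- attr(branch, "parameter")
  ctol <- attr(branch, "corrector_tol") %||% 1e-9
  sys <- make_extended_system(model, parameter)
  n <- sys$n
  pts <- lapply(seq_len(nrow(branch)), function(i) list(
    u = c(branch$independent_state[[i]], branch[[parameter]][[i]]),
    p = branch[[parameter]][[i]],
    det = branch$det_jacobian[[i]],
    eigenvalues = branch$eigenvalues[[i]],
    tangent_p = branch$tangent_p[[i]]))

  found <- list()
  tests <- list(fold = test_fold, hopf = test_hopf,
                focus_node = test_focus_node)
  for (type in names(tests)) {
    tf <- tests[[type]]
    vals <- vapply(pts, tf, 0)
    for (k in seq_len(length(pts) - 1L)) {
      a <- vals[[k]]; b <- vals[[k + 1L]]
      if (is.na(a) || is.na(b) || a == 0 || sign(a) == sign(b)) next
      if (type == "hopf") {
        # require a genuinely complex pair at the crossing
        imax <- max(abs(Im(pts[[k]]$eigenvalues)),
                    abs(Im(pts[[k + 1L]]$eigenvalues)))
        if (imax <= 1e-6) next
      }
      if (type == "fold") {
        # fold geometry: the branch parameter direction reverses
        tp <- vapply(pts[max(1L, k - 1L):min(length(pts), k + 2L)],
                     function(q) q$tangent_p, 0)
        tp <- tp[is.finite(tp)]
        if (length(tp) && (all(tp > 1e-8) || all(tp < -1e-8))) next
      }
      ref <- refine_bifurcation(sys, n, pts[[k]]$u, pts[[k + 1L]]$u,
                                tf, a, tol, ctol)
      info <- point_info(sys, ref$u, n)
      st <- sys$state_at(ref$u)
      found[[length(found) + 1L]] <- tibble::tibble(
        type = type, parameter = info$p, test_value = ref$value,
        refined = ref$refined,
        state = list(st$species),
        eigenvector = list(critical_eigenvector(info$jacobian, type)))
    }
  }
  res <- if (length(found)) do.call(rbind, found) else
    tibble::tibble(type = character(), parameter = numeric(),
                   test_value = numeric(), refined = logical(),
                   state = list(), eigenvector = list())
  names(res)[names(res) == "parameter"] <- attr(branch, "parameter")
  attr(res, "parameter") <- attr(branch, "parameter")
  class(res) <- c("kin_bifurcations", class(res))
  res
}

# Bisection on the secant chord between extended points u1, u2.
refine_bifurcation <- function(sys, n, u1, u2, tf, f1, tol, ctol,
                               max_iter = 80L) {
  d <- (u2 - u1); d <- d / sqrt(sum(d^2))
  eval_at <- function(s) {
    pred <- u1 + s * (u2 - u1)
    res <- correct_on_plane(sys, pred, d, pred, ctol, max_iter = 12L)
    if (is.null(res)) return(NULL)
    info <- point_info(sys, res$u, n)
    list(u = res$u, value = tf(info))
  }
  lo <- 0; hi <- 1; flo <- f1
  best <- NULL
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    r <- eval_at(mid)
    if (is.null(r) || is.na(r$value)) break
    best <- r
    if (abs(r$value) <= tol)
      return(list(u = r$u, value = r$value, refined = TRUE))
    if (sign(r$value) == sign(flo)) { lo <- mid; flo <- r$value }
    else hi <- mid
  }
  if (!is.null(best) && abs(best$value) <= tol * 10)
    return(list(u = best$u, value = best$value, refined = TRUE))
  mid <- eval_at(0.5)
  if (is.null(mid)) mid <- list(u = (u1 + u2) / 2, value = NA_real_)
  list(u = mid$u, value = mid$value, refined = FALSE)
}

## ---- metabolic control analysis -------------------------------------------------

#' Metabolic control analysis at a steady state
#'
#' Flux control coefficients \eqn{C^J_i = (v_i/J) \partial J/\partial v_i}
#' and concentration control coefficients \eqn{C^S_i} are computed by
#' central finite differences: the rate law of each reaction in turn is
#' multiplied by \eqn{1 \pm \delta}, the steady state is re-solved
#' (warm-started from the reference state), and the log-responses are
#' differenced.  The summation theorems (flux coefficients sum to 1,
#' concentration coefficients to 0) hold up to the finite-difference and
#' Newton tolerances.
#'
#' @param model a `kinetic_model`
#' @param steady_state_point a `kin_steady_state` (default: solved from the
#'   model's initial values)
#' @param delta relative rate perturbation (default 1e-4)
#' @param tol steady-state tolerance for the perturbed solves
#' @return list with tibbles `flux` (reaction x flux coefficients) and
#'   `concentration` (reaction x species coefficients); entries are `NA`
#'   when the perturbed steady state is lost
#' @export
control_coefficients <- function(model, steady_state_point = NULL,
                                 delta = 1e-4, tol = 1e-11) {
  if (is.null(steady_state_point)) steady_state_point <- steady_state(model, tol = tol)
  base <- steady_state_point
  rids <- vapply(model$reactions, function(r) r$id, "")
  J0 <- base$fluxes; S0 <- base$state
  fcc <- matrix(NA_real_, length(rids), length(rids),
                dimnames = list(rids, rids))
  scc <- matrix(NA_real_, length(rids), length(S0),
                dimnames = list(rids, names(S0)))
  for (i in rids) {
    solve_scaled <- function(fac) tryCatch(
      steady_state(scale_rate(model, i, fac),
                   initial_guess = base$independent, tol = tol),
      error = function(e) NULL)
    up <- solve_scaled(1 + delta)
    dn <- solve_scaled(1 - delta)
    if (is.null(up) || is.null(dn)) next
    fcc[i, ] <- (up$fluxes - dn$fluxes) / (2 * delta * J0)
    scc[i, ] <- (up$state - dn$state) / (2 * delta * S0)
  }
  list(
    flux = tibble::as_tibble(cbind(data.frame(reaction = rids), fcc)),
    concentration = tibble::as_tibble(cbind(data.frame(reaction = rids), scc)))
}
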