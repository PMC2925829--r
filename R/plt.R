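#' @title PLT simulation-results format
#' @description The plain-text table consumed by the animation player.
#'   Row 1 gives the number of metabolites N1, row 2 the number of reactions
#'   N2, row 3 the column titles (the independent column is labelled
#'   `X[0]`), and each following row holds the independent value (time step
#'   or parameter step), N1 concentrations and N2 fluxes.  Tab-delimited on
#'   write; tab, comma or whitespace accepted on read.  Numeric values are
#'   written with 17 significant digits so a write/read round trip is
#'   lossless.
#' @name plt
NULL

PLT_INDEPENDENT_LABEL <- "X[0]"

#' Construct a PLT table
#'
#' @param independent numeric vector (monotone time or parameter steps)
#' @param concentrations matrix/data frame, one named column per metabolite
#' @param fluxes matrix/data frame, one named column per reaction
#' @return object of class `kin_plt`: tibble with the independent column
#'   `X[0]` first and attributes `n1`, `n2`, `titles`
#' @export
plt_data <- function(independent, concentrations, fluxes) {
  concentrations <- as.matrix(concentrations)
  fluxes <- as.matrix(fluxes)
  stopifnot(nrow(concentrations) == length(independent),
            nrow(fluxes) == length(independent))
  if (any(diff(independent) < 0) && any(diff(independent) > 0))
    stop("independent column must be monotone")
  d <- tibble::as_tibble(cbind(
    stats::setNames(data.frame(independent), PLT_INDEPENDENT_LABEL),
    concentrations, fluxes), .name_repair = "minimal")
  attr(d, "n1") <- ncol(concentrations)
  attr(d, "n2") <- ncol(fluxes)
  attr(d, "titles") <- c(PLT_INDEPENDENT_LABEL, colnames(concentrations),
                         colnames(fluxes))
  class(d) <- c("kin_plt", class(d))
  d
}

#' Convert a time course or continuation branch to a PLT table
#'
#' The independent column is time for an ODE-solver result and the varied
#' parameter for a continuation branch; column order follows the model
#' declaration order.
#'
#' @param x a `kin_timecourse` or `kin_branch`
#' @return a `kin_plt`
#' @export
as_plt <- function(x) {
  sp <- attr(x, "species"); rx <- attr(x, "reactions")
  ind_col <- if (inherits(x, "kin_timecourse")) "time"
             else attr(x, "parameter")
  plt_data(x[[ind_col]],
           as.matrix(as.data.frame(x)[, sp, drop = FALSE]),
           as.matrix(as.data.frame(x)[, rx, drop = FALSE]))
}

#' Write a PLT file
#' @param x a `kin_plt`, `kin_timecourse` or `kin_branch`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_plt <- function(x, path) {
  if (!inherits(x, "kin_plt")) x <- as_plt(x)
  titles <- attr(x, "titles")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(as.character(attr(x, "n1")), as.character(attr(x, "n2")),
               paste(titles, collapse = "\t")), con)
  m <- as.matrix(as.data.frame(x))
  apply_fmt <- function(row) paste(sprintf("%.17g", row), collapse = "\t")
  writeLines(vapply(seq_len(nrow(m)), function(i) apply_fmt(m[i, ]), ""), con)
  invisible(path)
}

#' Read a PLT file
#' @param path file path
#' @return a `kin_plt`
#' @export
read_plt <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("PLT format error: fewer than 3 header rows")
  n1 <- suppressWarnings(as.integer(trimws(lines[[1L]])))
  n2 <- suppressWarnings(as.integer(trimws(lines[[2L]])))
  if (is.na(n1) || is.na(n2))
    stop("PLT format error: rows 1-2 must be the metabolite and reaction counts")
  split_fields <- function(s) {
    s <- trimws(s)
    if (grepl("\t", s)) strsplit(s, "\t", fixed = TRUE)[[1L]]
    else if (grepl(",", s)) strsplit(s, ",", fixed = TRUE)[[1L]]
    else strsplit(s, "[[:space:]]+")[[1L]]
  }
  titles <- split_fields(lines[[3L]])
  if (length(titles) != 1L + n1 + n2)
    stop(sprintf("PLT format error at row 3: %d titles, expected %d",
                 length(titles), 1L + n1 + n2))
  body <- lines[-(1:3)]
  body <- body[nzchar(trimws(body))]
  rows <- lapply(seq_along(body), function(i) {
    f <- suppressWarnings(as.numeric(split_fields(body[[i]])))
    if (length(f) != length(titles) || anyNA(f))
      stop(sprintf("PLT format error at row %d: expected %d numeric fields",
                   i + 3L, length(titles)))
    f
  })
  m <- do.call(rbind, rows)
  colnames(m) <- titles
  plt_data(m[, 1L], m[, 1L + seq_len(n1), drop = FALSE],
           m[, 1L + n1 + seq_len(n2), drop = FALSE])
}

#' Metabolite and reaction titles of a PLT table
#' @param x a `kin_plt`
#' @return list with `independent`, `metabolites`, `reactions`
#' @export
plt_titles <- function(x) {
  titles <- attr(x, "titles")
  n1 <- attr(x, "n1")
  list(independent = titles[[1L]],
       metabolites = titles[1L + seq_len(n1)],
       reactions = titles[1L + n1 + seq_len(attr(x, "n2"))])
}
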