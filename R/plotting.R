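#' @title ggplot2 methods for result objects
#' @name plotting
NULL

tc_long <- function(x, cols) {
  df <- tibble::as_tibble(as.data.frame(x))
  tidyr::pivot_longer(df[, c(names(df)[[1L]], cols)], -1,
                      names_to = "series", values_to = "value")
}

#' Plot a time course
#' @param object a `kin_timecourse`
#' @param what `"concentrations"`, `"fluxes"` or `"both"`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.kin_timecourse <- function(object,
                                    what = c("concentrations", "fluxes",
                                             "both"), ...) {
  what <- match.arg(what)
  cols <- switch(what,
                 concentrations = attr(object, "species"),
                 fluxes = attr(object, "reactions"),
                 both = c(attr(object, "species"), attr(object, "reactions")))
  d <- tc_long(object, cols)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$value,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = what, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a continuation branch
#'
#' One curve per selected variable against the continuation parameter,
#' with the line type encoding local stability; bifurcation points are
#' marked as filled black rectangles.
#'
#' @param object a `kin_branch`
#' @param variables species/flux columns to draw (default: all species)
#' @param bifurcations optional `kin_bifurcations` to mark
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.kin_branch <- function(object, variables = NULL,
                                bifurcations = NULL, ...) {
  par_id <- attr(object, "parameter")
  if (is.null(variables)) variables <- attr(object, "species")
  df <- tibble::as_tibble(as.data.frame(object[, c(par_id, variables,
                                                   "stability")]))
  d <- tidyr::pivot_longer(df, tidyr::all_of(variables),
                           names_to = "series", values_to = "value")
  d$stable <- ifelse(grepl("^stable", d$stability), "stable", "unstable")
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data[[par_id]], y = .data$value,
                                       colour = .data$series,
                                       linetype = .data$stable,
                                       group = .data$series)) +
    ggplot2::geom_path() +
    ggplot2::labs(x = par_id, y = "steady state", colour = NULL,
                  linetype = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(bifurcations) && nrow(bifurcations)) {
    bd <- do.call(rbind, lapply(seq_len(nrow(bifurcations)), function(i) {
      st <- bifurcations$state[[i]]
      tibble::tibble(x = bifurcations[[par_id]][[i]],
                     value = st[variables], series = variables)
    }))
    p <- p + ggplot2::geom_point(
      data = bd, ggplot2::aes(x = .data$x, y = .data$value),
      inherit.aes = FALSE, shape = 15, size = 3, colour = "black")
  }
  p
}

#' Plot an explicit-function scan
#' @param object a `kin_scan`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.kin_scan <- function(object, ...) {
  d <- tc_long(object, names(object)[-1L])
  xname <- names(object)[[1L]]
  names(d)[[1L]] <- xname
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[xname]], y = .data$value,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a visual map
#' @param object a `visual_map`
#' @param ... unused
#' @return a ggplot (y axis points down, matching canvas coordinates)
#' @export
autoplot.visual_map <- function(object, ...) {
  p <- ggplot2::ggplot() + ggplot2::theme_void() +
    ggplot2::coord_fixed(xlim = c(0, object$canvas[[1L]]),
                         ylim = c(object$canvas[[2L]], 0))
  if (length(object$arrows)) {
    seg <- do.call(rbind, lapply(object$arrows, function(a) {
      g <- arrow_geometry(object, a)
      tibble::tibble(x = g$x1, y = g$y1, xend = g$x2, yend = g$y2)
    }))
    p <- p + ggplot2::geom_segment(
      data = seg, ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                               yend = .data$yend),
      arrow = ggplot2::arrow(length = ggplot2::unit(8, "pt")),
      colour = "#1f4ab0")
  }
  if (nrow(object$nodes))
    p <- p +
      ggplot2::geom_point(data = object$nodes,
                          ggplot2::aes(x = .data$x, y = .data$y),
                          shape = 21, size = 6, colour = "#218c21") +
      ggplot2::geom_text(data = object$nodes,
                         ggplot2::aes(x = .data$x, y = .data$y - 18,
                                      label = .data$label), size = 3)
  if (nrow(object$bars))
    p <- p + ggplot2::geom_rect(
      data = object$bars,
      ggplot2::aes(xmin = .data$x, xmax = .data$x + .data$width,
                   ymin = .data$y - .data$max_height, ymax = .data$y,
                   fill = .data$kind), alpha = 0.4)
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
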