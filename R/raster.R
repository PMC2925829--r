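#' @title Deterministic software rasterizer
#' @description Minimal drawing primitives (discs, thick lines, triangles,
#'   rectangles, a 3x5 digit font) on an RGB pixel array.  All rendering in
#'   the package goes through these routines so that exported images and
#'   video frames are bit-reproducible across platforms.  Canvas
#'   coordinates: abstract units equal to pixels, origin top-left, x right,
#'   y down.
#' @name raster
#' @keywords internal
NULL

new_canvas <- function(width, height, bg = c(1, 1, 1)) {
  img <- array(0, dim = c(height, width, 3))
  for (k in 1:3) img[, , k] <- bg[[k]]
  img
}

clamp_int <- function(v, lo, hi) pmin(pmax(as.integer(round(v)), lo), hi)

fill_mask <- function(img, rows, cols, mask, col) {
  for (k in 1:3) {
    plane <- img[rows, cols, k, drop = FALSE]
    plane[mask] <- col[[k]]
    img[rows, cols, k] <- plane
  }
  img
}

draw_disc <- function(img, cx, cy, r, col) {
  if (r <= 0) return(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  rows <- max(1L, floor(cy - r)):min(h, ceiling(cy + r))
  cols <- max(1L, floor(cx - r)):min(w, ceiling(cx + r))
  if (length(rows) == 0L || length(cols) == 0L) return(img)
  dy <- outer(rows - cy, rep(1, length(cols)))
  dx <- outer(rep(1, length(rows)), cols - cx)
  fill_mask(img, rows, cols, dy^2 + dx^2 <= r^2, col)
}

draw_circle_outline <- function(img, cx, cy, r, col, lw = 1) {
  if (r <= 0) return(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  rows <- max(1L, floor(cy - r - lw)):min(h, ceiling(cy + r + lw))
  cols <- max(1L, floor(cx - r - lw)):min(w, ceiling(cx + r + lw))
  if (length(rows) == 0L || length(cols) == 0L) return(img)
  dy <- outer(rows - cy, rep(1, length(cols)))
  dx <- outer(rep(1, length(rows)), cols - cx)
  d2 <- dy^2 + dx^2
  fill_mask(img, rows, cols, d2 <= (r + lw / 2)^2 & d2 >= (r - lw / 2)^2, col)
}

draw_rect <- function(img, x1, y1, x2, y2, col, fill = TRUE, lw = 1) {
  h <- dim(img)[1]; w <- dim(img)[2]
  xs <- sort(c(x1, x2)); ys <- sort(c(y1, y2))
  if (fill) {
    rows <- clamp_int(ys[1], 1L, h):clamp_int(ys[2], 1L, h)
    cols <- clamp_int(xs[1], 1L, w):clamp_int(xs[2], 1L, w)
    for (k in 1:3) img[rows, cols, k] <- col[[k]]
    return(img)
  }
  img <- draw_rect(img, xs[1], ys[1], xs[2], ys[1] + lw - 1, col)
  img <- draw_rect(img, xs[1], ys[2] - lw + 1, xs[2], ys[2], col)
  img <- draw_rect(img, xs[1], ys[1], xs[1] + lw - 1, ys[2], col)
  draw_rect(img, xs[2] - lw + 1, ys[1], xs[2], ys[2], col)
}

# Thick line as a swept disc along the segment.
draw_segment <- function(img, x1, y1, x2, y2, thickness, col) {
  len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  if (len == 0) return(draw_disc(img, x1, y1, max(thickness / 2, 0.5), col))
  steps <- max(2L, ceiling(len))
  r <- max(thickness / 2, 0.5)
  for (s in seq(0, 1, length.out = steps))
    img <- draw_disc(img, x1 + s * (x2 - x1), y1 + s * (y2 - y1), r, col)
  img
}

draw_polyline <- function(img, xs, ys, thickness, col) {
  for (i in seq_len(length(xs) - 1L))
    img <- draw_segment(img, xs[i], ys[i], xs[i + 1], ys[i + 1],
                        thickness, col)
  img
}

# Filled triangle by sign tests against the three edges.
draw_triangle <- function(img, xs, ys, col) {
  h <- dim(img)[1]; w <- dim(img)[2]
  rows <- clamp_int(min(ys), 1L, h):clamp_int(max(ys), 1L, h)
  cols <- clamp_int(min(xs), 1L, w):clamp_int(max(xs), 1L, w)
  if (length(rows) == 0L || length(cols) == 0L) return(img)
  px <- outer(rep(1, length(rows)), cols)
  py <- outer(rows, rep(1, length(cols)))
  edge <- function(ax, ay, bx, by) (px - ax) * (by - ay) - (py - ay) * (bx - ax)
  e1 <- edge(xs[1], ys[1], xs[2], ys[2])
  e2 <- edge(xs[2], ys[2], xs[3], ys[3])
  e3 <- edge(xs[3], ys[3], xs[1], ys[1])
  mask <- (e1 >= 0 & e2 >= 0 & e3 >= 0) | (e1 <= 0 & e2 <= 0 & e3 <= 0)
  fill_mask(img, rows, cols, mask, col)
}

# Arrowhead at (x2, y2) pointing along the segment direction.
draw_arrowhead <- function(img, x1, y1, x2, y2, size, col) {
  dx <- x2 - x1; dy <- y2 - y1
  len <- sqrt(dx^2 + dy^2)
  if (len == 0) return(img)
  ux <- dx / len; uy <- dy / len
  bx <- x2 - size * ux; by <- y2 - size * uy
  px <- -uy; py <- ux
  draw_triangle(img,
                c(x2, bx + size * 0.5 * px, bx - size * 0.5 * px),
                c(y2, by + size * 0.5 * py, by - size * 0.5 * py), col)
}

# 3x5 bitmap font for numeric legends.
RASTER_FONT <- list(
  "0" = c("111","101","101","101","111"),
  "1" = c("010","110","010","010","111"),
  "2" = c("111","001","111","100","111"),
  "3" = c("111","001","111","001","111"),
  "4" = c("101","101","111","001","001"),
  "5" = c("111","100","111","001","111"),
  "6" = c("111","100","111","101","111"),
  "7" = c("111","001","010","010","010"),
  "8" = c("111","101","111","101","111"),
  "9" = c("111","101","111","001","111"),
  "." = c("000","000","000","000","010"),
  "-" = c("000","000","111","000","000"),
  "+" = c("000","010","111","010","000"),
  "e" = c("000","111","110","100","111"),
  ":" = c("000","010","000","010","000"),
  " " = c("000","000","000","000","000"))

draw_text <- function(img, x, y, text, col, scale = 2) {
  cx <- x
  for (ch in strsplit(text, "")[[1]]) {
    glyph <- RASTER_FONT[[ch]]
    if (is.null(glyph)) glyph <- RASTER_FONT[["."]]
    for (r in 1:5) {
      bits <- strsplit(glyph[[r]], "")[[1]]
      for (c_ in 1:3) if (bits[[c_]] == "1")
        img <- draw_rect(img, cx + (c_ - 1) * scale, y + (r - 1) * scale,
                         cx + c_ * scale - 1, y + r * scale - 1, col)
    }
    cx <- cx + 4 * scale
  }
  img
}

# named default palette used across map rendering
KIN_COLORS <- list(
  node = c(0.13, 0.55, 0.13),      # green: metabolite concentrations
  arrow = c(0.12, 0.29, 0.69),     # blue: reaction rates
  bar_concentration = c(0.13, 0.55, 0.13),
  bar_rate = c(0.12, 0.29, 0.69),
  outline = c(0.25, 0.25, 0.25),
  text = c(0.1, 0.1, 0.1),
  progress = c(0.85, 0.33, 0.1),
  bifurcation = c(0, 0, 0))
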