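#' @title Dynamic visualization (animation player)
#' @description Bind simulation results (a PLT table) to a visual map and
#'   render one frame per table row: node circle radii follow metabolite
#'   concentrations and arrow thicknesses (or rate circles, or bar heights)
#'   follow reaction rates through a clamped linear scaling.  Frames carry
#'   their scaled geometry as metadata and can be exported as an AVI video
#'   (uncompressed 24-bit frames).  Every frame overlays a progress bar for
#'   the current time / parameter value and a numeric legend of the scale
#'   bounds.
#' @name animation
NULL

#' Clamped linear scaling of a concentration to a circle radius
#'
#' \deqn{r_i = 0 \textrm{ if } C_i < C_{min};\;
#'   (C_i - C_{min})/(C_{max} - C_{min}) \cdot r_{max}
#'   \textrm{ if } C_{min} \le C_i \le C_{max};\;
#'   r_{max} \textrm{ if } C_i > C_{max}}
#'
#' @param c_i concentration value(s)
#' @param c_min,c_max user-chosen scale bounds, `c_min < c_max`
#' @param r_max maximal circle radius (canvas units), positive
#' @return radius value(s) in `[0, r_max]`
#' @export
scale_radius <- function(c_i, c_min, c_max, r_max) {
  if (!is.finite(c_min) || !is.finite(c_max) || c_min >= c_max)
    stop("invalid scale bounds: require c_min < c_max")
  if (!is.finite(r_max) || r_max <= 0)
    stop("invalid scale bounds: require r_max > 0")
  pmin(pmax((c_i - c_min) / (c_max - c_min), 0), 1) * r_max
}

#' Clamped linear scaling of a reaction rate to an arrow thickness
#'
#' Same piecewise-linear form as [scale_radius()] with `(V, h)` in place of
#' `(C, r)`; also used for the rate-circle radius and for bar heights.
#'
#' @param v_i rate value(s)
#' @param v_min,v_max scale bounds, `v_min < v_max`
#' @param h_max maximal thickness (canvas units), positive
#' @return thickness value(s) in `[0, h_max]`
#' @export
scale_thickness <- function(v_i, v_min, v_max, h_max) {
  if (!is.finite(v_min) || !is.finite(v_max) || v_min >= v_max)
    stop("invalid scale bounds: require v_min < v_max")
  if (!is.finite(h_max) || h_max <= 0)
    stop("invalid scale bounds: require h_max > 0")
  pmin(pmax((v_i - v_min) / (v_max - v_min), 0), 1) * h_max
}

#' Animation bindings: scale bounds and display style per entity
#'
#' @param species tibble with columns `id`, `cmin`, `cmax`, `rmax`
#' @param reactions tibble with columns `id`, `vmin`, `vmax`, `hmax`,
#'   `style` (`"arrow_thickness"` or `"circle"`)
#' @param fps frame rate for video export (frames per second)
#' @param progress progress-bar geometry `c(x, y, width, height)`; `NA` to
#'   place it along the bottom edge automatically
#' @return object of class `animation_bindings`
#' @export
animation_bindings <- function(species, reactions, fps = 10,
                               progress = c(NA_real_, NA_real_,
                                            NA_real_, NA_real_)) {
  species <- tibble::as_tibble(species)
  reactions <- tibble::as_tibble(reactions)
  if (nrow(species) && (any(species$cmin >= species$cmax) ||
                        any(species$rmax <= 0)))
    stop("invalid species bindings: require cmin < cmax and rmax > 0")
  if (nrow(reactions) && (any(reactions$vmin >= reactions$vmax) ||
                          any(reactions$hmax <= 0)))
    stop("invalid reaction bindings: require vmin < vmax and hmax > 0")
  if (nrow(reactions) && !all(reactions$style %in%
                              c("arrow_thickness", "circle")))
    stop("reaction style must be 'arrow_thickness' or 'circle'")
  structure(list(species = species, reactions = reactions, fps = fps,
                 progress = progress),
            class = "animation_bindings")
}

#' Default bindings for a map and a PLT table
#'
#' Scale bounds default to `[0, column maximum]` (so the dynamics are
#' always visible); `r_max` 20 canvas units, `h_max` 10, bar heights use
#' the bar's own `max_height`.
#'
#' @param map a `visual_map`
#' @param plt a `kin_plt`
#' @param fps frame rate (default 10)
#' @param style rate display style (default `"arrow_thickness"`)
#' @return an `animation_bindings`
#' @export
default_bindings <- function(map, plt, fps = 10,
                             style = "arrow_thickness") {
  tt <- plt_titles(plt)
  colmax <- function(v) {
    m <- max(v, na.rm = TRUE)
    if (!is.finite(m) || m <= 0) 1 else m
  }
  species <- tibble::tibble(
    id = tt$metabolites,
    cmin = 0,
    cmax = unname(vapply(tt$metabolites, function(s) colmax(plt[[s]]), 0)),
    rmax = 20)
  reactions <- tibble::tibble(
    id = tt$reactions,
    vmin = 0,
    vmax = unname(vapply(tt$reactions, function(s) colmax(plt[[s]]), 0)),
    hmax = 10,
    style = style)
  animation_bindings(species, reactions, fps = fps)
}

#' Render animation frames from a map, bindings and PLT table
#'
#' PLT columns are matched to map objects by title (case-sensitive): node
#' ids against metabolite columns, arrow ids against reaction columns, bar
#' ids against either.  One frame is rendered per PLT row; each frame
#' stores the scaled radii/thicknesses/heights as metadata alongside the
#' rendered image, plus a progress bar showing the current independent
#' value and a numeric legend with the scale bounds.
#'
#' @param map a `visual_map`
#' @param bindings an `animation_bindings` (default: [default_bindings()])
#' @param plt a `kin_plt`
#' @return list of `kin_frame` objects: `index`, `value` (independent),
#'   `radii`, `thicknesses`, `heights` (named numerics), `image`
#'   (height x width x 3 array)
#' @export
render_frames <- function(map, bindings = NULL, plt) {
  stopifnot(inherits(map, "visual_map"), inherits(plt, "kin_plt"))
  if (is.null(bindings)) bindings <- default_bindings(map, plt)
  tt <- plt_titles(plt)
  plt_cols <- c(tt$metabolites, tt$reactions)
  mapped <- c(map$nodes$id, vapply(map$arrows, function(a) a$id, ""),
              map$bars$id)
  unmatched <- setdiff(mapped, plt_cols)
  if (length(unmatched))
    stop("map objects without matching PLT column title: ",
         paste(unmatched, collapse = ", "))
  sp_bind <- bindings$species
  rx_bind <- bindings$reactions
  miss_b <- setdiff(mapped, c(sp_bind$id, rx_bind$id))
  if (length(miss_b))
    stop("map objects without bindings: ", paste(miss_b, collapse = ", "))

  ind <- plt[[tt$independent]]
  v_lo <- min(ind); v_hi <- max(ind)
  # progress-bar geometry: bottom edge unless given explicitly
  pb <- bindings$progress
  if (anyNA(pb))
    pb <- c(10, map$canvas[[2L]] - 18, map$canvas[[1L]] - 20, 8)

  bar_kind <- stats::setNames(map$bars$kind, map$bars$id)
  rate_style <- stats::setNames(rx_bind$style, rx_bind$id)

  scale_entity <- function(id, value) {
    if (id %in% sp_bind$id) {
      b <- sp_bind[sp_bind$id == id, ]
      scale_radius(value, b$cmin, b$cmax, b$rmax)
    } else {
      b <- rx_bind[rx_bind$id == id, ]
      scale_thickness(value, b$vmin, b$vmax, b$hmax)
    }
  }

  frames <- vector("list", nrow(plt))
  for (i in seq_len(nrow(plt))) {
    row <- plt[i, ]
    radii <- stats::setNames(vapply(map$nodes$id, function(id) {
      b <- sp_bind[sp_bind$id == id, ]
      scale_radius(row[[id]], b$cmin, b$cmax, b$rmax)
    }, 0), map$nodes$id)
    arrow_ids <- vapply(map$arrows, function(a) a$id, "")
    thick <- stats::setNames(vapply(arrow_ids, function(id) {
      b <- rx_bind[rx_bind$id == id, ]
      scale_thickness(row[[id]], b$vmin, b$vmax, b$hmax)
    }, 0), arrow_ids)
    heights <- stats::setNames(vapply(map$bars$id, function(id) {
      bmax <- map$bars$max_height[[which(map$bars$id == id)]]
      if (bar_kind[[id]] == "concentration") {
        b <- sp_bind[sp_bind$id == id, ]
        scale_radius(row[[id]], b$cmin, b$cmax, b$rmax) / b$rmax * bmax
      } else {
        b <- rx_bind[rx_bind$id == id, ]
        scale_thickness(row[[id]], b$vmin, b$vmax, b$hmax) / b$hmax * bmax
      }
    }, 0), map$bars$id)

    img <- render_map_raster(map, radii = radii, thicknesses = thick,
                             heights = heights, rate_style = rate_style)
    # progress bar: outline plus fill proportional to the independent value
    img <- draw_rect(img, pb[1], pb[2], pb[1] + pb[3], pb[2] + pb[4],
                     KIN_COLORS$outline, fill = FALSE)
    frac <- if (v_hi > v_lo) (ind[[i]] - v_lo) / (v_hi - v_lo) else 1
    if (frac > 0)
      img <- draw_rect(img, pb[1] + 1, pb[2] + 1,
                       pb[1] + 1 + frac * (pb[3] - 2), pb[2] + pb[4] - 1,
                       KIN_COLORS$progress)
    legend <- sprintf("%s: %.4g  0..%.4g", tt$independent, ind[[i]],
                      max(c(sp_bind$cmax, rx_bind$vmax)))
    legend <- gsub("[^0-9eE.:+ -]", " ", legend)
    img <- draw_text(img, pb[1], pb[2] - 14, legend, KIN_COLORS$text)
    frames[[i]] <- structure(list(index = i, value = ind[[i]],
                                  radii = radii, thicknesses = thick,
                                  heights = heights, image = img),
                             class = "kin_frame")
  }
  frames
}

## ---- AVI container -------------------------------------------------------------

w_u32 <- function(con, x) writeBin(as.integer(x), con, size = 4,
                                   endian = "little")
w_u16 <- function(con, x) writeBin(as.integer(x), con, size = 2,
                                   endian = "little")
w_4cc <- function(con, s) writeBin(charToRaw(s), con)

# One frame as a bottom-up, BGR, 4-byte-aligned DIB pixel buffer.
frame_to_dib <- function(img) {
  h <- dim(img)[1]; w <- dim(img)[2]
  rowbytes <- ceiling(3 * w / 4) * 4
  px <- array(0L, dim = c(rowbytes, h))
  bytes <- function(k) as.integer(round(pmin(pmax(img[, , k], 0), 1) * 255))
  r <- matrix(bytes(1), h, w); g <- matrix(bytes(2), h, w)
  b <- matrix(bytes(3), h, w)
  for (row in seq_len(h)) {
    src <- h - row + 1L                 # bottom-up
    px[seq(1L, 3L * w, by = 3L), row] <- b[src, ]
    px[seq(2L, 3L * w, by = 3L), row] <- g[src, ]
    px[seq(3L, 3L * w, by = 3L), row] <- r[src, ]
  }
  as.raw(as.vector(px))
}

#' Export frames as an AVI video
#'
#' Writes an AVI container with uncompressed 24-bit DIB frames at the given
#' frame rate.  All frames must share the pixel dimensions of the first.
#'
#' @param frames list of `kin_frame` objects (or raw image arrays)
#' @param path output file
#' @param fps frames per second (default 10)
#' @return `path`, invisibly
#' @export
export_video <- function(frames, path, fps = 10) {
  stopifnot(length(frames) >= 1L)
  imgs <- lapply(frames, function(f)
    if (inherits(f, "kin_frame")) f$image else f)
  h <- dim(imgs[[1L]])[1]; w <- dim(imgs[[1L]])[2]
  for (im in imgs)
    if (!identical(dim(im)[1:2], c(h, w)))
      stop("all frames must have identical pixel dimensions")
  dibs <- lapply(imgs, frame_to_dib)
  fsize <- length(dibs[[1L]])
  n <- length(dibs)

  strl_size <- 4 + (8 + 56) + (8 + 40)
  hdrl_size <- 4 + (8 + 56) + (8 + strl_size)
  movi_size <- 4 + n * (8 + fsize)
  idx1_size <- n * 16
  riff_size <- 4 + (8 + hdrl_size) + (8 + movi_size) + (8 + idx1_size)

  con <- file(path, "wb")
  on.exit(close(con))
  w_4cc(con, "RIFF"); w_u32(con, riff_size); w_4cc(con, "AVI ")

  w_4cc(con, "LIST"); w_u32(con, hdrl_size); w_4cc(con, "hdrl")
  w_4cc(con, "avih"); w_u32(con, 56)
  w_u32(con, round(1e6 / fps))          # microseconds per frame
  w_u32(con, fsize * fps)               # max bytes per second
  w_u32(con, 0)                         # padding granularity
  w_u32(con, 0x10)                      # AVIF_HASINDEX
  w_u32(con, n); w_u32(con, 0); w_u32(con, 1); w_u32(con, fsize)
  w_u32(con, w); w_u32(con, h)
  for (k in 1:4) w_u32(con, 0)          # reserved

  w_4cc(con, "LIST"); w_u32(con, strl_size); w_4cc(con, "strl")
  w_4cc(con, "strh"); w_u32(con, 56)
  w_4cc(con, "vids"); w_4cc(con, "DIB ")
  w_u32(con, 0); w_u32(con, 0); w_u32(con, 0)
  w_u32(con, 1)                         # scale
  w_u32(con, fps)                       # rate -> fps frames per second
  w_u32(con, 0); w_u32(con, n)          # start, length
  w_u32(con, fsize); w_u32(con, 0); w_u32(con, 0)
  w_u16(con, 0); w_u16(con, 0); w_u16(con, w); w_u16(con, h)

  w_4cc(con, "strf"); w_u32(con, 40)
  w_u32(con, 40); w_u32(con, w); w_u32(con, h)
  w_u16(con, 1); w_u16(con, 24)
  w_u32(con, 0); w_u32(con, fsize)
  w_u32(con, 0); w_u32(con, 0); w_u32(con, 0); w_u32(con, 0)

  w_4cc(con, "LIST"); w_u32(con, movi_size); w_4cc(con, "movi")
  for (d in dibs) {
    w_4cc(con, "00db"); w_u32(con, fsize)
    writeBin(d, con)
  }
  w_4cc(con, "idx1"); w_u32(con, idx1_size)
  off <- 4
  for (d in dibs) {
    w_4cc(con, "00db"); w_u32(con, 0x10); w_u32(con, off); w_u32(con, fsize)
    off <- off + 8 + fsize
  }
  invisible(path)
}

#' Decode an AVI file written by [export_video()]
#'
#' Minimal RIFF parser used as the decode-back check: returns the header
#' metadata and (optionally) the decoded frames.
#'
#' @param path AVI file
#' @param frames if `TRUE`, decode the pixel data of every frame
#' @return list: `n_frames`, `width`, `height`, `fps`, `n_chunks` (frame
#'   chunks actually present in the movi list), and `images` when
#'   `frames = TRUE`
#' @export
read_avi <- function(path, frames = FALSE) {
  con <- file(path, "rb")
  on.exit(close(con))
  r_u32 <- function() readBin(con, "integer", size = 4, endian = "little")
  r_4cc <- function() rawToChar(readBin(con, "raw", 4))
  if (r_4cc() != "RIFF") stop("not a RIFF file")
  r_u32()
  if (r_4cc() != "AVI ") stop("not an AVI file")
  n_frames <- NA_integer_; width <- NA_integer_; height <- NA_integer_
  fps <- NA_real_; n_chunks <- 0L; images <- list()
  repeat {
    fourcc <- readBin(con, "raw", 4)
    if (length(fourcc) < 4) break
    fourcc <- rawToChar(fourcc)
    size <- r_u32()
    if (fourcc == "LIST") {
      kind <- r_4cc()
      if (kind == "movi") {
        remaining <- size - 4
        while (remaining >= 8) {
          ck <- r_4cc(); cksz <- r_u32()
          dat <- readBin(con, "raw", cksz + (cksz %% 2))
          remaining <- remaining - 8 - cksz - (cksz %% 2)
          if (ck %in% c("00db", "00dc")) {
            n_chunks <- n_chunks + 1L
            if (frames)
              images[[n_chunks]] <- dib_to_frame(dat[seq_len(cksz)],
                                                 width, height)
          }
        }
      }
      # other LISTs (hdrl, strl): descend by continuing the loop
    } else if (fourcc == "avih") {
      body <- readBin(con, "raw", size)
      u32at <- function(i) sum(as.integer(body[(4 * i + 1):(4 * i + 4)]) *
                                 c(1, 256, 65536, 16777216))
      fps <- 1e6 / u32at(0)
      n_frames <- u32at(4)
      width <- u32at(8); height <- u32at(9)
    } else {
      seek(con, size + (size %% 2), origin = "current")
    }
  }
  out <- list(n_frames = n_frames, width = width, height = height,
              fps = fps, n_chunks = n_chunks)
  if (frames) out$images <- images
  out
}

dib_to_frame <- function(bytes, width, height) {
  rowbytes <- ceiling(3 * width / 4) * 4
  v <- as.integer(bytes)
  img <- array(0, dim = c(height, width, 3))
  for (row in seq_len(height)) {
    base <- (row - 1L) * rowbytes
    dst <- height - row + 1L
    img[dst, , 3] <- v[base + seq(1L, 3L * width, by = 3L)] / 255
    img[dst, , 2] <- v[base + seq(2L, 3L * width, by = 3L)] / 255
    img[dst, , 1] <- v[base + seq(3L, 3L * width, by = 3L)] / 255
  }
  img
}
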