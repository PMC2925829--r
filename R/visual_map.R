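#' @title Visual pathway maps
#' @description The visual-map data model: automatic layout from a
#'   stoichiometric matrix (arrows or bars mode), the inverse construction
#'   of a stoichiometric matrix from a map, free-form annotation, XML
#'   serialization with a strict schema, and static export to SVG and PNG.
#'   Canvas coordinates are abstract units with the origin at the top-left,
#'   x to the right and y down.
#' @name visual_map
NULL

#' Construct a visual map
#'
#' @param canvas numeric `c(width, height)`
#' @param nodes tibble with columns `id`, `x`, `y`, `label`
#' @param arrows list; each element has `id`, `sources` and `targets`
#'   (tibbles with columns `node`, `mult`), optional `points` (tibble `x`,
#'   `y`: polyline control points, used for the free end of an exchange
#'   arrow), `thickness`, `style` (`"solid"` or `"dashed"`, the latter used
#'   for modifier links)
#' @param bars tibble with columns `id`, `kind` (`"concentration"` or
#'   `"rate"`), `x`, `y` (baseline), `width`, `max_height`
#' @param annotations list; each element has `type` (`"text"`, `"line"`,
#'   `"box"`), coordinates `x`, `y` (and `x2`, `y2` for line/box) and
#'   `text`
#' @return object of class `visual_map`
#' @export
visual_map <- function(canvas = c(640, 480),
                       nodes = empty_nodes(), arrows = list(),
                       bars = empty_bars(), annotations = list()) {
  nodes <- tibble::as_tibble(nodes)
  bars <- tibble::as_tibble(bars)
  m <- structure(list(canvas = as.numeric(canvas), nodes = nodes,
                      arrows = arrows, bars = bars,
                      annotations = annotations),
                 class = "visual_map")
  validate_visual_map(m)
  m
}

empty_nodes <- function() tibble::tibble(id = character(), x = numeric(),
                                         y = numeric(), label = character())
empty_bars <- function() tibble::tibble(id = character(), kind = character(),
                                        x = numeric(), y = numeric(),
                                        width = numeric(),
                                        max_height = numeric())

validate_visual_map <- function(m) {
  stopifnot(length(m$canvas) == 2L, all(m$canvas > 0))
  if (anyDuplicated(m$nodes$id))
    stop("node ids must be unique: ",
         m$nodes$id[duplicated(m$nodes$id)][[1L]])
  inside <- function(x, y) all(x >= 0 & x <= m$canvas[[1L]]) &&
    all(y >= 0 & y <= m$canvas[[2L]])
  if (nrow(m$nodes) && !inside(m$nodes$x, m$nodes$y))
    stop("node positions must lie within the canvas")
  for (a in m$arrows) {
    bad <- setdiff(c(a$sources$node, a$targets$node), m$nodes$id)
    if (length(bad))
      stop(sprintf("arrow '%s' references missing node '%s'",
                   a$id, bad[[1L]]))
    if (nrow(a$sources) == 0L && nrow(a$targets) == 0L)
      stop(sprintf("arrow '%s' has no endpoints", a$id))
  }
  invisible(m)
}

#' @export
print.visual_map <- function(x, ...) {
  cat(sprintf("Visual map %g x %g: %d nodes, %d arrows, %d bars, %d annotations\n",
              x$canvas[[1L]], x$canvas[[2L]], nrow(x$nodes),
              length(x$arrows), nrow(x$bars), length(x$annotations)))
  invisible(x)
}

## ---- automatic layout -------------------------------------------------------

#' Automatic map layout from a stoichiometric matrix
#'
#' Arrows mode places one node per species on a grid (ordered by row order
#' of `S`, i.e. first appearance) and draws one arrow per reaction from its
#' substrates to its products; an exchange reaction gets a free boundary
#' point in place of the empty side.  Bars mode creates one bar per species
#' (kind `"concentration"`) followed by one bar per reaction (kind
#' `"rate"`), left to right.  The construction is deterministic: the same
#' matrix always yields the same map.
#'
#' @param S stoichiometric matrix with species row names and reaction
#'   column names
#' @param mode `"arrows"` or `"bars"`
#' @return a `visual_map`
#' @export
auto_layout <- function(S, mode = c("arrows", "bars")) {
  mode <- match.arg(mode)
  species <- rownames(S); rxns <- colnames(S)
  if (mode == "arrows") {
    n <- length(species)
    ncols <- max(1L, ceiling(sqrt(n)))
    nrows <- max(1L, ceiling(n / ncols))
    margin <- 80; spacing <- 140
    canvas <- c(2 * margin + (ncols - 1) * spacing,
                2 * margin + (nrows - 1) * spacing)
    idx <- seq_len(n) - 1L
    nodes <- tibble::tibble(
      id = species,
      x = margin + (idx %% ncols) * spacing,
      y = margin + (idx %/% ncols) * spacing,
      label = species)
    arrows <- lapply(seq_along(rxns), function(j) {
      col <- stats::setNames(S[, j], rownames(S))   # names survive 1-row S
      subs <- names(col)[col < 0]; prods <- names(col)[col > 0]
      pts <- tibble::tibble(x = numeric(), y = numeric())
      centroid <- function(ids) c(mean(nodes$x[match(ids, nodes$id)]),
                                  mean(nodes$y[match(ids, nodes$id)]))
      if (length(subs) == 0L && length(prods) > 0L) {
        ctr <- centroid(prods)
        pts <- tibble::tibble(x = max(0, ctr[[1L]] - spacing / 2),
                              y = max(0, ctr[[2L]] - spacing / 2))
      } else if (length(prods) == 0L && length(subs) > 0L) {
        ctr <- centroid(subs)
        pts <- tibble::tibble(x = min(canvas[[1L]], ctr[[1L]] + spacing / 2),
                              y = min(canvas[[2L]], ctr[[2L]] + spacing / 2))
      }
      list(id = rxns[[j]],
           sources = tibble::tibble(node = subs, mult = as.numeric(-col[subs])),
           targets = tibble::tibble(node = prods, mult = as.numeric(col[prods])),
           points = pts, thickness = 2, style = "solid")
    })
    visual_map(canvas, nodes, arrows)
  } else {
    ids <- c(species, rxns)
    kinds <- c(rep("concentration", length(species)),
               rep("rate", length(rxns)))
    width <- 28; gap <- 14; margin <- 40; max_h <- 160
    canvas <- c(2 * margin + length(ids) * (width + gap) - gap,
                2 * margin + max_h + 40)
    bars <- tibble::tibble(
      id = ids, kind = kinds,
      x = margin + (seq_along(ids) - 1L) * (width + gap),
      y = margin + max_h,             # baseline; bars grow upward
      width = width, max_height = max_h)
    visual_map(canvas, bars = bars)
  }
}

#' Recover a stoichiometric matrix from an arrows-mode map
#'
#' Each arrow contributes its source multiplicities negatively and its
#' target multiplicities positively; the inverse of [auto_layout()] on its
#' image.  Species order follows node order, reaction order follows arrow
#' order.
#'
#' @param map a `visual_map` with nodes and arrows
#' @return integer stoichiometric matrix
#' @export
map_to_stoichiometry <- function(map) {
  stopifnot(inherits(map, "visual_map"))
  if (length(map$arrows) == 0L)
    stop("map has no arrows: cannot build a stoichiometric matrix")
  species <- map$nodes$id
  S <- matrix(0L, length(species), length(map$arrows),
              dimnames = list(species,
                              vapply(map$arrows, function(a) a$id, "")))
  for (j in seq_along(map$arrows)) {
    a <- map$arrows[[j]]
    for (k in seq_len(nrow(a$sources))) {
      nd <- a$sources$node[[k]]
      if (!nd %in% species)
        stop(sprintf("arrow '%s' has a dangling source endpoint '%s'",
                     a$id, nd))
      S[nd, j] <- S[nd, j] - as.integer(a$sources$mult[[k]])
    }
    for (k in seq_len(nrow(a$targets))) {
      nd <- a$targets$node[[k]]
      if (!nd %in% species)
        stop(sprintf("arrow '%s' has a dangling target endpoint '%s'",
                     a$id, nd))
      S[nd, j] <- S[nd, j] + as.integer(a$targets$mult[[k]])
    }
  }
  S
}

#' Add a free annotation to a map
#' @param map a `visual_map`
#' @param type `"text"`, `"line"` or `"box"`
#' @param x,y position (top-left / first endpoint)
#' @param x2,y2 second corner / endpoint (line and box)
#' @param text annotation text (type `"text"`)
#' @return updated map
#' @export
annotate_map <- function(map, type = c("text", "line", "box"), x, y,
                         x2 = NA_real_, y2 = NA_real_, text = "") {
  type <- match.arg(type)
  map$annotations[[length(map$annotations) + 1L]] <-
    list(type = type, x = x, y = y, x2 = x2, y2 = y2, text = text)
  map
}

## ---- XML serialization -------------------------------------------------------

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}
parse_num <- function(s) {
  out <- suppressWarnings(as.numeric(s))
  out[s == "NA"] <- NA_real_
  out
}

#' Write a visual map (and optional animation bindings) as XML
#'
#' The schema has elements `map`, `node`, `arrow` (children `source`,
#' `target`, `point`), `bar`, `annotation` and `bindings` (children
#' `species`, `reaction`, `global`); numeric attributes are decimal strings
#' at full double precision, so `read_map(write_map(m))` is structurally
#' equal to `m`.
#'
#' @param map a `visual_map`
#' @param path output file
#' @param bindings optional `animation_bindings`
#' @return `path`, invisibly
#' @export
write_map <- function(map, path, bindings = NULL) {
  stopifnot(inherits(map, "visual_map"))
  doc <- xml2::xml_new_root("map",
                            width = fmt_num(map$canvas[[1L]]),
                            height = fmt_num(map$canvas[[2L]]))
  for (i in seq_len(nrow(map$nodes)))
    xml2::xml_add_child(doc, "node", id = map$nodes$id[[i]],
                        x = fmt_num(map$nodes$x[[i]]),
                        y = fmt_num(map$nodes$y[[i]]),
                        label = map$nodes$label[[i]])
  for (a in map$arrows) {
    an <- xml2::xml_add_child(doc, "arrow", id = a$id,
                              thickness = fmt_num(a$thickness),
                              style = a$style)
    for (k in seq_len(nrow(a$sources)))
      xml2::xml_add_child(an, "source", node = a$sources$node[[k]],
                          mult = fmt_num(a$sources$mult[[k]]))
    for (k in seq_len(nrow(a$targets)))
      xml2::xml_add_child(an, "target", node = a$targets$node[[k]],
                          mult = fmt_num(a$targets$mult[[k]]))
    for (k in seq_len(nrow(a$points)))
      xml2::xml_add_child(an, "point", x = fmt_num(a$points$x[[k]]),
                          y = fmt_num(a$points$y[[k]]))
  }
  for (i in seq_len(nrow(map$bars)))
    xml2::xml_add_child(doc, "bar", id = map$bars$id[[i]],
                        kind = map$bars$kind[[i]],
                        x = fmt_num(map$bars$x[[i]]),
                        y = fmt_num(map$bars$y[[i]]),
                        width = fmt_num(map$bars$width[[i]]),
                        max_height = fmt_num(map$bars$max_height[[i]]))
  for (an in map$annotations) {
    node <- xml2::xml_add_child(doc, "annotation", type = an$type,
                                x = fmt_num(an$x), y = fmt_num(an$y),
                                x2 = fmt_num(an$x2), y2 = fmt_num(an$y2))
    xml2::xml_text(node) <- an$text
  }
  if (!is.null(bindings)) {
    bn <- xml2::xml_add_child(doc, "bindings",
                              fps = fmt_num(bindings$fps))
    xml2::xml_add_child(bn, "global",
                        progress_x = fmt_num(bindings$progress[[1L]]),
                        progress_y = fmt_num(bindings$progress[[2L]]),
                        progress_w = fmt_num(bindings$progress[[3L]]),
                        progress_h = fmt_num(bindings$progress[[4L]]))
    for (i in seq_len(nrow(bindings$species)))
      xml2::xml_add_child(bn, "species",
                          id = bindings$species$id[[i]],
                          cmin = fmt_num(bindings$species$cmin[[i]]),
                          cmax = fmt_num(bindings$species$cmax[[i]]),
                          rmax = fmt_num(bindings$species$rmax[[i]]))
    for (i in seq_len(nrow(bindings$reactions)))
      xml2::xml_add_child(bn, "reaction",
                          id = bindings$reactions$id[[i]],
                          vmin = fmt_num(bindings$reactions$vmin[[i]]),
                          vmax = fmt_num(bindings$reactions$vmax[[i]]),
                          hmax = fmt_num(bindings$reactions$hmax[[i]]),
                          style = bindings$reactions$style[[i]])
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a visual map XML file
#'
#' Strict reader: an element outside the published schema is an error
#' naming the element and its path.
#'
#' @param path file path
#' @return list with elements `map` (a `visual_map`) and `bindings`
#'   (`animation_bindings` or `NULL`)
#' @export
read_map <- function(path) {
  doc <- xml2::read_xml(path)
  if (xml2::xml_name(doc) != "map")
    stop("map schema violation at /: root element must be <map>")
  att <- function(node, name) {
    v <- xml2::xml_attr(node, name)
    if (is.na(v)) stop(sprintf("map schema violation at %s: missing attribute '%s'",
                               xml2::xml_path(node), name))
    v
  }
  canvas <- c(parse_num(att(doc, "width")), parse_num(att(doc, "height")))
  nodes <- empty_nodes(); arrows <- list(); bars <- empty_bars()
  annotations <- list(); bindings <- NULL
  for (child in xml2::xml_children(doc)) {
    nm <- xml2::xml_name(child)
    if (nm == "node") {
      nodes <- rbind(nodes, tibble::tibble(
        id = att(child, "id"), x = parse_num(att(child, "x")),
        y = parse_num(att(child, "y")), label = att(child, "label")))
    } else if (nm == "arrow") {
      sources <- tibble::tibble(node = character(), mult = numeric())
      targets <- sources
      points <- tibble::tibble(x = numeric(), y = numeric())
      for (sub in xml2::xml_children(child)) {
        snm <- xml2::xml_name(sub)
        if (snm == "source")
          sources <- rbind(sources, tibble::tibble(
            node = att(sub, "node"), mult = parse_num(att(sub, "mult"))))
        else if (snm == "target")
          targets <- rbind(targets, tibble::tibble(
            node = att(sub, "node"), mult = parse_num(att(sub, "mult"))))
        else if (snm == "point")
          points <- rbind(points, tibble::tibble(
            x = parse_num(att(sub, "x")), y = parse_num(att(sub, "y"))))
        else stop(sprintf("map schema violation: unknown element '%s' at %s",
                          snm, xml2::xml_path(sub)))
      }
      arrows[[length(arrows) + 1L]] <- list(
        id = att(child, "id"), sources = sources, targets = targets,
        points = points, thickness = parse_num(att(child, "thickness")),
        style = att(child, "style"))
    } else if (nm == "bar") {
      bars <- rbind(bars, tibble::tibble(
        id = att(child, "id"), kind = att(child, "kind"),
        x = parse_num(att(child, "x")), y = parse_num(att(child, "y")),
        width = parse_num(att(child, "width")),
        max_height = parse_num(att(child, "max_height"))))
    } else if (nm == "annotation") {
      annotations[[length(annotations) + 1L]] <- list(
        type = att(child, "type"), x = parse_num(att(child, "x")),
        y = parse_num(att(child, "y")), x2 = parse_num(att(child, "x2")),
        y2 = parse_num(att(child, "y2")), text = xml2::xml_text(child))
    } else if (nm == "bindings") {
      bindings <- read_bindings_node(child, att)
    } else {
      stop(sprintf("map schema violation: unknown element '%s' at %s",
                   nm, xml2::xml_path(child)))
    }
  }
  list(map = visual_map(canvas, nodes, arrows, bars, annotations),
       bindings = bindings)
}

read_bindings_node <- function(node, att) {
  species <- tibble::tibble(id = character(), cmin = numeric(),
                            cmax = numeric(), rmax = numeric())
  reactions <- tibble::tibble(id = character(), vmin = numeric(),
                              vmax = numeric(), hmax = numeric(),
                              style = character())
  progress <- c(NA_real_, NA_real_, NA_real_, NA_real_)
  for (sub in xml2::xml_children(node)) {
    nm <- xml2::xml_name(sub)
    if (nm == "species")
      species <- rbind(species, tibble::tibble(
        id = att(sub, "id"), cmin = parse_num(att(sub, "cmin")),
        cmax = parse_num(att(sub, "cmax")),
        rmax = parse_num(att(sub, "rmax"))))
    else if (nm == "reaction")
      reactions <- rbind(reactions, tibble::tibble(
        id = att(sub, "id"), vmin = parse_num(att(sub, "vmin")),
        vmax = parse_num(att(sub, "vmax")),
        hmax = parse_num(att(sub, "hmax")), style = att(sub, "style")))
    else if (nm == "global")
      progress <- c(parse_num(att(sub, "progress_x")),
                    parse_num(att(sub, "progress_y")),
                    parse_num(att(sub, "progress_w")),
                    parse_num(att(sub, "progress_h")))
    else stop(sprintf("map schema violation: unknown element '%s' at %s",
                      nm, xml2::xml_path(sub)))
  }
  animation_bindings(species, reactions,
                     fps = parse_num(xml2::xml_attr(node, "fps")),
                     progress = progress)
}

## ---- static export -----------------------------------------------------------

arrow_geometry <- function(map, a) {
  nd <- map$nodes
  pos <- function(ids) cbind(nd$x[match(ids, nd$id)], nd$y[match(ids, nd$id)])
  src <- if (nrow(a$sources)) pos(a$sources$node) else
    as.matrix(a$points[1L, c("x", "y")])
  tgt <- if (nrow(a$targets)) pos(a$targets$node) else
    as.matrix(a$points[nrow(a$points), c("x", "y")])
  list(x1 = mean(src[, 1L]), y1 = mean(src[, 2L]),
       x2 = mean(tgt[, 1L]), y2 = mean(tgt[, 2L]))
}

#' Export a visual map to SVG or PNG
#'
#' The SVG contains one drawing element per map object (a `circle` per
#' node, a `line` per arrow, a `rect` per bar, plus annotation elements)
#' and is byte-deterministic; the PNG raster has exactly the canvas pixel
#' dimensions.
#'
#' @param map a `visual_map`
#' @param path output file; format chosen by `format`
#' @param format `"svg"` or `"png"`
#' @return `path`, invisibly
#' @export
export_map <- function(map, path, format = c("svg", "png")) {
  format <- match.arg(format)
  if (format == "svg") {
    lines <- c(sprintf(
      '<svg xmlns="http://www.w3.org/2000/svg" width="%s" height="%s">',
      fmt_num(map$canvas[[1L]]), fmt_num(map$canvas[[2L]])))
    for (a in map$arrows) {
      g <- arrow_geometry(map, a)
      dash <- if (identical(a$style, "dashed")) ' stroke-dasharray="6,4"' else ""
      lines <- c(lines, sprintf(
        '<line class="arrow" id="%s" x1="%s" y1="%s" x2="%s" y2="%s" stroke="#1f4ab0" stroke-width="%s"%s/>',
        a$id, fmt_num(g$x1), fmt_num(g$y1), fmt_num(g$x2), fmt_num(g$y2),
        fmt_num(a$thickness), dash))
    }
    for (i in seq_len(nrow(map$nodes)))
      lines <- c(lines, sprintf(
        '<circle class="node" id="%s" cx="%s" cy="%s" r="12" fill="none" stroke="#218c21" stroke-width="2"/>',
        map$nodes$id[[i]], fmt_num(map$nodes$x[[i]]),
        fmt_num(map$nodes$y[[i]])))
    for (i in seq_len(nrow(map$bars)))
      lines <- c(lines, sprintf(
        '<rect class="bar" id="%s" x="%s" y="%s" width="%s" height="%s" fill="none" stroke="#444444"/>',
        map$bars$id[[i]], fmt_num(map$bars$x[[i]]),
        fmt_num(map$bars$y[[i]] - map$bars$max_height[[i]]),
        fmt_num(map$bars$width[[i]]), fmt_num(map$bars$max_height[[i]])))
    for (an in map$annotations) {
      if (an$type == "text")
        lines <- c(lines, sprintf(
          '<text class="annotation" x="%s" y="%s">%s</text>',
          fmt_num(an$x), fmt_num(an$y), an$text))
      else if (an$type == "line")
        lines <- c(lines, sprintf(
          '<line class="annotation" x1="%s" y1="%s" x2="%s" y2="%s" stroke="#333333"/>',
          fmt_num(an$x), fmt_num(an$y), fmt_num(an$x2), fmt_num(an$y2)))
      else
        lines <- c(lines, sprintf(
          '<rect class="annotation" x="%s" y="%s" width="%s" height="%s" fill="none" stroke="#333333"/>',
          fmt_num(min(an$x, an$x2)), fmt_num(min(an$y, an$y2)),
          fmt_num(abs(an$x2 - an$x)), fmt_num(abs(an$y2 - an$y))))
    }
    lines <- c(lines, "</svg>")
    con <- file(path, "wb")   # binary: byte-identical across platforms
    on.exit(close(con))
    writeBin(charToRaw(paste0(paste(lines, collapse = "\n"), "\n")), con)
  } else {
    img <- render_map_raster(map)
    png::writePNG(img, path)
  }
  invisible(path)
}

# Base rendering (no animation data): node circles at a fixed radius,
# arrows at base thickness, bars as outlines at max height.
render_map_raster <- function(map, radii = NULL, thicknesses = NULL,
                              heights = NULL, rate_style = NULL) {
  img <- new_canvas(round(map$canvas[[1L]]), round(map$canvas[[2L]]))
  for (a in map$arrows) {
    g <- arrow_geometry(map, a)
    th <- if (!is.null(thicknesses) && a$id %in% names(thicknesses))
      thicknesses[[a$id]] else a$thickness
    style <- if (!is.null(rate_style) && a$id %in% names(rate_style))
      rate_style[[a$id]] else "arrow_thickness"
    if (style == "circle") {
      img <- draw_segment(img, g$x1, g$y1, g$x2, g$y2, 1, KIN_COLORS$arrow)
      img <- draw_disc(img, (g$x1 + g$x2) / 2, (g$y1 + g$y2) / 2,
                       th, KIN_COLORS$arrow)
    } else if (th > 0) {
      img <- draw_segment(img, g$x1, g$y1, g$x2, g$y2, th, KIN_COLORS$arrow)
      img <- draw_arrowhead(img, g$x1, g$y1, g$x2, g$y2,
                            max(8, 2.5 * th), KIN_COLORS$arrow)
    }
  }
  for (i in seq_len(nrow(map$nodes))) {
    nd <- map$nodes[i, ]
    r <- if (!is.null(radii) && nd$id %in% names(radii)) radii[[nd$id]] else 12
    if (r > 0) img <- draw_disc(img, nd$x, nd$y, r, KIN_COLORS$node)
    img <- draw_circle_outline(img, nd$x, nd$y, 13, KIN_COLORS$outline)
  }
  for (i in seq_len(nrow(map$bars))) {
    b <- map$bars[i, ]
    img <- draw_rect(img, b$x, b$y - b$max_height, b$x + b$width, b$y,
                     KIN_COLORS$outline, fill = FALSE)
    hgt <- if (!is.null(heights) && b$id %in% names(heights))
      heights[[b$id]] else 0
    if (hgt > 0)
      img <- draw_rect(img, b$x + 1, b$y - hgt, b$x + b$width - 1, b$y,
                       KIN_COLORS[[paste0("bar_", b$kind)]])
  }
  for (an in map$annotations) {
    if (an$type == "text")
      img <- draw_text(img, an$x, an$y, an$text, KIN_COLORS$text)
    else if (an$type == "line")
      img <- draw_segment(img, an$x, an$y, an$x2, an$y2, 1, KIN_COLORS$text)
    else
      img <- draw_rect(img, an$x, an$y, an$x2, an$y2, KIN_COLORS$text,
                       fill = FALSE)
  }
  img
}
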