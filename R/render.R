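#' Styling for rendered figures
#'
#' Collects the palette and scale choices the renderer uses. Discrete
#' categories draw from an ordered 12-colour palette; when a layer has
#' more categories than `max_categories`, the least frequent ones pool
#' into `"Other"`. Continuous values map through a sequential or diverging
#' anchor ramp interpolated in Lab space (so the ramp is perceptually
#' monotone in the data value); diverging maps are centred on the data
#' midpoint. Bar lengths scale linearly from the data range onto
#' `bar_length` pixels.
#'
#' @param discrete_palette ordered vector of hex colours.
#' @param sequential two anchor colours, low to high.
#' @param diverging three anchor colours: low, midpoint, high.
#' @param missing_color colour for missing values.
#' @param bar_length c(min, max) bar length in px for numeric layers.
#' @param max_categories discrete categories kept before pooling.
#' @return a `style_spec`.
#' @export
style_spec <- function(discrete_palette = c(
                         "#1f77b4", "#ff7f0e", "#2ca02c", "#d62728",
                         "#9467bd", "#8c564b", "#e377c2", "#7f7f7f",
                         "#bcbd22", "#17becf", "#aec7e8", "#ffbb78"),
                       sequential = c("#f7fbff", "#08306b"),
                       diverging = c("#2166ac", "#f7f7f7", "#b2182b"),
                       missing_color = "#bdbdbd",
                       bar_length = c(4, 40),
                       max_categories = 12L) {
  stopifnot(length(sequential) == 2L, length(diverging) == 3L,
            length(bar_length) == 2L, max_categories >= 1L)
  structure(list(discrete_palette = discrete_palette,
                 sequential = sequential, diverging = diverging,
                 missing_color = missing_color, bar_length = bar_length,
                 max_categories = max_categories),
            class = "style_spec")
}

hexify <- function(rgb_rows) {
  grDevices::rgb(rgb_rows[, 1L], rgb_rows[, 2L], rgb_rows[, 3L],
                 maxColorValue = 255)
}

#' Map numeric values through a continuous colour ramp
#'
#' @param values numeric vector (NA allowed).
#' @param style a [style_spec()].
#' @param map `"sequential"` or `"diverging"` (centred on the data
#'   midpoint).
#' @return hex colours, `missing_color` for NA.
#' @export
continuous_colors <- function(values, style = style_spec(),
                              map = c("sequential", "diverging")) {
  map <- match.arg(map)
  anchors <- if (map == "sequential") style$sequential else style$diverging
  ramp <- grDevices::colorRamp(anchors, space = "Lab")
  rng <- range(values, na.rm = TRUE)
  t <- if (diff(rng) == 0) ifelse(is.na(values), NA_real_, 0.5) else
    (values - rng[1L]) / diff(rng)
  out <- rep(style$missing_color, length(values))
  ok <- !is.na(t)
  if (any(ok)) out[ok] <- hexify(ramp(t[ok]))
  out
}

# assign palette colours to category names; pool overflow into "Other"
discrete_assignment <- function(categories, counts, style) {
  ord <- names(sort(counts, decreasing = TRUE))
  ord <- c(setdiff(ord, MISSING_CATEGORY), intersect(ord, MISSING_CATEGORY))
  kept <- utils::head(setdiff(ord, MISSING_CATEGORY),
                      style$max_categories - 1L)
  pooled <- setdiff(ord, c(kept, MISSING_CATEGORY))
  if (length(pooled) == 1L) { kept <- c(kept, pooled); pooled <- character(0) }
  lab <- c(kept, if (length(pooled)) "Other")
  col <- stats::setNames(
    rep(style$discrete_palette, length.out = length(lab)), lab)
  map <- stats::setNames(rep("Other", length(categories)), categories)
  map[intersect(kept, categories)] <- intersect(kept, categories)
  if (MISSING_CATEGORY %in% categories) map[MISSING_CATEGORY] <- MISSING_CATEGORY
  list(map = map, colors = col)
}

fmt <- function(x) sprintf("%.4f", x)

svg_el <- function(tag, ..., children = NULL) {
  attrs <- c(...)
  a <- if (length(attrs))
    paste0(" ", paste0(names(attrs), "=\"", attrs, "\"", collapse = "")) else ""
  if (is.null(children)) paste0("<", tag, a, "/>")
  else paste0("<", tag, a, ">", paste(children, collapse = ""),
              "</", tag, ">")
}

svg_line <- function(x1, y1, x2, y2, stroke = "#333333", width = 1) {
  svg_el("line", x1 = fmt(x1), y1 = fmt(y1), x2 = fmt(x2), y2 = fmt(y2),
         stroke = stroke, `stroke-width` = fmt(width))
}

svg_text <- function(x, y, s, size = 10, anchor = "start") {
  paste0("<text x=\"", fmt(x), "\" y=\"", fmt(y), "\" font-size=\"",
         fmt(size), "\" font-family=\"sans-serif\" text-anchor=\"", anchor,
         "\">", xml_escape(s), "</text>")
}

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

# arc path at fixed radius from angle a0 to a1 (radians, |a1-a0| < 2*pi)
svg_arc <- function(cx, cy, r, a0, a1, stroke = "#333333", width = 1) {
  large <- as.integer(abs(a1 - a0) > pi)
  sweep <- as.integer(a1 > a0)
  paste0("<path d=\"M ", fmt(cx + r * cos(a0)), " ", fmt(cy + r * sin(a0)),
         " A ", fmt(r), " ", fmt(r), " 0 ", large, " ", sweep, " ",
         fmt(cx + r * cos(a1)), " ", fmt(cy + r * sin(a1)),
         "\" fill=\"none\" stroke=\"", stroke, "\" stroke-width=\"",
         fmt(width), "\"/>")
}

svg_polygon <- function(xs, ys, fill, stroke = "none") {
  paste0("<polygon points=\"",
         paste(paste0(fmt(xs), ",", fmt(ys)), collapse = " "),
         "\" fill=\"", fill, "\" stroke=\"", stroke, "\"/>")
}

svg_rect <- function(x, y, w, h, fill) {
  svg_el("rect", x = fmt(x), y = fmt(y), width = fmt(w), height = fmt(h),
         fill = fill)
}

# annular sector (ring cell) between radii r0 < r1 over angles a0..a1
svg_ring_cell <- function(cx, cy, r0, r1, a0, a1, fill) {
  large <- as.integer(abs(a1 - a0) > pi)
  p <- function(r, a) paste0(fmt(cx + r * cos(a)), " ", fmt(cy + r * sin(a)))
  paste0("<path d=\"M ", p(r0, a0),
         " L ", p(r1, a0),
         " A ", fmt(r1), " ", fmt(r1), " 0 ", large, " 1 ", p(r1, a1),
         " L ", p(r0, a1),
         " A ", fmt(r0), " ", fmt(r0), " 0 ", large, " 0 ", p(r0, a0),
         " Z\" fill=\"", fill, "\" stroke=\"none\"/>")
}

#' Render a laid-out tree to a static SVG file
#'
#' Draws the tree edges for any layout, optional per-node colours,
#' collapsed clades as labelled wedges, and — for rectangular and circular
#' layouts — barplot layers beside/around the tips, innermost first, each
#' with a legend block. Output is deterministic: the same inputs produce
#' byte-identical SVG.
#'
#' @param layout a `tree_layout` from one of the [layouts].
#' @param node_colors optional character vector of per-node colours
#'   (preorder, NA = not drawn), e.g. derived from
#'   [propagate_uniform_metadata()].
#' @param collapsed optional data.frame from [collapse_uniform_clades()];
#'   collapsed subtrees are replaced by wedges labelled value (n tips).
#' @param barplot_layers list of `barplot_layer` objects, innermost first.
#'   An error for unrooted layouts, whose tips are not aligned.
#' @param style a [style_spec()].
#' @param out_path file to write.
#' @param width,height canvas size in px.
#' @return `out_path`, invisibly; the file is written.
#' @export
render_svg <- function(layout, node_colors = NULL, collapsed = NULL,
                       barplot_layers = list(), style = style_spec(),
                       out_path, width = 800, height = 600) {
  stopifnot(inherits(layout, "tree_layout"))
  if (length(barplot_layers) && layout$kind == "unrooted")
    stop("barplot layers are not supported on the unrooted layout ",
         "(tips are not aligned)")
  tree <- layout$tree
  nodes <- layout$nodes
  margin <- 40
  legend_w <- if (length(barplot_layers) || !is.null(node_colors)) 170 else 0

  hidden <- rep(FALSE, tree$n_nodes)      # nodes inside collapsed clades
  if (!is.null(collapsed) && nrow(collapsed)) {
    for (r in seq_len(nrow(collapsed))) {
      nd <- node_of(tree, collapsed$node[r])
      inside <- tree$open_pos > tree$open_pos[nd] &
        tree$open_pos <= tree$close_pos[nd]
      hidden <- hidden | inside
    }
  }

  # data-space bounding box including bar space
  bar_total <- if (length(barplot_layers)) length(barplot_layers) else 0
  body <- character(0)
  if (layout$kind == "circular") {
    max_r <- max(nodes$radius)
    ring_w <- 0.12 * max_r
    ext <- max_r + bar_total * ring_w * 1.1 + ring_w * 0.2
    lim <- c(-ext, ext)
    sc <- min((width - 2 * margin - legend_w) / diff(lim),
              (height - 2 * margin) / diff(lim))
    tx <- function(x) margin + (x - lim[1L]) * sc
    ty <- function(y) margin + (lim[2L] - y) * sc    # y up in data space
    cx <- tx(0); cy <- ty(0)
    s_r <- function(r) r * sc
    # edges: radial segment from parent's radius to node's radius
    for (nd in 2:tree$n_nodes) {
      if (hidden[nd]) next
      p <- tree$parent[nd]
      a <- nodes$angle[nd]
      body <- c(body, svg_line(cx + s_r(nodes$radius[p]) * cos(a),
                               cy - s_r(nodes$radius[p]) * sin(a),
                               cx + s_r(nodes$radius[nd]) * cos(a),
                               cy - s_r(nodes$radius[nd]) * sin(a)))
    }
    cn <- layout$connectors
    for (r in seq_len(nrow(cn))) {
      nd <- node_of(tree, cn$node[r])
      if (hidden[nd] || cn$span[r] <= 0) next
      body <- c(body, svg_arc(cx, cy, s_r(cn$radius[r]),
                              -cn$angle_start[r],
                              -(cn$angle_start[r] + cn$span[r])))
    }
  } else {
    xr <- range(nodes$x); yr <- range(nodes$y)
    if (diff(yr) == 0) yr <- yr + c(-0.5, 0.5)
    bar_w_data <- 0.08 * max(diff(xr), 1e-9)
    ext_x <- xr[2L] + bar_total * bar_w_data * 1.25 + bar_w_data * 0.25
    sc_x <- (width - 2 * margin - legend_w) / max(ext_x - xr[1L], 1e-9)
    sc_y <- (height - 2 * margin) / diff(yr)
    tx <- function(x) margin + (x - xr[1L]) * sc_x
    ty <- function(y) margin + (y - yr[1L]) * sc_y
    if (layout$kind == "rectangular") {
      for (nd in 2:max(tree$n_nodes, 2L)) {
        if (tree$n_nodes == 1L) break
        if (hidden[nd]) next
        p <- tree$parent[nd]
        body <- c(body, svg_line(tx(nodes$x[p]), ty(nodes$y[nd]),
                                 tx(nodes$x[nd]), ty(nodes$y[nd])))
      }
      cn <- layout$connectors
      for (r in seq_len(nrow(cn))) {
        if (hidden[node_of(tree, cn$node[r])]) next
        body <- c(body, svg_line(tx(cn$x[r]), ty(cn$y_min[r]),
                                 tx(cn$x[r]), ty(cn$y_max[r])))
      }
    } else {                              # unrooted: straight edges
      for (nd in 2:max(tree$n_nodes, 2L)) {
        if (tree$n_nodes == 1L) break
        if (hidden[nd]) next
        p <- tree$parent[nd]
        body <- c(body, svg_line(tx(nodes$x[p]), ty(nodes$y[p]),
                                 tx(nodes$x[nd]), ty(nodes$y[nd])))
      }
    }
  }

  # node colour dots
  legend <- list()
  if (!is.null(node_colors)) {
    stopifnot(length(node_colors) == tree$n_nodes)
    for (nd in which(!is.na(node_colors) & !hidden)) {
      if (layout$kind == "circular") {
        a <- nodes$angle[nd]; r <- nodes$radius[nd]
        px <- cx + r * sc * cos(a); py <- cy - r * sc * sin(a)
      } else { px <- tx(nodes$x[nd]); py <- ty(nodes$y[nd]) }
      body <- c(body, svg_el("circle", cx = fmt(px), cy = fmt(py),
                             r = "2.5", fill = node_colors[nd]))
    }
  }

  # collapsed wedges
  if (!is.null(collapsed) && nrow(collapsed)) {
    pal <- rep(style$discrete_palette,
               length.out = max(nrow(collapsed), 1L))
    for (r in seq_len(nrow(collapsed))) {
      nd <- node_of(tree, collapsed$node[r])
      span <- which(tree$open_pos >= tree$open_pos[nd] &
                    tree$open_pos <= tree$close_pos[nd])
      tipsd <- span[tree$is_tip[span]]
      lab <- paste0(collapsed$value[r], " (", collapsed$n_tips[r], ")")
      if (layout$kind == "circular") {
        a <- range(nodes$angle[tipsd])
        rr <- max(nodes$radius[tipsd])
        body <- c(body, svg_polygon(
          c(cx + nodes$radius[nd] * sc * cos(nodes$angle[nd]),
            cx + rr * sc * cos(a[1L]), cx + rr * sc * cos(a[2L])),
          c(cy - nodes$radius[nd] * sc * sin(nodes$angle[nd]),
            cy - rr * sc * sin(a[1L]), cy - rr * sc * sin(a[2L])),
          fill = pal[r]))
        body <- c(body, svg_text(cx + rr * sc * cos(mean(a)) + 3,
                                 cy - rr * sc * sin(mean(a)), lab, size = 9))
      } else {
        yr2 <- range(nodes$y[tipsd]); xr2 <- max(nodes$x[tipsd])
        body <- c(body, svg_polygon(
          c(tx(nodes$x[nd]), tx(xr2), tx(xr2)),
          c(ty(nodes$y[nd]), ty(yr2[1L]), ty(yr2[2L])),
          fill = pal[r]))
        body <- c(body, svg_text(tx(xr2) + 3, ty(nodes$y[nd]) + 3, lab,
                                 size = 9))
      }
    }
  }

  # barplot layers (rect: columns right of tips; circular: rings)
  if (length(barplot_layers)) {
    tip_nd <- which(tree$is_tip & !hidden)
    for (li in seq_along(barplot_layers)) {
      layer <- barplot_layers[[li]]
      stopifnot(inherits(layer, "barplot_layer"))
      group <- character(0)
      if (layer$kind == "categorical_stacked") {
        cats <- sort(unique(unlist(lapply(layer$payload, names))))
        counts <- table(unlist(lapply(layer$payload, names)))
        da <- discrete_assignment(cats, counts, style)
        shown <- unique(unname(da$map))
        cols <- stats::setNames(
          rep(style$discrete_palette, length.out = length(shown)), shown)
        if (MISSING_CATEGORY %in% shown)
          cols[MISSING_CATEGORY] <- style$missing_color
        legend[[length(legend) + 1L]] <-
          list(title = layer$field, labels = shown, colors = cols)
      } else {
        vals <- layer$payload
        rngv <- suppressWarnings(range(vals, na.rm = TRUE))
        legend[[length(legend) + 1L]] <-
          list(title = layer$field,
               labels = c(format(rngv[1L]), format(rngv[2L])),
               colors = continuous_colors(rngv, style))
      }
      for (nd in tip_nd) {
        tip <- tree$names[nd]
        pay <- layer$payload[[tip]]
        if (layout$kind == "rectangular") {
          x0 <- tx(xr[2L] + (li - 1) * bar_w_data * 1.25 + bar_w_data * 0.25)
          wpx <- bar_w_data * 1.0 * sc_x
          hpx <- 0.8 * sc_y
          y0 <- ty(nodes$y[nd]) - hpx / 2
          if (layer$kind == "categorical_stacked") {
            if (length(pay) == 0L) next
            acc <- 0
            for (cname in names(pay)) {
              shown_c <- da$map[[cname]]
              body <- c(body, svg_rect(x0 + acc * wpx, y0,
                                       pay[[cname]] * wpx, hpx,
                                       cols[[shown_c]]))
              acc <- acc + pay[[cname]]
            }
            body <- c(body, paste0("<!-- bar tip=\"", xml_escape(tip),
                                   "\" layer=\"", li, "\" -->"))
          } else {
            v <- pay
            allv <- layer$payload
            rngv <- suppressWarnings(range(allv, na.rm = TRUE))
            tval <- if (is.na(v)) NA else if (diff(rngv) == 0) 0.5 else
              (v - rngv[1L]) / diff(rngv)
            fill <- if (is.na(v)) style$missing_color else
              continuous_colors(c(rngv, v), style)[3L]
            len <- if (is.na(tval)) 0 else
              if (layer$encode %in% c("both", "length")) tval else 1
            if (layer$encode == "color" && !is.na(v)) len <- 1
            if (!is.na(v))
              body <- c(body, svg_rect(x0, y0, max(len, 0.02) * wpx, hpx,
                                       fill),
                        paste0("<!-- bar tip=\"", xml_escape(tip),
                               "\" layer=\"", li, "\" -->"))
          }
        } else {                          # circular rings
          a0 <- nodes$angle[nd] - pi / max(layout$n_tips, 1L) * 0.9
          a1 <- nodes$angle[nd] + pi / max(layout$n_tips, 1L) * 0.9
          r0 <- (max_r + (li - 1) * ring_w * 1.1 + ring_w * 0.1) * sc
          if (layer$kind == "categorical_stacked") {
            if (length(pay) == 0L) next
            acc <- 0
            for (cname in names(pay)) {
              shown_c <- da$map[[cname]]
              body <- c(body, svg_ring_cell(
                cx, cy, r0 + acc * ring_w * sc,
                r0 + (acc + pay[[cname]]) * ring_w * sc,
                -a0, -a1, cols[[shown_c]]))
              acc <- acc + pay[[cname]]
            }
            body <- c(body, paste0("<!-- bar tip=\"", xml_escape(tip),
                                   "\" layer=\"", li, "\" -->"))
          } else {
            v <- pay
            if (!is.na(v)) {
              allv <- layer$payload
              rngv <- suppressWarnings(range(allv, na.rm = TRUE))
              tval <- if (diff(rngv) == 0) 0.5 else
                (v - rngv[1L]) / diff(rngv)
              fill <- continuous_colors(c(rngv, v), style)[3L]
              len <- if (layer$encode == "color") 1 else tval
              body <- c(body, svg_ring_cell(
                cx, cy, r0, r0 + max(len, 0.02) * ring_w * sc,
                -a0, -a1, fill),
                paste0("<!-- bar tip=\"", xml_escape(tip),
                       "\" layer=\"", li, "\" -->"))
            }
          }
        }
      }
    }
  }

  # legend blocks
  lx <- width - legend_w + 10
  lyy <- margin
  for (lg in legend) {
    body <- c(body, svg_text(lx, lyy, lg$title, size = 11))
    lyy <- lyy + 6
    for (k in seq_along(lg$labels)) {
      lyy <- lyy + 14
      body <- c(body, svg_rect(lx, lyy - 9, 10, 10, lg$colors[[k]]),
                svg_text(lx + 14, lyy, lg$labels[[k]], size = 9))
    }
    lyy <- lyy + 22
  }

  out <- c(paste0("<svg xmlns=\"http://www.w3.org/2000/svg\" width=\"",
                  width, "\" height=\"", height, "\" viewBox=\"0 0 ",
                  width, " ", height, "\">"),
           svg_rect(0, 0, width, height, "#ffffff"),
           body, "</svg>")
  writeLines(out, out_path)
  invisible(out_path)
}
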