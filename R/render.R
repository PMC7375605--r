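# Static rendering of an annotated lineage tree.
#
# SVG is the native target and is written directly as text so the output is
# byte-stable across runs; PNG and EPS are produced through the standard R
# graphics devices from the same layered layout.

# Layered layout: leaves get consecutive y slots in pre-order, internal
# nodes sit at the mean y of their children, x is the depth from the root.
#' @noRd
tree_layout <- function(tree) {
  ord <- preorder_ids(tree)
  leaves <- leaf_ids(tree)
  y <- stats::setNames(rep(NA_real_, length(ord)), ord)
  next_slot <- 0
  for (id in ord) {
    if (id %in% leaves) {
      next_slot <- next_slot + 1
      y[[id]] <- next_slot
    }
  }
  for (id in rev(ord)) {
    if (is.na(y[[id]]))
      y[[id]] <- mean(y[children_of(tree, id)])
  }
  depth <- stats::setNames(rep(0, length(ord)), ord)
  for (id in ord) {
    p <- parent_of(tree, id)
    if (!is.na(p)) depth[[id]] <- depth[[p]] + 1
  }
  data.frame(id = ord, x = depth[ord], y = y[ord],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @noRd
node_display_label <- function(n) {
  lab <- if (length(n$members) > 1L) paste(n$members, collapse = ",") else n$label
  if (!is.na(n$ec50)) lab <- sprintf("%s [EC50 %s]", lab, n$ec50)
  lab
}

#' @noRd
edge_display_label <- function(ann) {
  if (is.null(ann)) "" else sprintf("%d (%d)", ann$nt_count, ann$aa_count)
}

#' @noRd
render_svg <- function(tree, path) {
  lay <- tree_layout(tree)
  xs <- 140; ys <- 46; margin <- 60
  px <- function(x) margin + x * xs
  py <- function(y) margin + (y - 1) * ys
  w <- px(max(lay$x)) + 260
  h <- py(max(lay$y)) + margin
  ln <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
                  round(w), round(h)),
          '<g font-family="monospace" font-size="12">')
  coord <- function(id) lay[lay$id == id, c("x", "y")]
  for (k in seq_len(nrow(tree$edges))) {
    pid <- tree$edges$parent[[k]]; cid <- tree$edges$child[[k]]
    a <- coord(pid); b <- coord(cid)
    ln <- c(ln, sprintf('<line x1="%.1f" y1="%.1f" x2="%.1f" y2="%.1f" stroke="black"/>',
                        px(a$x), py(a$y), px(b$x), py(b$y)))
    lab <- edge_display_label(tree$annotations[[cid]])
    if (nzchar(lab))
      ln <- c(ln, sprintf('<text x="%.1f" y="%.1f" fill="darkred">%s</text>',
                          (px(a$x) + px(b$x)) / 2, (py(a$y) + py(b$y)) / 2 - 4, lab))
  }
  for (k in seq_len(nrow(lay))) {
    n <- tree$nodes[[lay$id[[k]]]]
    fill <- switch(n$kind, UCA = "gold", OBSERVED = "steelblue", BP = "grey")
    ln <- c(ln, sprintf('<circle cx="%.1f" cy="%.1f" r="6" fill="%s" stroke="black"/>',
                        px(lay$x[[k]]), py(lay$y[[k]]), fill),
            sprintf('<text x="%.1f" y="%.1f">%s</text>',
                    px(lay$x[[k]]) + 10, py(lay$y[[k]]) + 4,
                    xml_escape(node_display_label(n))))
  }
  ln <- c(ln, "</g>", "</svg>")
  writeLines(ln, path)
  invisible(path)
}

#' @noRd
xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' @noRd
plot_lineage_base <- function(tree) {
  lay <- tree_layout(tree)
  graphics::par(mar = c(1, 1, 1, 1))
  graphics::plot(NA, xlim = c(-0.2, max(lay$x) + 1.6),
                 ylim = c(max(lay$y) + 0.5, 0.5),
                 axes = FALSE, xlab = "", ylab = "")
  coord <- function(id) lay[lay$id == id, c("x", "y")]
  for (k in seq_len(nrow(tree$edges))) {
    a <- coord(tree$edges$parent[[k]]); b <- coord(tree$edges$child[[k]])
    graphics::segments(a$x, a$y, b$x, b$y)
    lab <- edge_display_label(tree$annotations[[tree$edges$child[[k]]]])
    if (nzchar(lab))
      graphics::text((a$x + b$x) / 2, (a$y + b$y) / 2, lab,
                     col = "darkred", cex = 0.7, pos = 3)
  }
  cols <- c(UCA = "gold", OBSERVED = "steelblue", BP = "grey")
  kinds <- vapply(tree$nodes[lay$id], `[[`, character(1), "kind")
  graphics::points(lay$x, lay$y, pch = 21, bg = cols[kinds], cex = 1.4)
  labs <- vapply(tree$nodes[lay$id], node_display_label, character(1))
  graphics::text(lay$x, lay$y, labs, pos = 4, cex = 0.7)
}

#' Render a lineage tree to an image file
#'
#' Draws the layered tree with `nt (aa)` mutation counts on every edge and
#' node labels showing member lists and any EC50 annotation. SVG output is
#' written directly (byte-stable); PNG and EPS use the R graphics devices.
#'
#' @param tree An annotated `lineage_tree`.
#' @param path Output file path.
#' @param format One of `"svg"`, `"png"`, `"eps"` (default: from the file
#'   extension).
#' @param dpi Raster resolution for PNG.
#' @return `path`, invisibly.
#' @export
render_tree <- function(tree, path,
                        format = tolower(tools::file_ext(path)), dpi = 150) {
  if (!(format %in% c("svg", "png", "eps")))
    fatal("unsupported render format '%s'; supported formats: svg, png, eps",
          format)
  if (format == "svg") return(render_svg(tree, path))
  lay <- tree_layout(tree)
  win <- c(max(lay$x) * 1.6 + 3, max(lay$y) * 0.45 + 1)
  if (format == "png") {
    grDevices::png(path, width = win[1], height = win[2], units = "in",
                   res = dpi, type = "cairo")
  } else {
    grDevices::postscript(path, width = win[1], height = win[2],
                          horizontal = FALSE, onefile = FALSE,
                          paper = "special")
  }
  on.exit(grDevices::dev.off(), add = TRUE)
  plot_lineage_base(tree)
  invisible(path)
}
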