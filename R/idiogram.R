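#' Idiogram drawing style
#'
#' Geometry and colors for idiogram rendering. All dimensions are in SVG
#' user units (pixels).
#'
#' @param px_per_rl Vertical pixels per unit of relative length (RL, % of
#'   the haploid complement).
#' @param chrom_width Total width of a chromosome glyph (two chromatids).
#' @param pair_spacing Horizontal distance between pair centres.
#' @param margin Outer margin.
#' @param sat_gap Gap between an arm end and its satellite glyph
#'   (the secondary constriction).
#' @param label_size Font size of the arm-ratio labels.
#' @param colors Named fill colors per marker class.
#' @return A list of class \code{"idiogram_style"}.
#' @export
idiogram_style <- function(px_per_rl = 22, chrom_width = 14,
                           pair_spacing = 34, margin = 30, sat_gap = 3,
                           label_size = 9,
                           colors = c(CPD_band = "#d62728",
                                      DAPI_band = "#1f4e9c",
                                      rDNA_45S = "#2ca02c")) {
  vals <- c(px_per_rl, chrom_width, pair_spacing, margin, sat_gap, label_size)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("idiogram style dimensions must be positive")
  structure(list(px_per_rl = px_per_rl, chrom_width = chrom_width,
                 pair_spacing = pair_spacing, margin = margin,
                 sat_gap = sat_gap, label_size = label_size, colors = colors),
            class = "idiogram_style")
}

# midpoints used for markers annotated by position class only
position_class_midpoints <- c(CEN = 0.02, PCEN = 0.10, PROX = 0.27,
                              INT = 0.62, TER = 0.93)

# shared geometry for the SVG writer and the base-graphics plot:
# chromatid rectangles, marker rectangles, satellite glyphs and labels,
# with y growing downwards and all pairs' centromeres aligned
idiogram_geometry <- function(k, markers = NULL, style = idiogram_style()) {
  stopifnot(inherits(k, "karyotype"))
  p <- k$pairs
  rl_short <- p$RL * p$mean_short / p$total_len
  rl_long <- p$RL * p$mean_long / p$total_len
  px <- style$px_per_rl
  um_to_px <- px * 100 / sum(p$total_len)   # µm -> px on the RL scale
  y_cen <- style$margin + max(rl_short) * px +
    (if (any(p$sat & p$sat_arm == "short"))
       max(p$sat_len[p$sat]) * um_to_px + style$sat_gap else 0)
  half_w <- style$chrom_width / 2 - 1
  x0 <- style$margin + (seq_len(nrow(p)) - 1) * style$pair_spacing

  chromatid_x <- function(i) c(x0[i], x0[i] + half_w + 2)
  rects <- list(); mrects <- list(); srects <- list(); labels <- list()
  for (i in seq_len(nrow(p))) {
    hs <- rl_short[i] * px
    hl <- rl_long[i] * px
    for (cx in chromatid_x(i)) {
      rects[[length(rects) + 1]] <- data.frame(
        pair_id = p$pair_id[i], arm = "S", x = cx, y = y_cen - hs - 0.5,
        w = half_w, h = hs)
      rects[[length(rects) + 1]] <- data.frame(
        pair_id = p$pair_id[i], arm = "L", x = cx, y = y_cen + 0.5,
        w = half_w, h = hl)
    }
    if (p$sat[i]) {
      sh <- p$sat_len[i] * um_to_px
      sy <- if (p$sat_arm[i] == "long")
        y_cen + 0.5 + hl + style$sat_gap
      else
        y_cen - hs - 0.5 - style$sat_gap - sh
      for (cx in chromatid_x(i))
        srects[[length(srects) + 1]] <- data.frame(
          pair_id = p$pair_id[i], x = cx, y = sy, w = half_w, h = sh)
    }
    labels[[i]] <- data.frame(
      pair_id = p$pair_id[i], x = x0[i] + half_w + 1,
      y = y_cen + 0.5 + max(rl_long) * px + 14 +
        (if (any(p$sat & p$sat_arm == "long"))
           max(p$sat_len[p$sat]) * um_to_px + style$sat_gap else 0),
      text = sprintf("%.2f", p$AR[i]))
  }
  if (!is.null(markers) && nrow(as.data.frame(markers))) {
    m <- as.data.frame(markers)
    for (r in seq_len(nrow(m))) {
      i <- match(m$pair_id[r], p$pair_id)
      if (is.na(i))
        stop("marker references pair ", m$pair_id[r],
             " absent from the karyotype")
      arm_um <- if (identical(m$arm[r], "S")) p$mean_short[i] else p$mean_long[i]
      frac <- if (!is.na(m$d_um[r])) rdna_di(m$d_um[r], arm_um) / 100
              else position_class_midpoints[[m$position_class[r]]]
      h <- max(m$band_len_um[r] * um_to_px, 1.5)
      centre <- if (is.na(m$arm[r])) {
        0  # centromere-spanning band
      } else if (m$arm[r] == "S") {
        -frac * rl_short[i] * px
      } else {
        frac * rl_long[i] * px
      }
      xs <- chromatid_x(i)
      if (m$homologs_present[r] == "one") xs <- xs[1]
      for (cx in xs)
        mrects[[length(mrects) + 1]] <- data.frame(
          pair_id = m$pair_id[r], class = m$marker_class[r],
          x = cx, y = y_cen + centre - h / 2, w = half_w, h = h)
    }
  }
  bind <- function(l) if (length(l)) do.call(rbind, l) else NULL
  list(
    arms = bind(rects), markers = bind(mrects), satellites = bind(srects),
    labels = bind(labels),
    width = style$margin * 2 + (nrow(p) - 1) * style$pair_spacing +
      style$chrom_width,
    height = max(vapply(labels, function(l) l$y, numeric(1))) +
      style$margin,
    y_cen = y_cen, style = style
  )
}

#' Render a karyotype idiogram as SVG
#'
#' Draws one two-chromatid glyph per homolog pair, to relative-length (RL)
#' scale with all centromeric constrictions aligned, the arm ratio printed
#' beneath each pair, satellites drawn distal to a secondary-constriction
#' gap, and fluorochrome bands / rDNA sites drawn at their fractional arm
#' positions in class colors (an rDNA site with a recorded distance d sits
#' at di% of its arm from the centromere; other markers sit at their
#' position-class midpoint). Markers present on one homolog are drawn on
#' one chromatid only.
#'
#' The output is deterministic for fixed inputs and style.
#'
#' @param karyotype A \code{karyotype} object.
#' @param markers Optional \code{cyto_markers} table.
#' @param style An \code{\link{idiogram_style}}.
#' @param file Optional path; when given the SVG is written there.
#' @return The SVG document as a single string (invisibly when writing).
#' @export
render_idiogram <- function(karyotype, markers = NULL,
                            style = idiogram_style(), file = NULL) {
  g <- idiogram_geometry(karyotype, markers, style)
  num <- function(x) sprintf("%.3f", x)
  rect <- function(r, cls, fill)
    sprintf('    <rect class="%s" x="%s" y="%s" width="%s" height="%s" fill="%s" stroke="#333" stroke-width="0.5"/>',
            cls, num(r$x), num(r$y), num(r$w), num(r$h), fill)
  lines <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%s" height="%s" viewBox="0 0 %s %s">',
    num(g$width), num(g$height), num(g$width), num(g$height)))
  for (pid in unique(g$arms$pair_id)) {
    lines <- c(lines, sprintf('  <g class="pair" id="pair-%d">', pid))
    a <- g$arms[g$arms$pair_id == pid, ]
    for (r in seq_len(nrow(a)))
      lines <- c(lines, rect(a[r, ], paste("arm", a$arm[r]), "#e8e8e8"))
    if (!is.null(g$satellites)) {
      s <- g$satellites[g$satellites$pair_id == pid, ]
      for (r in seq_len(nrow(s)))
        lines <- c(lines, rect(s[r, ], "satellite", "#e8e8e8"))
    }
    if (!is.null(g$markers)) {
      m <- g$markers[g$markers$pair_id == pid, ]
      for (r in seq_len(nrow(m)))
        lines <- c(lines, rect(m[r, ], paste("marker", m$class[r]),
                               g$style$colors[[m$class[r]]]))
    }
    lab <- g$labels[g$labels$pair_id == pid, ]
    lines <- c(lines, sprintf(
      '    <text class="ar-label" x="%s" y="%s" font-size="%s" text-anchor="middle">%s</text>',
      num(lab$x), num(lab$y), num(g$style$label_size), lab$text))
    lines <- c(lines, "  </g>")
  }
  lines <- c(lines, "</svg>")
  svg <- paste(lines, collapse = "\n")
  if (!is.null(file)) {
    writeLines(svg, file)
    return(invisible(svg))
  }
  svg
}

#' Plot a karyotype idiogram
#'
#' Base-graphics rendering of the same geometry as
#' \code{\link{render_idiogram}}.
#'
#' @param x A \code{karyotype} object.
#' @param markers Optional \code{cyto_markers} table.
#' @param style An \code{\link{idiogram_style}}.
#' @param ... Ignored.
#' @return \code{x}, invisibly.
#' @export
plot.karyotype <- function(x, markers = NULL, style = idiogram_style(), ...) {
  g <- idiogram_geometry(x, markers, style)
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, g$width), ylim = c(g$height, 0),
                        asp = 1)
  draw <- function(df, col) {
    if (is.null(df)) return(invisible())
    graphics::rect(df$x, df$y + df$h, df$x + df$w, df$y, col = col,
                   border = "#333333")
  }
  draw(g$arms, "#e8e8e8")
  draw(g$satellites, "#e8e8e8")
  if (!is.null(g$markers))
    graphics::rect(g$markers$x, g$markers$y + g$markers$h,
                   g$markers$x + g$markers$w, g$markers$y,
                   col = g$style$colors[g$markers$class], border = NA)
  graphics::text(g$labels$x, g$labels$y, g$labels$text, cex = 0.7)
  graphics::title(main = x$species)
  invisible(x)
}
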