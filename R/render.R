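#' Render a heat map to a PNG file
#'
#' Diverging blue (low) to red (high) colormap; values at or below
#' `scale[1]` map to the blue end, at or above `scale[2]` to the red end;
#' missing blocks are rendered neutral gray. A color scale bar with the
#' bounds is drawn above the map. Rendering never mutates the heat map.
#'
#' @param map a `junction_heatmap`.
#' @param scale numeric `c(low, high)`, finite, low < high.
#' @param file output PNG path.
#' @param px_per_block rendered pixels per block edge.
#' @return `file`, invisibly.
#' @export
render_heatmap <- function(map, scale = c(0.5, 1.5), file, px_per_block = 12) {
  stopifnot(inherits(map, "junction_heatmap"))
  if (length(scale) != 2L || !all(is.finite(scale)) || scale[1L] >= scale[2L])
    stop_bad_arg("`scale` must be finite c(low, high) with low < high")
  v <- map$values
  if (all(is.na(v))) stop_bad_arg("empty heat map")
  pal <- grDevices::colorRampPalette(
    c("#2166AC", "#67A9CF", "#F7F7F7", "#EF8A62", "#B2182B"))(256L)
  idx <- round(1 + 255 * (pmin(pmax(v, scale[1L]), scale[2L]) - scale[1L]) /
                 (scale[2L] - scale[1L]))
  colmat <- matrix(pal[idx], nrow(v), ncol(v))
  colmat[is.na(v)] <- "#BDBDBD"
  w <- max(300L, ncol(v) * px_per_block)
  h <- max(260L, nrow(v) * px_per_block + 60L)
  grDevices::png(file, width = w, height = h)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mar = c(0.5, 0.5, 3.5, 0.5))
  graphics::plot(NA, xlim = c(0, ncol(v)), ylim = c(nrow(v), 0),
                 asp = 1, axes = FALSE, xlab = "", ylab = "")
  graphics::rasterImage(grDevices::as.raster(colmat), 0, nrow(v), ncol(v), 0,
                        interpolate = FALSE)
  # scale bar on top
  nseg <- 100L
  xs <- seq(0, ncol(v), length.out = nseg + 1L)
  graphics::rect(xs[-(nseg + 1L)], -2.5, xs[-1L], -1,
                 col = pal[round(seq(1, 256, length.out = nseg))],
                 border = NA, xpd = NA)
  graphics::text(0, -3, sprintf("%.3g", scale[1L]), adj = c(0, 0), xpd = NA)
  graphics::text(ncol(v), -3, sprintf("%.3g", scale[2L]), adj = c(1, 0),
                 xpd = NA)
  graphics::title(main = sprintf("%s (%s)", map$channel, map$normalization),
                  line = 2.2)
  invisible(file)
}
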