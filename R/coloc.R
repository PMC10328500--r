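#' Masked Pearson colocalization between two channels
#'
#' Pearson correlation of two channels' intensities over the junction-mask
#' pixels — the conventional colocalization score for junctional proteins.
#' By default restricted to the mask (junctional signal is what matters;
#' whole-frame correlation is dominated by the junction/background contrast
#' itself); set `full_frame = TRUE` to use every pixel. No Costes
#' randomization or Manders coefficients: only Pearson is reported.
#'
#' @param image a [disc_image()].
#' @param mask a [build_mask()] result or logical matrix; ignored when
#'   `full_frame = TRUE`.
#' @param channel_a,channel_b channel names.
#' @param full_frame if TRUE, correlate over all pixels.
#' @return List of class `coloc_result` with `pearson_r` and `n_pixels`.
#' @examples
#' img <- disc_image(list(a = matrix(runif(100), 10), b = matrix(runif(100), 10)),
#'                   pixel_size_um = 0.2, reference = "a")
#' pearson_coloc(img, matrix(TRUE, 10, 10), "a", "b")
#' @export
pearson_coloc <- function(image, mask, channel_a, channel_b,
                          full_frame = FALSE) {
  stopifnot(inherits(image, "disc_image"))
  a <- get_channel(image, channel_a)
  b <- get_channel(image, channel_b)
  if (full_frame) {
    va <- as.vector(a); vb <- as.vector(b)
  } else {
    m <- if (inherits(mask, "junction_mask")) mask$mask else mask
    if (!is.logical(m) || !identical(dim(m), dim(image)))
      stop_bad_arg("mask shape does not match image")
    va <- a[m]; vb <- b[m]
  }
  if (length(va) < 2L)
    stop_bad_arg("need at least 2 masked pixels (got %d)", length(va))
  if (stats::var(va) == 0 || stats::var(vb) == 0)
    stop_bad_arg("correlation undefined: zero variance in a channel over the mask")
  r <- stats::cor(va, vb)
  # perfectly collinear channels report exactly +/-1 (guard against the
  # ~1e-16 rounding of the two-pass formula)
  if (abs(r) > 1 - 1e-14) r <- sign(r)
  structure(list(pearson_r = r, n_pixels = length(va)),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.4f over %d masked pixels\n",
              x$pearson_r, x$n_pixels))
  invisible(x)
}
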