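#' Parameters for the synthetic epithelium image generator
#'
#' Describes a two-compartment pseudo-epithelium: a Voronoi tessellation of
#' cells whose boundaries (cell-cell junctions) carry the fluorescent signal.
#' The posterior half of the field carries a known multiplicative change of
#' the signal channel on junctions, emulating a genetic manipulation driven
#' in one compartment while the anterior half serves as internal control.
#'
#' Defaults describe a 40 x 40 um field (200 px at 0.2 um/px) of ~150 cells
#' (apical cell diameter ~3 um, typical of columnar imaginal-disc epithelia),
#' junction intensity 100 a.u. over a 10 a.u. background, and 10% Gaussian
#' noise.
#'
#' @param image_size_px integer pair `c(nrow, ncol)` in pixels.
#' @param pixel_size_um pixel size, um/px.
#' @param n_cells number of Voronoi cells (>= 4 so both compartments contain
#'   junctions).
#' @param junction_width_px target junction thickness in pixels.
#' @param ref_level junctional intensity of the reference channel (a.u.).
#' @param signal_level junctional intensity of the signal channel in the
#'   anterior compartment (a.u.).
#' @param posterior_multiplier true fold-change of junctional signal in the
#'   posterior compartment (the ground-truth P/A ratio).
#' @param noise_sd_frac Gaussian noise SD as a fraction of the channel's
#'   junctional level; must be < 1.
#' @param background_level additive background (a.u.).
#' @param seed integer RNG seed; the generator is deterministic given it.
#' @return A validated list of class `synth_disc_params`.
#' @export
synth_disc_params <- function(image_size_px = c(200L, 200L),
                              pixel_size_um = 0.2,
                              n_cells = 150L,
                              junction_width_px = 2L,
                              ref_level = 100,
                              signal_level = 100,
                              posterior_multiplier = 1,
                              noise_sd_frac = 0.1,
                              background_level = 10,
                              seed = 1L) {
  if (length(image_size_px) != 2L || any(image_size_px < 8) ||
      any(image_size_px != floor(image_size_px)))
    stop_bad_arg("`image_size_px` must be two integers >= 8")
  if (!is_count(n_cells) || n_cells < 4)
    stop_bad_arg("`n_cells` must be an integer >= 4")
  if (!is_count(junction_width_px))
    stop_bad_arg("`junction_width_px` must be a positive integer")
  for (nm in c("pixel_size_um", "ref_level", "signal_level",
               "posterior_multiplier")) {
    v <- get(nm)
    if (!is_scalar_num(v) || v <= 0) stop_bad_arg("`%s` must be > 0", nm)
  }
  if (!is_scalar_num(noise_sd_frac) || noise_sd_frac < 0 || noise_sd_frac >= 1)
    stop_bad_arg("`noise_sd_frac` must lie in [0, 1)")
  if (!is_scalar_num(background_level) || background_level < 0)
    stop_bad_arg("`background_level` must be >= 0")
  structure(list(image_size_px = as.integer(image_size_px),
                 pixel_size_um = pixel_size_um, n_cells = as.integer(n_cells),
                 junction_width_px = as.integer(junction_width_px),
                 ref_level = ref_level, signal_level = signal_level,
                 posterior_multiplier = posterior_multiplier,
                 noise_sd_frac = noise_sd_frac,
                 background_level = background_level,
                 seed = as.integer(seed)),
            class = "synth_disc_params")
}

#' Generate a ground-truthed synthetic two-compartment disc image
#'
#' Seeds `n_cells` points uniformly in the field, applies one Lloyd
#' relaxation step (seeds moved to their Voronoi cell centroids) to avoid
#' sliver cells, labels each pixel by nearest seed, and takes as junction
#' skeleton the pixels whose 4-neighborhood crosses a cell boundary, dilated
#' to `junction_width_px`. The reference channel carries `ref_level` on
#' junction pixels; the signal channel carries `signal_level` on anterior
#' junctions and `signal_level * posterior_multiplier` on posterior
#' junctions; off-junction pixels carry `background_level`, so the
#' masked-pixel mean ratio equals the multiplier exactly in the noiseless
#' case. Additive Gaussian noise is truncated at zero (cameras report
#' nonnegative counts). The compartment boundary is a
#' straight vertical (or horizontal) line through the field center.
#'
#' @param params a [synth_disc_params()].
#' @param posterior_axis side of the field that is posterior:
#'   `"right"` (default), `"left"`, `"up"` or `"down"`.
#' @return An object of class `synth_disc`: list with `image` (a
#'   [disc_image()] with channels `ecad` and `signal`), `center_px` (0-based
#'   `c(row, col)` of the field center), `posterior_axis`, `compartment_map`
#'   (integer matrix, 1 = posterior, 0 = anterior), and `truth` (list:
#'   `pa_ratio`, the logical `junction_mask` before noise, and the params).
#' @examples
#' d <- generate_disc(synth_disc_params(image_size_px = c(64, 64),
#'                                      n_cells = 16, noise_sd_frac = 0,
#'                                      posterior_multiplier = 1.5, seed = 7))
#' d$truth$pa_ratio
#' @export
generate_disc <- function(params,
                          posterior_axis = c("right", "left", "up", "down")) {
  stopifnot(inherits(params, "synth_disc_params"))
  posterior_axis <- match.arg(posterior_axis)
  nr <- params$image_size_px[1L]; nc <- params$image_size_px[2L]

  with_seed(params$seed, {
    lab <- voronoi_labels(nr, nc, params$n_cells)
    junction <- boundary_pixels(lab)
    extra <- ceiling(max(0L, params$junction_width_px - 2L) / 2)
    if (extra > 0L) junction <- dilate_square(junction, extra)

    # 0-based field center; compartment boundary line passes through it
    center <- c(floor(nr / 2), floor(nc / 2))
    rows0 <- row(lab) - 1L; cols0 <- col(lab) - 1L
    post <- switch(posterior_axis,
      right = cols0 >= center[2L],
      left  = cols0 <  center[2L],
      down  = rows0 >= center[1L],
      up    = rows0 <  center[1L])
    compartment_map <- matrix(as.integer(post), nr, nc)

    # junction pixels carry the junctional level (background included in it);
    # off-junction pixels carry background only. This keeps the ground truth
    # exact: the masked-pixel mean ratio equals the posterior multiplier.
    m <- params$posterior_multiplier
    ref <- ifelse(junction, params$ref_level, params$background_level)
    sig <- ifelse(junction, params$signal_level * ifelse(post, m, 1),
                  params$background_level)
    if (params$noise_sd_frac > 0) {
      ref <- ref + stats::rnorm(nr * nc,
                                sd = params$noise_sd_frac * params$ref_level)
      sig <- sig + stats::rnorm(nr * nc,
                                sd = params$noise_sd_frac * params$signal_level)
    }
    ref <- matrix(pmax(ref, 0), nr, nc)
    sig <- matrix(pmax(sig, 0), nr, nc)

    img <- disc_image(list(ecad = ref, signal = sig),
                      pixel_size_um = params$pixel_size_um,
                      reference = "ecad")
    structure(list(image = img, center_px = as.integer(center),
                   posterior_axis = posterior_axis,
                   compartment_map = compartment_map,
                   truth = list(pa_ratio = m, junction_mask = junction,
                                params = params)),
              class = "synth_disc")
  })
}

#' @export
print.synth_disc <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf(
    "<synth_disc> %d x %d px, posterior=%s, truth P/A = %.4g\n",
    d[1], d[2], x$posterior_axis, x$truth$pa_ratio))
  invisible(x)
}

# Nearest-seed labels after one Lloyd relaxation. Seeds giving an empty cell
# (degenerate tessellation) are jittered and the labeling repeated.
voronoi_labels <- function(nr, nc, n_cells, max_tries = 10L) {
  sx <- stats::runif(n_cells, 0, nc)
  sy <- stats::runif(n_cells, 0, nr)
  lab <- nearest_seed(nr, nc, sx, sy)
  # Lloyd step: move seeds to cell centroids
  px <- as.vector(col(lab)) - 0.5; py <- as.vector(row(lab)) - 0.5
  sx <- tapply(px, factor(as.vector(lab), levels = seq_len(n_cells)), mean)
  sy <- tapply(py, factor(as.vector(lab), levels = seq_len(n_cells)), mean)
  for (try in seq_len(max_tries)) {
    bad <- !is.finite(sx) | !is.finite(sy)
    if (any(bad)) {
      sx[bad] <- stats::runif(sum(bad), 0, nc)
      sy[bad] <- stats::runif(sum(bad), 0, nr)
    }
    lab <- nearest_seed(nr, nc, sx, sy)
    present <- tabulate(lab, n_cells) > 0L
    if (all(present)) return(lab)
    message("degenerate tessellation: ", sum(!present),
            " empty cell(s); perturbing seeds (attempt ", try, ")")
    sx <- sx + stats::rnorm(n_cells, sd = nc / 50)
    sy <- sy + stats::rnorm(n_cells, sd = nr / 50)
    sx[!present] <- stats::runif(sum(!present), 0, nc)
    sy[!present] <- stats::runif(sum(!present), 0, nr)
  }
  lab  # labeling is still valid even if some cells stayed empty
}

nearest_seed <- function(nr, nc, sx, sy) {
  px <- rep(seq_len(nc) - 0.5, each = nr)
  py <- rep(seq_len(nr) - 0.5, times = nc)
  best_d <- rep(Inf, nr * nc); best <- integer(nr * nc)
  for (j in seq_along(sx)) {
    d <- (px - sx[j])^2 + (py - sy[j])^2
    upd <- d < best_d
    best_d[upd] <- d[upd]; best[upd] <- j
  }
  matrix(best, nr, nc)
}

# Pixels whose 4-neighborhood contains a different cell label (~2 px wide).
boundary_pixels <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  b <- matrix(FALSE, nr, nc)
  b[-nr, ] <- b[-nr, ] | lab[-nr, ] != lab[-1L, ]
  b[-1L, ] <- b[-1L, ] | lab[-1L, ] != lab[-nr, ]
  b[, -nc] <- b[, -nc] | lab[, -nc] != lab[, -1L]
  b[, -1L] <- b[, -1L] | lab[, -1L] != lab[, -nc]
  b
}

# Binary dilation with a (2r+1) x (2r+1) square structuring element.
dilate_square <- function(mask, r) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- mask
  for (dr in -r:r) for (dc in -r:r) {
    if (dr == 0L && dc == 0L) next
    ri <- seq_len(nr) + dr; ci <- seq_len(nc) + dc
    ok_r <- ri >= 1L & ri <= nr; ok_c <- ci >= 1L & ci <= nc
    out[ok_r, ok_c] <- out[ok_r, ok_c] | mask[ri[ok_r], ci[ok_c]]
  }
  out
}
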