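#' Multi-channel apical-projection image
#'
#' Container for a registered multi-channel 2D image of the apical surface of
#' an epithelium, together with its pixel size and the biological role of each
#' channel. All downstream quantification (masking, block heat maps,
#' colocalization) operates on this container. Exactly one channel must carry
#' the role `"reference"` (typically E-cadherin, marking adherens junctions);
#' any number of channels may be `"signal"` (e.g. myosin light chain, Ajuba,
#' beta-heavy spectrin fusions), and an optional channel may be a compartment
#' `"marker"`.
#'
#' @param channels named list of numeric matrices (arbitrary units,
#'   nonnegative), all with identical dimensions. Names are channel names.
#' @param pixel_size_um positive scalar, physical pixel size in micrometers.
#' @param reference name of the reference channel.
#' @param signals character vector of signal channel names (default: all
#'   channels other than reference and marker).
#' @param marker optional name of a compartment-marker channel.
#'
#' @return An object of class `disc_image`: a list with elements `channels`,
#'   `pixel_size_um` and `roles`.
#' @examples
#' img <- disc_image(
#'   channels = list(ecad = matrix(1, 8, 8), sqh = matrix(2, 8, 8)),
#'   pixel_size_um = 0.2, reference = "ecad"
#' )
#' dim(img)
#' @export
disc_image <- function(channels, pixel_size_um, reference,
                       signals = NULL, marker = NULL) {
  if (!is.list(channels) || length(channels) < 1L ||
      is.null(names(channels)) || any(!nzchar(names(channels))))
    stop_bad_arg("`channels` must be a non-empty named list of matrices")
  dims <- lapply(channels, dim)
  if (any(vapply(channels, function(m) !is.matrix(m) || !is.numeric(m), TRUE)))
    stop_bad_arg("all channels must be numeric matrices")
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop_bad_arg("all channels must share identical dimensions")
  if (!is_scalar_num(pixel_size_um) || pixel_size_um <= 0)
    stop_bad_arg("`pixel_size_um` must be a positive scalar")
  if (!reference %in% names(channels))
    stop_bad_arg("reference channel '%s' not found", reference)
  if (!is.null(marker) && !marker %in% names(channels))
    stop_bad_arg("marker channel '%s' not found", marker)
  if (is.null(signals))
    signals <- setdiff(names(channels), c(reference, marker))
  if (!all(signals %in% names(channels)))
    stop_bad_arg("unknown signal channel(s): %s",
                 paste(setdiff(signals, names(channels)), collapse = ", "))
  structure(
    list(channels = channels,
         pixel_size_um = pixel_size_um,
         roles = list(reference = reference, signals = signals,
                      marker = marker)),
    class = "disc_image")
}

#' @export
dim.disc_image <- function(x) dim(x$channels[[1L]])

#' @export
print.disc_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<disc_image> %d x %d px (%.4g um/px)\n", d[1], d[2],
              x$pixel_size_um))
  for (nm in names(x$channels)) {
    role <- if (nm == x$roles$reference) "reference"
      else if (!is.null(x$roles$marker) && nm == x$roles$marker) "marker"
      else "signal"
    cat(sprintf("  %-12s [%s]\n", nm, role))
  }
  invisible(x)
}

ref_channel <- function(image) image$channels[[image$roles$reference]]

get_channel <- function(image, channel) {
  if (!channel %in% names(image$channels))
    stop_bad_arg("unknown channel '%s' (have: %s)", channel,
                 paste(names(image$channels), collapse = ", "))
  image$channels[[channel]]
}

#' Build the junction mask from the reference channel
#'
#' Thresholds the reference (E-cadherin) channel to retain only junctional
#' pixels; every intensity quantification downstream is restricted to this
#' mask. Three thresholding rules are offered because published pipelines of
#' this kind rarely state theirs: Otsu's method (default; parameter-free,
#' suited to bimodal junction/background images), a percentile threshold, and
#' a fixed intensity threshold. Connected components smaller than
#' `min_object_px` pixels are removed to suppress noise speckle.
#'
#' The analogous mask in thin confocal z-stacks is three-dimensional; this
#' package operates on 2D apical projections, so the mask is 2D.
#'
#' @param image a [disc_image()].
#' @param method `"otsu"`, `"percentile"` or `"fixed"`.
#' @param param for `"percentile"`, a percentile in (0, 100); for `"fixed"`,
#'   a threshold value >= 0; ignored for `"otsu"`.
#' @param min_object_px connected components (4-connectivity) with fewer
#'   pixels than this are dropped. Set to 0 or 1 to disable.
#'
#' @return An object of class `junction_mask`: list with `mask` (logical
#'   matrix, TRUE = junctional), `method`, `threshold_value`,
#'   `min_object_px`.
#' @examples
#' img <- disc_image(list(ecad = matrix(c(10, 100), 10, 10)),
#'                   pixel_size_um = 0.2, reference = "ecad")
#' m <- build_mask(img, min_object_px = 0)
#' sum(m$mask)
#' @export
build_mask <- function(image, method = c("otsu", "percentile", "fixed"),
                       param = NULL, min_object_px = 5L) {
  method <- match.arg(method)
  stopifnot(inherits(image, "disc_image"))
  ref <- ref_channel(image)
  if (stats::var(as.vector(ref)) == 0)
    stop_bad_arg("mask undefined: reference channel has zero variance")
  thr <- switch(method,
    otsu = otsu_threshold(ref),
    percentile = {
      if (!is_scalar_num(param) || param <= 0 || param >= 100)
        stop_bad_arg("percentile `param` must lie in (0, 100)")
      as.numeric(stats::quantile(ref, param / 100, names = FALSE))
    },
    fixed = {
      if (!is_scalar_num(param) || param < 0)
        stop_bad_arg("fixed `param` must be >= 0")
      param
    })
  mask <- if (method == "fixed" && thr == 0) ref >= thr else ref > thr
  if (min_object_px > 1L && any(mask))
    mask <- remove_small_objects(mask, min_object_px)
  if (!any(mask))
    stop_bad_arg("empty junction mask (method=%s, threshold=%.6g)", method, thr)
  structure(list(mask = mask, method = method, threshold_value = thr,
                 min_object_px = as.integer(min_object_px)),
            class = "junction_mask")
}

#' @export
print.junction_mask <- function(x, ...) {
  cat(sprintf("<junction_mask> %d/%d px (method=%s, threshold=%.6g)\n",
              sum(x$mask), length(x$mask), x$method, x$threshold_value))
  invisible(x)
}

# Otsu's threshold on a 256-bin histogram: maximizes between-class variance.
otsu_threshold <- function(x) {
  x <- as.vector(x)
  rng <- range(x)
  nbins <- 256L
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(x, br, all.inside = TRUE), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (br[-1L] + br[-(nbins + 1L)]) / 2
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  denom <- omega * (1 - omega)
  sigma_b2 <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  k <- which.max(sigma_b2)
  br[k + 1L]  # upper edge of the chosen bin; mask = pixels strictly above
}

# Two-pass union-find connected-component labeling, 4-connectivity.
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  nxt <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j]) next
    up <- if (i > 1L) labels[i - 1L, j] else 0L
    lf <- if (j > 1L) labels[i, j - 1L] else 0L
    if (up == 0L && lf == 0L) {
      nxt <- nxt + 1L; parent[nxt] <- nxt; labels[i, j] <- nxt
    } else if (up != 0L && lf != 0L) {
      ru <- find(up); rl <- find(lf)
      labels[i, j] <- ru
      if (ru != rl) parent[rl] <- ru
    } else {
      labels[i, j] <- max(up, lf)
    }
  }
  if (nxt == 0L) return(labels)
  roots <- vapply(seq_len(nxt), find, 0L)
  compact <- match(roots, unique(roots))
  idx <- labels != 0L
  labels[idx] <- compact[labels[idx]]
  labels
}

remove_small_objects <- function(mask, min_px) {
  lab <- label_components(mask)
  if (max(lab) == 0L) return(mask)
  sizes <- tabulate(lab[lab != 0L])
  keep <- which(sizes >= min_px)
  lab %in% keep & mask
}

#' Extract masked pixel values from one channel
#'
#' @param image a [disc_image()].
#' @param mask a [build_mask()] result (or logical matrix of matching shape).
#' @param channel channel name.
#' @return Numeric vector of the channel's values at mask-TRUE pixels (length
#'   equals the mask cardinality; zero-length result carries attribute
#'   `empty = TRUE`).
#' @export
apply_mask <- function(image, mask, channel) {
  stopifnot(inherits(image, "disc_image"))
  m <- if (inherits(mask, "junction_mask")) mask$mask else mask
  if (!is.logical(m) || !identical(dim(m), dim(image)))
    stop_bad_arg("mask shape does not match image")
  ch <- get_channel(image, channel)
  out <- ch[m]
  if (length(out) == 0L) attr(out, "empty") <- TRUE
  out
}
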