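#' Per-disc annotation: anatomical center and posterior side
#'
#' The disc center (the intersection of the anterior/posterior and
#' dorsal/ventral boundaries in a wing imaginal disc) is picked manually per
#' image and anchors the block grid; automatic center detection is out of
#' scope. Pixel coordinates are 0-based, row-major, origin top-left.
#'
#' @param center_px integer pair `c(row, col)`, 0-based pixel coordinates of
#'   the anatomical center.
#' @param posterior_side which side of the center line is the posterior
#'   compartment: `"right"`, `"left"`, `"up"` or `"down"`.
#' @param block_size_um block edge length in micrometers (default 3).
#' @return A list of class `disc_annotation`.
#' @export
disc_annotation <- function(center_px,
                            posterior_side = c("right", "left", "up", "down"),
                            block_size_um = 3.0) {
  posterior_side <- match.arg(posterior_side)
  if (length(center_px) != 2L || any(center_px < 0) ||
      any(center_px != floor(center_px)))
    stop_bad_arg("`center_px` must be two nonnegative integers (row, col)")
  if (!is_scalar_num(block_size_um) || block_size_um <= 0)
    stop_bad_arg("`block_size_um` must be > 0")
  structure(list(center_px = as.integer(center_px),
                 posterior_side = posterior_side,
                 block_size_um = block_size_um),
            class = "disc_annotation")
}

new_heatmap <- function(values, counts, center_index, block_size_um,
                        normalization, row_edges = NULL, col_edges = NULL,
                        channel = NA_character_) {
  stopifnot(identical(dim(values), dim(counts)))
  structure(list(values = values, counts = counts,
                 center_index = as.integer(center_index),
                 block_size_um = block_size_um,
                 normalization = normalization,
                 row_edges = row_edges, col_edges = col_edges,
                 channel = channel),
            class = "junction_heatmap")
}

#' @export
print.junction_heatmap <- function(x, ...) {
  cat(sprintf(
    "<junction_heatmap> %d x %d blocks of %.3g um (center block [%d, %d], %s)\n",
    nrow(x$values), ncol(x$values), x$block_size_um,
    x$center_index[1], x$center_index[2], x$normalization))
  cat(sprintf("  %d/%d blocks non-missing\n",
              sum(!is.na(x$values)), length(x$values)))
  invisible(x)
}

# Block edges along one axis: positions floor(center + k * block_px) for
# integer k, keeping only blocks fully inside [0, extent). The center pixel
# coordinate sits on a block corner, so the four center-adjacent blocks are
# symmetric about it; k = -1 is the block up/left of the anchor.
block_edges <- function(center, block_px, extent) {
  k_lo <- -ceiling(center / block_px) - 1L
  k_hi <- ceiling((extent - center) / block_px) + 1L
  ks <- k_lo:k_hi
  e <- floor(center + ks * block_px)
  keep <- which(e >= 0 & c(e[-1L], Inf) <= extent)
  keep <- keep[keep < length(ks)]          # need both edges
  if (length(keep) == 0L)
    stop_bad_arg("no complete block fits inside the image")
  list(edges = e[keep[1L]:(keep[length(keep)] + 1L)],
       ks = ks[keep])
}

#' Block-averaged intensity heat map of one channel
#'
#' Splits the image into square blocks of `block_size_um` per side, anchored
#' so that the annotated disc center lies on a block corner, and records per
#' block the mean intensity of `channel` over the junction-mask pixels inside
#' it. Blocks containing no masked pixels are missing (`NA`), not zero —
#' zeros would bias compartment means. Blocks only partially covered by the
#' image are dropped, not rescaled. `counts` records masked pixels per block.
#'
#' @param image a [disc_image()].
#' @param mask a [build_mask()] result (or logical matrix).
#' @param annotation a [disc_annotation()].
#' @param channel channel name to quantify.
#' @return A `junction_heatmap`: `values` and `counts` matrices,
#'   `center_index` (1-based matrix index of the block up-and-left of the
#'   center anchor), `block_size_um`, block `row_edges`/`col_edges`
#'   (0-based pixel positions), `normalization = "none"`.
#' @export
block_quantify <- function(image, mask, annotation, channel) {
  stopifnot(inherits(image, "disc_image"),
            inherits(annotation, "disc_annotation"))
  m <- if (inherits(mask, "junction_mask")) mask$mask else mask
  if (!is.logical(m) || !identical(dim(m), dim(image)))
    stop_bad_arg("mask shape does not match image")
  if (!any(m)) stop_bad_arg("mask is empty")
  d <- dim(image)
  ctr <- annotation$center_px
  if (ctr[1L] >= d[1L] || ctr[2L] >= d[2L])
    stop_bad_arg("center_px (%d, %d) outside image bounds", ctr[1], ctr[2])
  block_px <- annotation$block_size_um / image$pixel_size_um
  if (block_px < 1)
    stop_bad_arg("block size (%.3g px) smaller than one pixel", block_px)

  re <- block_edges(ctr[1L], block_px, d[1L])
  ce <- block_edges(ctr[2L], block_px, d[2L])
  nbr <- length(re$ks); nbc <- length(ce$ks)
  if (!(-1L %in% re$ks) || !(-1L %in% ce$ks))
    stop_bad_arg("center-adjacent blocks fall outside the image")

  ch <- get_channel(image, channel)
  idx <- which(m)
  r0 <- (idx - 1L) %% d[1L]                 # 0-based row
  c0 <- (idx - 1L) %/% d[1L]                # 0-based col
  br <- findInterval(r0, re$edges)
  bc <- findInterval(c0, ce$edges)
  ok <- br >= 1L & br <= nbr & bc >= 1L & bc <= nbc &
    r0 < re$edges[nbr + 1L] & c0 < ce$edges[nbc + 1L]
  bi <- (bc[ok] - 1L) * nbr + br[ok]
  counts <- matrix(tabulate(bi, nbr * nbc), nbr, nbc)
  sums <- numeric(nbr * nbc)
  if (length(bi)) {
    agg <- rowsum(ch[idx[ok]], bi)
    sums[as.integer(rownames(agg))] <- agg[, 1L]
  }
  values <- matrix(ifelse(counts > 0L, sums / pmax(counts, 1L), NA_real_),
                   nbr, nbc)
  new_heatmap(values, counts,
              center_index = c(match(-1L, re$ks), match(-1L, ce$ks)),
              block_size_um = annotation$block_size_um,
              normalization = "none",
              row_edges = re$edges, col_edges = ce$edges,
              channel = channel)
}

congruent_grids <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    identical(a$center_index, b$center_index) &&
    isTRUE(all.equal(a$block_size_um, b$block_size_um))
}

#' Normalize a signal heat map
#'
#' Two modes mirroring the two standard displays of junctional intensity:
#' `"ratio_to_reference"` divides signal and reference maps each by its own
#' mean over non-missing blocks, then takes the elementwise signal/reference
#' ratio (so the result is invariant to rescaling either channel);
#' `"self_mean"` divides the signal map by its own mean only, so the mean of
#' non-missing output blocks is exactly 1. Missing blocks propagate; blocks
#' where the reference is zero become missing (reported via a message).
#'
#' @param hm_signal signal-channel `junction_heatmap` (normalization
#'   `"none"`).
#' @param hm_reference reference-channel heat map on the identical grid;
#'   required for mode `"ratio_to_reference"`.
#' @param mode `"ratio_to_reference"` (default) or `"self_mean"`.
#' @return A `junction_heatmap` with the chosen `normalization`.
#' @export
normalize_heatmap <- function(hm_signal, hm_reference = NULL,
                              mode = c("ratio_to_reference", "self_mean")) {
  mode <- match.arg(mode)
  stopifnot(inherits(hm_signal, "junction_heatmap"))
  s <- hm_signal$values
  s_norm <- s / mean(s, na.rm = TRUE)
  if (mode == "self_mean") {
    out <- hm_signal
    out$values <- s_norm
    out$normalization <- "self_mean"
    return(out)
  }
  if (is.null(hm_reference))
    stop_bad_arg("mode 'ratio_to_reference' needs `hm_reference`")
  stopifnot(inherits(hm_reference, "junction_heatmap"))
  if (!congruent_grids(hm_signal, hm_reference))
    stop_bad_arg("signal and reference heat maps are not on the same grid")
  r <- hm_reference$values
  zero_ref <- which(!is.na(r) & r == 0)
  if (length(zero_ref)) {
    message(length(zero_ref), " block(s) with zero reference set to missing")
    r[zero_ref] <- NA_real_
  }
  r_norm <- r / mean(r, na.rm = TRUE)
  out <- hm_signal
  out$values <- s_norm / r_norm
  out$counts <- pmin(hm_signal$counts, hm_reference$counts)
  out$normalization <- "ratio_to_reference"
  out
}

#' Average heat maps from several discs
#'
#' Aligns maps on their center block, pads smaller maps with missing values
#' to the largest extent on each side of the center, and averages per block
#' over the discs contributing a non-missing value there — but only where at
#' least `min_count` discs contribute; other blocks are missing. The
#' returned `counts` matrix holds contributing discs per block.
#'
#' @param maps list of `junction_heatmap`s sharing block size and
#'   normalization mode.
#' @param min_count minimum discs per block (default 3).
#' @return A `junction_heatmap` of the union extent.
#' @export
average_discs <- function(maps, min_count = 3L) {
  if (!is.list(maps) || length(maps) == 0L)
    stop_bad_arg("`maps` must be a non-empty list of heat maps")
  stopifnot(all(vapply(maps, inherits, TRUE, "junction_heatmap")))
  if (!is_count(min_count))
    stop_bad_arg("`min_count` must be a positive integer")
  bs <- vapply(maps, `[[`, 0, "block_size_um")
  if (max(bs) - min(bs) > 1e-12)
    stop_bad_arg("heat maps have inconsistent block sizes")
  norm <- unique(vapply(maps, `[[`, "", "normalization"))
  if (length(norm) != 1L)
    stop_bad_arg("heat maps have inconsistent normalization modes: %s",
                 paste(norm, collapse = ", "))
  above <- vapply(maps, function(m) m$center_index[1L] - 1L, 0L)
  below <- vapply(maps, function(m) nrow(m$values) - m$center_index[1L], 0L)
  left  <- vapply(maps, function(m) m$center_index[2L] - 1L, 0L)
  right <- vapply(maps, function(m) ncol(m$values) - m$center_index[2L], 0L)
  # center block itself is in neither the "above" nor "below" count
  nr <- max(above) + max(below) + 1L
  nc <- max(left) + max(right) + 1L
  ctr <- c(max(above), max(left)) + 1L
  acc <- array(NA_real_, c(nr, nc, length(maps)))
  for (i in seq_along(maps)) {
    v <- maps[[i]]$values
    ro <- max(above) - above[i]
    co <- max(left) - left[i]
    acc[ro + seq_len(nrow(v)), co + seq_len(ncol(v)), i] <- v
  }
  n <- apply(acc, c(1, 2), function(z) sum(!is.na(z)))
  mu <- apply(acc, c(1, 2), function(z) mean(z, na.rm = TRUE))
  mu[n < min_count] <- NA_real_
  mu[is.nan(mu)] <- NA_real_
  new_heatmap(mu, n, center_index = ctr, block_size_um = maps[[1L]]$block_size_um,
              normalization = norm,
              channel = maps[[1L]]$channel)
}

#' Assign heat-map blocks to anterior / posterior compartments
#'
#' With a per-pixel compartment map (e.g. derived from an RFP marker
#' channel), each block is labeled by the majority compartment of its pixels
#' (restricted to `mask` if given); ties and empty blocks are excluded.
#' Without one, the geometric rule applies: the compartment boundary is the
#' straight line through the annotated center perpendicular to the
#' anterior-posterior axis; blocks entirely on the posterior side are
#' posterior, blocks entirely on the other side anterior, and a block the
#' line passes through (possible only when the center does not sit on a
#' block corner, e.g. in hand-built grids) is excluded. When the grid comes
#' from [block_quantify()] the center lies on a block corner and no block is
#' excluded.
#'
#' @param map a `junction_heatmap` carrying block edges (from
#'   [block_quantify()] or [make_heatmap()]).
#' @param annotation the [disc_annotation()] used to build the map.
#' @param compartment_map optional per-pixel matrix (1/TRUE = posterior).
#' @param mask optional logical matrix restricting the majority vote to
#'   masked pixels.
#' @return An object of class `compartment_split`: list with `labels`
#'   (character matrix `"anterior"`/`"posterior"`/`"excluded"` congruent with
#'   `map$values`).
#' @export
split_compartments <- function(map, annotation, compartment_map = NULL,
                               mask = NULL) {
  stopifnot(inherits(map, "junction_heatmap"),
            inherits(annotation, "disc_annotation"))
  if (is.null(map$row_edges) || is.null(map$col_edges))
    stop_bad_arg("heat map carries no block edges (averaged map?)")
  nbr <- nrow(map$values); nbc <- ncol(map$values)
  labels <- matrix("excluded", nbr, nbc)
  if (!is.null(compartment_map)) {
    post <- matrix(as.logical(compartment_map), nrow(compartment_map),
                   ncol(compartment_map))
    keep <- if (is.null(mask)) matrix(TRUE, nrow(post), ncol(post)) else {
      if (inherits(mask, "junction_mask")) mask$mask else mask
    }
    for (i in seq_len(nbr)) for (j in seq_len(nbc)) {
      rr <- (map$row_edges[i] + 1L):map$row_edges[i + 1L]
      cc <- (map$col_edges[j] + 1L):map$col_edges[j + 1L]
      sel <- keep[rr, cc]
      tot <- sum(sel)
      if (tot == 0L) next
      frac <- sum(post[rr, cc][sel]) / tot
      if (frac > 0.5) labels[i, j] <- "posterior"
      else if (frac < 0.5) labels[i, j] <- "anterior"
    }
  } else {
    side <- annotation$posterior_side
    along_cols <- side %in% c("left", "right")
    edges <- if (along_cols) map$col_edges else map$row_edges
    line <- annotation$center_px[if (along_cols) 2L else 1L]
    n <- length(edges) - 1L
    lab1 <- character(n)
    for (b in seq_len(n)) {
      lo <- edges[b]; hi <- edges[b + 1L]
      lab1[b] <- if (lo >= line) {
        if (side %in% c("right", "down")) "posterior" else "anterior"
      } else if (hi <= line) {
        if (side %in% c("right", "down")) "anterior" else "posterior"
      } else "excluded"
    }
    labels <- if (along_cols) matrix(lab1, nbr, nbc, byrow = TRUE)
              else matrix(lab1, nbr, nbc)
  }
  structure(list(labels = labels), class = "compartment_split")
}

#' Posterior / anterior intensity ratio of a heat map
#'
#' The study's core readout: mean of non-missing posterior blocks divided by
#' mean of non-missing anterior blocks. Computed per disc by default;
#' summarize across discs downstream (the averaged heat map is for display).
#'
#' @param map a `junction_heatmap`.
#' @param split a [split_compartments()] result congruent with `map`.
#' @return List of class `pa_ratio` with `value`, `n_posterior_blocks`,
#'   `n_anterior_blocks`.
#' @export
pa_ratio <- function(map, split) {
  stopifnot(inherits(map, "junction_heatmap"),
            inherits(split, "compartment_split"))
  if (!identical(dim(map$values), dim(split$labels)))
    stop_bad_arg("split labels not congruent with heat map")
  post <- map$values[split$labels == "posterior"]
  ant <- map$values[split$labels == "anterior"]
  post <- post[!is.na(post)]; ant <- ant[!is.na(ant)]
  if (length(post) == 0L) stop_bad_arg("posterior compartment is empty")
  if (length(ant) == 0L) stop_bad_arg("anterior compartment is empty")
  structure(list(value = mean(post) / mean(ant),
                 n_posterior_blocks = length(post),
                 n_anterior_blocks = length(ant)),
            class = "pa_ratio")
}

#' @export
print.pa_ratio <- function(x, ...) {
  cat(sprintf("P/A ratio = %.4f (posterior n=%d, anterior n=%d blocks)\n",
              x$value, x$n_posterior_blocks, x$n_anterior_blocks))
  invisible(x)
}

#' Construct a heat map by hand
#'
#' Mainly for tests and small worked examples: wraps a value matrix as a
#' `junction_heatmap` with uniform block edges.
#'
#' @param values numeric matrix (NA = missing).
#' @param center_index 1-based `c(row, col)` of the center block.
#' @param block_size_um block size (um).
#' @param block_px block size in pixels (used to lay out edges from 0).
#' @param normalization normalization tag.
#' @param counts optional counts matrix (default 1 where non-missing).
#' @return A `junction_heatmap`.
#' @export
make_heatmap <- function(values, center_index = c(1L, 1L), block_size_um = 3,
                         block_px = 1L, normalization = "none",
                         counts = NULL) {
  if (is.null(counts)) counts <- matrix(as.integer(!is.na(values)),
                                        nrow(values), ncol(values))
  new_heatmap(values, counts, center_index, block_size_um, normalization,
              row_edges = seq(0L, by = block_px, length.out = nrow(values) + 1L),
              col_edges = seq(0L, by = block_px, length.out = ncol(values) + 1L))
}
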