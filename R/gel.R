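#' Densitometry profile of one gel lane pair
#'
#' A 1D intensity profile along a supernatant/pellet lane pair from a
#' co-sedimentation assay: the supernatant band reports free protein, the
#' pellet band reports F-actin-bound protein. Gel image processing (lane
#' finding, 2D background) is out of scope; the input is the extracted
#' profile.
#'
#' @param position_px increasing positions along the profile.
#' @param intensity nonnegative intensities (a.u.), same length.
#' @param band_windows optional named list
#'   `list(supernatant = c(lo, hi), pellet = c(lo, hi))` in position units;
#'   if absent, [quantify_lane()] detects the two dominant peaks.
#' @return A list of class `gel_lane_profile`.
#' @export
gel_lane_profile <- function(position_px, intensity, band_windows = NULL) {
  if (length(position_px) != length(intensity))
    stop_bad_arg("lengths differ")
  if (any(diff(position_px) <= 0))
    stop_bad_arg("positions must be strictly increasing")
  if (any(intensity < 0)) stop_bad_arg("intensities must be >= 0")
  if (!is.null(band_windows)) {
    if (!all(c("supernatant", "pellet") %in% names(band_windows)))
      stop_bad_arg("band_windows needs 'supernatant' and 'pellet'")
    for (w in band_windows) if (length(w) != 2L || w[1L] >= w[2L])
      stop_bad_arg("each band window must be c(lo, hi) with lo < hi")
  }
  structure(list(position_px = position_px, intensity = intensity,
                 band_windows = band_windows),
            class = "gel_lane_profile")
}

trapezoid <- function(x, y) sum((y[-1L] + y[-length(y)]) / 2 * diff(x))

# Two dominant local maxima of a lightly smoothed profile; returns windows
# split at the intervening minimum.
detect_band_windows <- function(position_px, intensity) {
  n <- length(intensity)
  k <- min(5L, n)
  sm <- stats::filter(intensity, rep(1 / k, k), sides = 2)
  sm[is.na(sm)] <- intensity[is.na(sm)]
  sm <- as.numeric(sm)
  is_peak <- c(FALSE, diff(sign(diff(sm))) < 0, FALSE)
  peaks <- which(is_peak)
  if (length(peaks) < 2L)
    stop_bad_arg("could not detect two bands; provide band_windows")
  top2 <- peaks[order(sm[peaks], decreasing = TRUE)][1:2]
  top2 <- sort(top2)
  valley <- top2[1L] - 1L + which.min(sm[top2[1L]:top2[2L]])
  list(supernatant = c(position_px[1L], position_px[valley]),
       pellet = c(position_px[min(valley + 1L, n)], position_px[n]))
}

#' Fraction pelleted from a lane profile
#'
#' Within each band window the local baseline (the window minimum) is
#' subtracted and the band area integrated by the trapezoid rule; the
#' pelleted fraction is P / (S + P).
#'
#' @param profile a [gel_lane_profile()].
#' @return Scalar fraction between 0 and 1, with attributes `area_supernatant`,
#'   `area_pellet`.
#' @export
quantify_lane <- function(profile) {
  stopifnot(inherits(profile, "gel_lane_profile"))
  w <- profile$band_windows
  if (is.null(w))
    w <- detect_band_windows(profile$position_px, profile$intensity)
  if (max(w$supernatant[1L], w$pellet[1L]) <
      min(w$supernatant[2L], w$pellet[2L]))
    stop_bad_arg("band windows overlap")
  area <- function(win) {
    sel <- profile$position_px >= win[1L] & profile$position_px <= win[2L]
    if (sum(sel) < 2L) return(0)
    x <- profile$position_px[sel]
    y <- profile$intensity[sel]
    y <- y - min(y)   # local baseline
    trapezoid(x, y)
  }
  s_area <- area(w$supernatant); p_area <- area(w$pellet)
  if (s_area + p_area <= 0)
    stop_bad_arg("no signal in either band window (S + P <= 0)")
  structure(p_area / (s_area + p_area),
            area_supernatant = s_area, area_pellet = p_area)
}

#' Parameters for the synthetic co-sedimentation gel generator
#'
#' Defaults mirror a spectrin/F-actin titration: 2 uM F-actin binding
#' sites, titrant spanning the 0-12 uM range (starting at the lowest
#' nonzero point: a lane with zero tracked ligand carries no signal).
#'
#' @param site_conc_uM F-actin binding-site concentration (uM).
#' @param kd_uM dissociation constant of the tracked ligand (uM).
#' @param ligand_concs_uM nondecreasing total concentrations (uM) of the
#'   tracked ligand, one per lane.
#' @param band_sd_px Gaussian band width (SD, px).
#' @param lane_length_px profile length (px).
#' @param noise_sd_frac multiplicative log-normal noise (SD of log
#'   intensity), densitometry-like.
#' @param seed integer RNG seed.
#' @return A list of class `synth_gel_params`.
#' @export
synth_gel_params <- function(site_conc_uM = 2, kd_uM = 5,
                             ligand_concs_uM = c(0.75, 1.5, 3, 4.5, 6, 9, 12),
                             band_sd_px = 6, lane_length_px = 240L,
                             noise_sd_frac = 0, seed = 1L) {
  if (!is_scalar_num(site_conc_uM) || site_conc_uM <= 0)
    stop_bad_arg("`site_conc_uM` must be > 0")
  if (!is_scalar_num(kd_uM) || kd_uM <= 0) stop_bad_arg("`kd_uM` must be > 0")
  if (any(ligand_concs_uM < 0) || any(diff(ligand_concs_uM) < 0))
    stop_bad_arg("`ligand_concs_uM` must be nonnegative and nondecreasing")
  if (!is_scalar_num(band_sd_px) || band_sd_px <= 0)
    stop_bad_arg("`band_sd_px` must be > 0")
  if (!is_count(lane_length_px) || lane_length_px < 16L)
    stop_bad_arg("`lane_length_px` must be an integer >= 16")
  if (!is_scalar_num(noise_sd_frac) || noise_sd_frac < 0)
    stop_bad_arg("`noise_sd_frac` must be >= 0")
  structure(list(site_conc_uM = site_conc_uM, kd_uM = kd_uM,
                 ligand_concs_uM = ligand_concs_uM, band_sd_px = band_sd_px,
                 lane_length_px = as.integer(lane_length_px),
                 noise_sd_frac = noise_sd_frac, seed = as.integer(seed)),
            class = "synth_gel_params")
}

#' Generate synthetic co-sedimentation lane profiles with known truth
#'
#' For each titration point the bound fraction of the tracked ligand is
#' computed from the mass-action model — [solve_equilibrium()] for a direct
#' titration, [solve_competition()] when a competitor series is given (the
#' tracked ligand then typically held constant, competition-assay style).
#' Each lane is two Gaussian bands (supernatant at 1/4 lane length, pellet
#' at 3/4) whose *discrete trapezoid* areas equal the free and bound
#' concentrations exactly, so supernatant + pellet area equals total ligand
#' before noise to machine precision. Optional multiplicative log-normal
#' pixel noise emulates densitometry.
#'
#' For a lane with zero tracked ligand the truth fraction is the
#' zero-ligand limit sites / (sites + Kd); the lane itself carries no
#' signal and cannot be quantified.
#'
#' @param params a [synth_gel_params()].
#' @param competitor_concs_uM optional competitor concentrations, one per
#'   lane (same length as `ligand_concs_uM`).
#' @param competitor_kd_uM competitor dissociation constant (uM); required
#'   with `competitor_concs_uM`.
#' @return List of class `synth_gel`: `lanes` (list of
#'   [gel_lane_profile()]), `truth` (a [binding_series()]; titrant is the
#'   competitor when one is given, else the ligand), and `params`.
#' @export
generate_gel <- function(params, competitor_concs_uM = NULL,
                         competitor_kd_uM = NULL) {
  stopifnot(inherits(params, "synth_gel_params"))
  L <- params$ligand_concs_uM
  S <- params$site_conc_uM
  compete <- !is.null(competitor_concs_uM) || !is.null(competitor_kd_uM)
  if (compete) {
    if (is.null(competitor_concs_uM) || is.null(competitor_kd_uM))
      stop_bad_arg("competitor requires both concentrations and kd")
    if (length(competitor_concs_uM) != length(L))
      stop_bad_arg("competitor series length (%d) != ligand series length (%d)",
                   length(competitor_concs_uM), length(L))
  }
  bound <- vapply(seq_along(L), function(i) {
    if (compete)
      solve_competition(L[i], params$kd_uM, competitor_concs_uM[i],
                        competitor_kd_uM, S)$boundA_uM
    else solve_equilibrium(L[i], S, params$kd_uM)
  }, 0)
  frac <- ifelse(L > 0, bound / L, S / (S + params$kd_uM))

  len <- params$lane_length_px
  pos <- seq_len(len)
  half <- len %/% 2L
  windows <- list(supernatant = c(1, half), pellet = c(half + 1, len))
  sup_shape <- stats::dnorm(pos, mean = len / 4, sd = params$band_sd_px)
  pel_shape <- stats::dnorm(pos, mean = 3 * len / 4, sd = params$band_sd_px)
  band_area <- function(shape, win) {
    sel <- pos >= win[1L] & pos <= win[2L]
    trapezoid(pos[sel], shape[sel] - min(shape[sel]))
  }
  sup_unit <- band_area(sup_shape, windows$supernatant)
  pel_unit <- band_area(pel_shape, windows$pellet)

  lanes <- with_seed(params$seed, lapply(seq_along(L), function(i) {
    prof <- (L[i] - bound[i]) / sup_unit * sup_shape +
      bound[i] / pel_unit * pel_shape
    if (params$noise_sd_frac > 0)
      prof <- prof * exp(stats::rnorm(len, sd = params$noise_sd_frac))
    gel_lane_profile(pos, pmax(prof, 0), band_windows = windows)
  }))
  titrant <- if (compete) competitor_concs_uM else L
  structure(list(lanes = lanes,
                 truth = binding_series(titrant, frac, protein = "ligand"),
                 params = params),
            class = "synth_gel")
}
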