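#' Parameters for synthetic post-ablation recoil traces
#'
#' After a junction is cut, the flanking vertices separate with
#' saturating-exponential kinetics (the damped recoil of a viscoelastic
#' cortex): separation(t) = L0 + A (1 - exp(-t / tau)) + noise. Defaults
#' emulate live ablation imaging at 0.2 s per frame.
#'
#' @param amplitude_um plateau displacement A (um).
#' @param tau_s relaxation time (s).
#' @param noise_sd_um Gaussian measurement noise SD on separations (um).
#' @param frame_interval_s sampling interval (s), default 0.2.
#' @param duration_s trace duration (s); must be >= `frame_interval_s`.
#' @param l0_um pre-cut vertex separation (um).
#' @param seed integer RNG seed.
#' @return A list of class `synth_recoil_params`.
#' @export
synth_recoil_params <- function(amplitude_um = 2, tau_s = 0.5,
                                noise_sd_um = 0.05, frame_interval_s = 0.2,
                                duration_s = 4, l0_um = 3, seed = 1L) {
  if (!is_scalar_num(amplitude_um) || amplitude_um < 0)
    stop_bad_arg("`amplitude_um` must be >= 0")
  if (!is_scalar_num(tau_s) || tau_s <= 0) stop_bad_arg("`tau_s` must be > 0")
  if (!is_scalar_num(noise_sd_um) || noise_sd_um < 0)
    stop_bad_arg("`noise_sd_um` must be >= 0")
  if (!is_scalar_num(frame_interval_s) || frame_interval_s <= 0)
    stop_bad_arg("`frame_interval_s` must be > 0")
  if (!is_scalar_num(duration_s) || duration_s < frame_interval_s)
    stop_bad_arg("`duration_s` must be >= `frame_interval_s`")
  if (!is_scalar_num(l0_um) || l0_um < 0) stop_bad_arg("`l0_um` must be >= 0")
  structure(list(amplitude_um = amplitude_um, tau_s = tau_s,
                 noise_sd_um = noise_sd_um,
                 frame_interval_s = frame_interval_s,
                 duration_s = duration_s, l0_um = l0_um,
                 seed = as.integer(seed)),
            class = "synth_recoil_params")
}

#' Vertex-separation trace after junction ablation
#'
#' @param t_s times (s), strictly increasing, starting at 0 (= cut).
#' @param separation_um vertex separations (um), same length, >= 0.
#' @param side `"anterior"` or `"posterior"` (which compartment was cut).
#' @param disc_id identifier.
#' @return A data.frame of class `recoil_trace` with columns `t_s`,
#'   `separation_um` and attributes `side`, `disc_id`.
#' @export
recoil_trace <- function(t_s, separation_um,
                         side = c("anterior", "posterior"),
                         disc_id = "disc1") {
  side <- match.arg(side)
  if (length(t_s) != length(separation_um))
    stop_bad_arg("`t_s` and `separation_um` lengths differ")
  if (length(t_s) < 2L || t_s[1L] != 0 || any(diff(t_s) <= 0))
    stop_bad_arg("`t_s` must start at 0 and be strictly increasing")
  if (any(separation_um < 0))
    stop_bad_arg("separations must be nonnegative")
  structure(data.frame(t_s = t_s, separation_um = separation_um),
            side = side, disc_id = disc_id,
            class = c("recoil_trace", "data.frame"))
}

#' Generate a synthetic recoil trace
#'
#' @param params a [synth_recoil_params()].
#' @param side,disc_id passed to [recoil_trace()].
#' @return A `recoil_trace`; deterministic given the seed. Noise can push a
#'   separation below zero only for extreme noise settings; values are
#'   clipped at 0 (separations are distances).
#' @examples
#' tr <- generate_recoil_trace(synth_recoil_params(noise_sd_um = 0))
#' tr$separation_um[tr$t_s == 1] - tr$separation_um[1]  # 2 * (1 - exp(-2))
#' @export
generate_recoil_trace <- function(params, side = "anterior",
                                  disc_id = "disc1") {
  stopifnot(inherits(params, "synth_recoil_params"))
  t_s <- seq(0, params$duration_s, by = params$frame_interval_s)
  sep <- params$l0_um +
    params$amplitude_um * (1 - exp(-t_s / params$tau_s))
  if (params$noise_sd_um > 0)
    sep <- with_seed(params$seed,
                     sep + stats::rnorm(length(sep), sd = params$noise_sd_um))
  recoil_trace(t_s, pmax(sep, 0), side = side, disc_id = disc_id)
}

#' Initial recoil velocity of a trace
#'
#' The tension proxy: vertex displacement over the first `window_s` seconds
#' after the cut, divided by elapsed time. The `"endpoint"` method (default)
#' uses the separation at the last frame with t <= `window_s` minus the
#' separation at t = 0; `"linear_fit"` uses the least-squares slope over the
#' window as a robustness check.
#'
#' @param trace a [recoil_trace()].
#' @param window_s analysis window (s), default 1 (the first second after
#'   ablation).
#' @param method `"endpoint"` or `"linear_fit"`.
#' @return List of class `recoil_velocity`: `v_um_per_s`, `window_s`,
#'   `method`, `side`, `disc_id`.
#' @export
recoil_velocity <- function(trace, window_s = 1.0,
                            method = c("endpoint", "linear_fit")) {
  method <- match.arg(method)
  stopifnot(inherits(trace, "recoil_trace"))
  if (!is_scalar_num(window_s) || window_s <= 0)
    stop_bad_arg("`window_s` must be > 0")
  if (max(trace$t_s) < window_s)
    stop_bad_arg("trace (%.3g s) shorter than window (%.3g s)",
                 max(trace$t_s), window_s)
  in_win <- trace$t_s <= window_s
  if (sum(in_win) < 2L)
    stop_bad_arg("fewer than 2 samples inside the window")
  v <- if (method == "endpoint") {
    i <- max(which(in_win))
    (trace$separation_um[i] - trace$separation_um[1L]) /
      (trace$t_s[i] - trace$t_s[1L])
  } else {
    unname(stats::coef(stats::lm(separation_um ~ t_s,
                                 data = trace[in_win, ]))[2L])
  }
  structure(list(v_um_per_s = v, window_s = window_s, method = method,
                 side = attr(trace, "side"), disc_id = attr(trace, "disc_id")),
            class = "recoil_velocity")
}

#' Compare recoil velocities between anterior and posterior cuts
#'
#' Per-side mean with t-based 95% CI, a two-sided two-sample Student's t-test
#' (pooled variance by default, matching conventional reporting; set
#' `welch = TRUE` for the Welch correction), and the effect size
#' posterior mean / anterior mean.
#'
#' @param velocities list of [recoil_velocity()] objects carrying side
#'   labels, or a data.frame with columns `v_um_per_s` and `side`.
#' @param welch use Welch's unequal-variance t-test.
#' @return List of class `recoil_comparison`: `summary` (a data.frame of
#'   per-side n/mean/CI), `t_statistic`, `p_value`, `effect_p_over_a`.
#' @export
compare_sides <- function(velocities, welch = FALSE) {
  if (is.data.frame(velocities)) {
    v <- velocities$v_um_per_s; side <- velocities$side
  } else {
    v <- vapply(velocities, `[[`, 0, "v_um_per_s")
    side <- vapply(velocities, `[[`, "", "side")
  }
  if (!all(side %in% c("anterior", "posterior")))
    stop_bad_arg("sides must be 'anterior' or 'posterior'")
  va <- v[side == "anterior"]; vp <- v[side == "posterior"]
  if (length(va) < 2L || length(vp) < 2L)
    stop_bad_arg("need >= 2 velocities per side (anterior %d, posterior %d)",
                 length(va), length(vp))
  smry <- summarize_groups(list(anterior = va, posterior = vp))
  tt <- stats::t.test(vp, va, var.equal = !welch)
  structure(list(summary = smry,
                 t_statistic = unname(tt$statistic),
                 p_value = tt$p.value,
                 effect_p_over_a = mean(vp) / mean(va),
                 welch = welch),
            class = "recoil_comparison")
}

#' @export
print.recoil_comparison <- function(x, ...) {
  print(x$summary)
  cat(sprintf("t = %.4f, p = %.4g, posterior/anterior effect = %.4f\n",
              x$t_statistic, x$p_value, x$effect_p_over_a))
  invisible(x)
}

#' Vertex separation from paired vertex coordinates
#'
#' Helper for trace files recording the two tracked vertices as
#' (x1, y1, x2, y2) per frame: returns the Euclidean separation series.
#'
#' @param x1,y1,x2,y2 numeric vectors of equal length (um or px).
#' @return Numeric vector of separations.
#' @export
vertex_separation <- function(x1, y1, x2, y2) {
  n <- length(x1)
  if (any(lengths(list(y1, x2, y2)) != n))
    stop_bad_arg("coordinate vectors must share length")
  sqrt((x2 - x1)^2 + (y2 - y1)^2)
}
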