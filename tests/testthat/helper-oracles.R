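# Independent oracles used across the suite. Each deliberately takes the
# dumbest correct route (explicit loops, bisection, permutation, Monte Carlo)
# so it shares no code path with the implementation it checks.

# Brute-force block means: explicit per-pixel double loop over a block grid
# given by 0-based row/col edges; masked pixels only, empty block -> NA.
oracle_block_means <- function(channel, mask, row_edges, col_edges) {
  nbr <- length(row_edges) - 1L
  nbc <- length(col_edges) - 1L
  vals <- matrix(NA_real_, nbr, nbc)
  cnts <- matrix(0L, nbr, nbc)
  for (bi in seq_len(nbr)) for (bj in seq_len(nbc)) {
    acc <- 0; n <- 0L
    for (r in (row_edges[bi] + 1L):row_edges[bi + 1L])
      for (cc in (col_edges[bj] + 1L):col_edges[bj + 1L])
        if (mask[r, cc]) { acc <- acc + channel[r, cc]; n <- n + 1L }
    cnts[bi, bj] <- n
    if (n > 0L) vals[bi, bj] <- acc / n
  }
  list(values = vals, counts = cnts)
}

# Exhaustive Otsu: try every unique intensity as threshold, minimize
# within-class variance (weighted), pick the minimizer.
oracle_otsu <- function(x) {
  x <- as.vector(x)
  cand <- sort(unique(x))
  cand <- cand[-length(cand)]
  best <- NULL; best_w <- Inf
  for (th in cand) {
    lo <- x[x <= th]; hi <- x[x > th]
    w <- length(lo) * ifelse(length(lo) > 1, stats::var(lo) * (length(lo) - 1) / length(lo), 0) +
         length(hi) * ifelse(length(hi) > 1, stats::var(hi) * (length(hi) - 1) / length(hi), 0)
    if (w < best_w) { best_w <- w; best <- th }
  }
  best
}

# Bisection root of the mass-action equation for bound ligand:
# bound (K + (S - bound)) relation rewritten as f(b) = (L - b)(S - b) - K b.
oracle_bound_bisect <- function(L, S, K, iters = 200L) {
  f <- function(b) (L - b) * (S - b) - K * b
  lo <- 0; hi <- min(L, S)
  if (f(lo) <= 0) return(0)
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Nested-bisection competition oracle, independent of the free-site root
# formulation: for trial bound-B the A subproblem is single-ligand binding
# to the remaining sites (solved by oracle_bound_bisect); the outer
# bisection zeroes the B mass-action mismatch. (A plain damped fixed point
# on the bound pair oscillates for tight binding, so bisection it is.)
oracle_competition_nested <- function(LA, KA, LB, KB, S, iters = 200L) {
  g <- function(bB) {
    bA <- oracle_bound_bisect(LA, max(S - bB, 0), KA)
    f_sites <- S - bB - bA
    bB * KB - (LB - bB) * f_sites
  }
  lo <- 0; hi <- min(LB, S)
  if (hi == 0 || g(lo) >= 0) {
    bB <- 0
  } else {
    for (i in seq_len(iters)) {
      mid <- (lo + hi) / 2
      if (g(mid) < 0) lo <- mid else hi <- mid
    }
    bB <- (lo + hi) / 2
  }
  list(boundA = oracle_bound_bisect(LA, max(S - bB, 0), KA), boundB = bB)
}

# Two-sided permutation p-value for a difference in group means.
oracle_permutation_p <- function(x, y, n_perm = 1e5, seed = 42) {
  obs <- abs(mean(x) - mean(y))
  z <- c(x, y); nx <- length(x)
  set.seed(seed)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(length(z), nx)
    if (abs(mean(z[idx]) - mean(z[-idx])) >= obs - 1e-12) hits <- hits + 1L
  }
  (hits + 1) / (n_perm + 1)
}

# Monte-Carlo null distribution of max |t| over k contrasts vs a shared
# control (balanced or not), for Dunnett-adjusted p-values.
oracle_dunnett_mc <- function(t_obs, n_control, n_groups, df,
                              draws = 1e5, seed = 99) {
  set.seed(seed)
  k <- length(n_groups)
  z0 <- stats::rnorm(draws) / sqrt(n_control)
  u <- sqrt(stats::rchisq(draws, df) / df)
  maxt <- rep(0, draws)
  for (j in seq_len(k)) {
    tj <- abs(stats::rnorm(draws) / sqrt(n_groups[j]) - z0) /
      (u * sqrt(1 / n_groups[j] + 1 / n_control))
    maxt <- pmax(maxt, tj)
  }
  vapply(t_obs, function(t0) mean(maxt >= t0), 0)
}

# Tiny noiseless disc cohort shared by several tests.
make_test_disc <- function(multiplier = 1.5, noise = 0, seed = 1,
                           size = 96L, n_cells = 36L) {
  generate_disc(synth_disc_params(
    image_size_px = c(size, size), pixel_size_um = 0.25, n_cells = n_cells,
    posterior_multiplier = multiplier, noise_sd_frac = noise, seed = seed))
}

disc_pipeline_pa <- function(disc, mode = "ratio_to_reference") {
  ann <- disc_annotation(disc$center_px, "right")
  msk <- build_mask(disc$image)
  hs <- block_quantify(disc$image, msk, ann, "signal")
  hr <- block_quantify(disc$image, msk, ann, "ecad")
  hm <- normalize_heatmap(hs, hr, mode = mode)
  pa_ratio(hm, split_compartments(hm, ann))$value
}
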