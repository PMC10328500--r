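test_that("generate_disc is deterministic and honors its ground truth", {
  p <- synth_disc_params(image_size_px = c(96, 96), pixel_size_um = 0.25,
                         n_cells = 36, posterior_multiplier = 1.5,
                         noise_sd_frac = 0.1, seed = 11)
  d1 <- generate_disc(p)
  d2 <- generate_disc(p)
  expect_identical(d1$image$channels, d2$image$channels)   # bit-identical
  expect_identical(d1$compartment_map, d2$compartment_map)
  expect_equal(d1$truth$pa_ratio, 1.5)

  d3 <- generate_disc(synth_disc_params(image_size_px = c(96, 96),
                                        n_cells = 36, seed = 12))
  expect_false(identical(d1$image$channels$signal, d3$image$channels$signal))
})

test_that("noiseless masked-pixel mean ratio equals the multiplier exactly", {
  for (m in c(1, 1.25, 1.5, 0.8)) {
    d <- make_test_disc(multiplier = m, noise = 0, seed = 5)
    sig <- d$image$channels$signal
    j <- d$truth$junction_mask
    post <- d$compartment_map == 1L
    expect_gt(sum(j & post), 0)
    expect_gt(sum(j & !post), 0)
    ratio <- mean(sig[j & post]) / mean(sig[j & !post])
    expect_equal(ratio, m, tolerance = 1e-12)
  }
})

test_that("disc geometry: boundary through center, both compartments junctional", {
  d <- make_test_disc(seed = 2)
  ctr <- d$center_px
  # boundary line is vertical through the center column (posterior = right)
  expect_true(all(d$compartment_map[, (ctr[2] + 1):ncol(d$compartment_map)] == 1L))
  expect_true(all(d$compartment_map[, 1:ctr[2]] == 0L))
  expect_identical(dim(d$compartment_map), dim(d$image))
})

test_that("generate_recoil_trace matches its closed form and edge cases", {
  p <- synth_recoil_params(amplitude_um = 2, tau_s = 0.5, noise_sd_um = 0,
                           frame_interval_s = 0.2, duration_s = 4, l0_um = 3)
  tr <- generate_recoil_trace(p)
  expect_equal(tr$t_s, seq(0, 4, by = 0.2))
  # displacement at t = 1 s: A (1 - e^{-2})
  expect_equal(tr$separation_um[tr$t_s == 1] - tr$separation_um[1],
               2 * (1 - exp(-2)), tolerance = 1e-12)
  # A = 0 -> flat at L0; t = 0 -> zero displacement
  flat <- generate_recoil_trace(synth_recoil_params(amplitude_um = 0,
                                                    noise_sd_um = 0))
  expect_true(all(flat$separation_um == flat$separation_um[1]))
  expect_equal(tr$separation_um[1], 3)

  n1 <- generate_recoil_trace(synth_recoil_params(noise_sd_um = 0.05, seed = 7))
  n2 <- generate_recoil_trace(synth_recoil_params(noise_sd_um = 0.05, seed = 7))
  expect_identical(n1$separation_um, n2$separation_um)
})

test_that("generate_gel: limits, conservation, determinism", {
  # no-binding limit
  weak <- generate_gel(synth_gel_params(kd_uM = 1e9, noise_sd_frac = 0))
  expect_true(all(weak$truth$fraction_bound < 1e-6))
  # stoichiometric limit: ligand 2, sites 2, kd ~ 0
  tight <- generate_gel(synth_gel_params(kd_uM = 1e-9,
                                         ligand_concs_uM = 2,
                                         noise_sd_frac = 0))
  expect_equal(tight$truth$fraction_bound, 1, tolerance = 1e-4)
  # conservation: S + P areas equal total ligand before noise
  g <- generate_gel(synth_gel_params(noise_sd_frac = 0))
  for (i in seq_along(g$lanes)) {
    f <- quantify_lane(g$lanes[[i]])
    total <- attr(f, "area_supernatant") + attr(f, "area_pellet")
    expect_equal(total, g$params$ligand_concs_uM[i], tolerance = 1e-10)
  }
  # determinism with noise
  g1 <- generate_gel(synth_gel_params(noise_sd_frac = 0.05, seed = 3))
  g2 <- generate_gel(synth_gel_params(noise_sd_frac = 0.05, seed = 3))
  expect_identical(g1$lanes[[2]]$intensity, g2$lanes[[2]]$intensity)
})

test_that("generate_gel competitor contract", {
  p <- synth_gel_params(ligand_concs_uM = rep(12, 4), noise_sd_frac = 0)
  expect_error(generate_gel(p, competitor_concs_uM = c(0, 1),
                            competitor_kd_uM = 0.5),
               "length")
  expect_error(generate_gel(p, competitor_concs_uM = c(0, 1, 2, 2.59)),
               "both")
  g <- generate_gel(p, competitor_concs_uM = c(0, 1, 2, 2.59),
                    competitor_kd_uM = 0.5)
  expect_equal(g$truth$titrant_uM, c(0, 1, 2, 2.59))
  # fraction of the tracked ligand decreases as competitor rises
  expect_true(all(diff(g$truth$fraction_bound) < 0))
})

test_that("parameter validation rejects bad worlds", {
  expect_error(synth_disc_params(n_cells = 3), "n_cells")
  expect_error(synth_disc_params(noise_sd_frac = 1), "noise_sd_frac")
  expect_error(synth_disc_params(posterior_multiplier = 0), "> 0")
  expect_error(synth_recoil_params(duration_s = 0.1, frame_interval_s = 0.2),
               "duration")
  expect_error(synth_gel_params(ligand_concs_uM = c(3, 1)), "nondecreasing")
})
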