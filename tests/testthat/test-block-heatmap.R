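full_mask <- function(nr, nc) matrix(TRUE, nr, nc)

test_that("block means equal an explicit per-pixel loop (hand case + random)", {
  # 6x6 px image, 3-px blocks, hand-written values, center at (3,3)
  vals <- matrix(as.numeric(1:36), 6, 6)
  img <- disc_image(list(ecad = vals + 100, sig = vals), pixel_size_um = 1,
                    reference = "ecad")
  ann <- disc_annotation(c(3, 3), "right", block_size_um = 3)
  hm <- block_quantify(img, full_mask(6, 6), ann, "sig")
  expect_identical(dim(hm$values), c(2L, 2L))
  o <- oracle_block_means(vals, full_mask(6, 6), hm$row_edges, hm$col_edges)
  expect_equal(hm$values, o$values)
  expect_equal(hm$counts, o$counts)
  expect_equal(hm$center_index, c(1L, 1L))
  # four block means by hand: mean of 3x3 quadrants of the 6x6 matrix
  expect_equal(hm$values[1, 1], mean(vals[1:3, 1:3]))
  expect_equal(hm$values[2, 2], mean(vals[4:6, 4:6]))

  # random images + random masks vs oracle
  set.seed(21)
  for (rep in 1:5) {
    ch <- matrix(runif(48 * 48), 48, 48)
    mask <- matrix(runif(48 * 48) < 0.4, 48, 48)
    if (!any(mask)) next
    img <- disc_image(list(ecad = matrix(1 + runif(48 * 48), 48), s = ch),
                      pixel_size_um = 0.5, reference = "ecad")
    ctr <- c(sample(10:38, 1), sample(10:38, 1))
    ann <- disc_annotation(ctr, "right", block_size_um = sample(2:4, 1))
    hm <- block_quantify(img, mask, ann, "s")
    o <- oracle_block_means(ch, mask, hm$row_edges, hm$col_edges)
    expect_equal(hm$values, o$values, tolerance = 1e-12)
    expect_identical(hm$counts, o$counts)
  }
})

test_that("block grid contract: uniform input, empty blocks, edge drop, errors", {
  img <- disc_image(list(ecad = matrix(7, 20, 20), s = matrix(3.5, 20, 20)),
                    pixel_size_um = 1, reference = "ecad")
  ann <- disc_annotation(c(10, 10), "right", block_size_um = 3)
  hm <- block_quantify(img, full_mask(20, 20), ann, "s")
  expect_true(all(hm$values == 3.5))            # uniform channel
  # partial edge blocks dropped: all retained blocks span full 3 px
  expect_true(all(diff(hm$row_edges) == 3))
  expect_true(max(hm$row_edges) <= 20 && min(hm$row_edges) >= 0)
  # blocks with no masked pixels are NA with count 0
  mask <- full_mask(20, 20); mask[1:6, 1:6] <- FALSE
  hm2 <- block_quantify(img, mask, ann, "s")
  expect_true(any(hm2$counts == 0))
  expect_true(all(is.na(hm2$values[hm2$counts == 0])))
  expect_error(block_quantify(img, full_mask(20, 20),
                              disc_annotation(c(25, 10), "right"), "s"),
               "outside")
  tiny <- disc_annotation(c(10, 10), "right", block_size_um = 0.5)
  expect_error(block_quantify(img, full_mask(20, 20), tiny, "s"),
               "smaller than one pixel")
})

test_that("normalize_heatmap: arithmetic oracle, identity, scale invariance", {
  s <- make_heatmap(matrix(c(2, 6, 4, 8), 2, 2))
  r <- make_heatmap(matrix(1, 2, 2))
  out <- normalize_heatmap(s, r)
  # two-step formula by hand: s/mean(s) = {0.4,1.2,0.8,1.6}; r/mean(r) = 1
  expect_equal(out$values, matrix(c(0.4, 1.2, 0.8, 1.6), 2, 2))
  # signal == reference -> ratio map of ones
  same <- normalize_heatmap(s, s)
  expect_equal(same$values, matrix(1, 2, 2))
  # scaling the signal leaves ratio_to_reference unchanged
  s_scaled <- s; s_scaled$values <- s$values * 7.3
  expect_equal(normalize_heatmap(s_scaled, r)$values, out$values)
  # self_mean: mean of non-missing output is 1
  sm <- normalize_heatmap(s, mode = "self_mean")
  expect_equal(mean(sm$values, na.rm = TRUE), 1, tolerance = 1e-10)
  # missing propagates; zero reference becomes missing
  s2 <- s; s2$values[1, 1] <- NA
  r2 <- r; r2$values[2, 2] <- 0
  expect_message(out2 <- normalize_heatmap(s2, r2), "zero reference")
  expect_true(is.na(out2$values[1, 1]) && is.na(out2$values[2, 2]))
  # grid mismatch errors
  r3 <- make_heatmap(matrix(1, 3, 2))
  expect_error(normalize_heatmap(s, r3), "grid")
})

test_that("average_discs aligns on center, pads with NA, enforces min_count", {
  m1 <- make_heatmap(matrix(1, 3, 3), center_index = c(2L, 2L))
  # identity: averaging one map at min_count = 1 returns it
  expect_equal(average_discs(list(m1), min_count = 1)$values, m1$values)
  # three identical maps, min_count = 3 -> same map
  avg3 <- average_discs(list(m1, m1, m1), min_count = 3)
  expect_equal(avg3$values, m1$values)
  expect_true(all(avg3$counts == 3))
  # different extents: hand-aligned overlay oracle
  big <- make_heatmap(matrix(2, 5, 5), center_index = c(3L, 3L))
  avg <- average_discs(list(m1, big), min_count = 2)
  expect_identical(dim(avg$values), c(5L, 5L))
  expect_equal(avg$center_index, c(3L, 3L))
  inner <- avg$values[2:4, 2:4]     # overlap region: both discs present
  expect_true(all(inner == 1.5))
  ring <- avg$values; ring[2:4, 2:4] <- NA
  expect_true(all(is.na(ring)))     # only one disc contributes -> missing
  expect_equal(avg$counts[1, 1], 1L)
  # at min_count = 1 the ring keeps the big map's values
  avg1 <- average_discs(list(m1, big), min_count = 1)
  expect_equal(avg1$values[1, 1], 2)
  # contract errors
  expect_error(average_discs(list()), "non-empty")
  m_norm <- m1; m_norm$normalization <- "self_mean"
  expect_error(average_discs(list(m1, m_norm)), "normalization")
})

test_that("min-count rule: staggered 3-disc cohort, exact missingness", {
  maps <- list(
    make_heatmap(matrix(1, 3, 3), center_index = c(2L, 2L)),
    make_heatmap(matrix(2, 5, 5), center_index = c(3L, 3L)),
    make_heatmap(matrix(3, 7, 7), center_index = c(4L, 4L)))
  avg <- average_discs(maps, min_count = 3)
  expect_identical(dim(avg$values), c(7L, 7L))
  # exactly the 3x3 core has 3 contributors; everything else is missing
  for (i in 1:7) for (j in 1:7) {
    n <- avg$counts[i, j]
    if (i >= 3 && i <= 5 && j >= 3 && j <= 5) {
      expect_equal(n, 3L)
      expect_equal(avg$values[i, j], 2)
    } else {
      expect_lt(n, 3L)
      expect_true(is.na(avg$values[i, j]))
    }
  }
})

test_that("split_compartments: geometric enumeration and marker consistency", {
  # 4-column grid, 3-px blocks from 0; center inside column 2 -> excluded
  hm <- make_heatmap(matrix(1, 2, 4), block_px = 3)
  ann <- disc_annotation(c(3, 4), "right")
  sp <- split_compartments(hm, ann)
  expect_equal(sp$labels[1, ],
               c("anterior", "excluded", "posterior", "posterior"))
  # center on a block corner: nothing excluded
  ann2 <- disc_annotation(c(3, 6), "right")
  sp2 <- split_compartments(hm, ann2)
  expect_equal(sp2$labels[1, ],
               c("anterior", "anterior", "posterior", "posterior"))
  # posterior on the left flips labels
  sp3 <- split_compartments(hm, disc_annotation(c(3, 6), "left"))
  expect_equal(sp3$labels[1, ],
               c("posterior", "posterior", "anterior", "anterior"))
  # marker covering exactly the right half agrees with the geometric rule
  marker <- cbind(matrix(0L, 6, 6), matrix(1L, 6, 6))
  hm6 <- make_heatmap(matrix(1, 2, 4), block_px = 3)
  spm <- split_compartments(hm6, ann2, compartment_map = marker)
  expect_equal(spm$labels, sp2$labels)
  # all-posterior marker -> anterior empty -> pa_ratio errors
  spp <- split_compartments(hm6, ann2,
                            compartment_map = matrix(1L, 6, 12))
  expect_error(pa_ratio(hm6, spp), "anterior")
})

test_that("pa_ratio: symmetric map gives 1; block counts reported", {
  hm <- make_heatmap(matrix(c(3, 3, 3, 3), 2, 2), block_px = 3)
  ann <- disc_annotation(c(3, 3), "right")
  pr <- pa_ratio(hm, split_compartments(hm, ann))
  expect_equal(pr$value, 1)
  expect_equal(pr$n_posterior_blocks, 2)
  expect_equal(pr$n_anterior_blocks, 2)
})

test_that("noiseless disc pipeline recovers the multiplier to 1e-6", {
  d <- make_test_disc(multiplier = 1.5, noise = 0, seed = 13)
  expect_equal(disc_pipeline_pa(d), 1.5, tolerance = 1e-6)
})

test_that("parameter recovery across multipliers (seeded cohorts)", {
  # scaled-down version of the recovery property: 4 multipliers x 4 discs
  for (m in c(0.8, 1.0, 1.25, 1.5)) {
    vals <- vapply(1:4, function(s)
      disc_pipeline_pa(make_test_disc(multiplier = m, noise = 0.1,
                                      seed = 100 + s)), 0)
    expect_lt(abs(mean(vals) - m) / m, 0.07)
  }
})
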