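test_that("identical parameters and seed give bit-identical stacks", {
  p <- sim_params(shape = c(4L, 64L, 64L), n_puncta = 20L,
                  coloc_fraction = 0.2, seed = 77)
  s1 <- simulate_stack(p)
  s2 <- simulate_stack(p)
  expect_identical(s1$stack$channels, s2$stack$channels)
  expect_identical(s1$truth$centroids, s2$truth$centroids)
  s3 <- simulate_stack(sim_params(shape = c(4L, 64L, 64L), n_puncta = 20L,
                                  coloc_fraction = 0.2, seed = 78))
  expect_false(identical(s1$stack$channels, s3$stack$channels))
})

test_that("ground truth carries the planted pairing counts and geometry", {
  p <- sim_params(shape = c(6L, 128L, 128L), n_puncta = 50L,
                  coloc_fraction = 0.2, seed = 5)
  sim <- simulate_stack(p)
  gt <- sim$truth
  expect_identical(unname(gt$n_puncta), rep(50L, 3L))
  for (pr in list(1:2, c(1L, 3L), 2:3)) {
    np <- sum((gt$pairings$channel_a == pr[1] & gt$pairings$channel_b == pr[2]))
    expect_identical(np, 10L)  # ceiling(0.2 * 50)
  }
  # paired centroids sit within one PSF width of each other
  for (k in seq_len(nrow(gt$pairings))) {
    pa <- gt$pairings[k, ]
    d <- sqrt(sum((gt$centroids[[pa$channel_a]][pa$index_a, ] -
                   gt$centroids[[pa$channel_b]][pa$index_b, ])^2))
    expect_lt(d, p$punctum_sigma)
  }
  # intensities are 8-bit
  expect_true(all(vapply(sim$stack$channels, function(a)
    all(a >= 0 & a <= 255 & a == round(a)), logical(1))))

  expect_error(sim_params(coloc_fraction = 1.2), "0, 1")
  expect_error(sim_params(coloc_fraction = 0.1, triple_fraction = 0.2),
               "exceed")
  expect_error(sim_params(amplitude = 10, noise_sd = 6), "amplitude")
  expect_error(simulate_stack(sim_params(shape = c(2L, 16L, 16L),
                                         n_puncta = 400L, seed = 1)),
               "crowded")
})

test_that("expected co-localization follows from pairings and counts", {
  p <- sim_params(shape = c(6L, 128L, 128L), n_puncta = 50L,
                  coloc_fraction = 0.2, seed = 5)
  ec <- expected_coloc(simulate_stack(p)$truth)
  expect_equal(ec$percent[ec$ref == "ch1" & ec$target == "ch2"], 20.0)
  p0 <- sim_params(shape = c(4L, 96L, 96L), n_puncta = 30L,
                   coloc_fraction = 0, seed = 5)
  expect_true(all(expected_coloc(simulate_stack(p0)$truth)$percent == 0))

  # asymmetric counts give directional expectations
  gt <- structure(list(
    centroids = list(matrix(0, 50, 3), matrix(0, 80, 3)),
    pairings = data.frame(channel_a = rep(1L, 10), index_a = 1:10,
                          channel_b = rep(2L, 10), index_b = 1:10,
                          triple = FALSE),
    n_puncta = c(50L, 80L)), class = "ground_truth")
  ec2 <- expected_coloc(gt)
  expect_equal(ec2$percent[ec2$ref == "ch1"], 20.0)
  expect_equal(ec2$percent[ec2$ref == "ch2"], 12.5)
})

test_that("rendered peaks coincide with recorded centroids before noise", {
  p <- sim_params(shape = c(6L, 96L, 96L), n_channels = 2L, n_puncta = 15L,
                  coloc_fraction = 0, noise_sd = 0, background_gradient = 0,
                  seed = 9)
  sim <- simulate_stack(p)
  a <- sim$stack$channels$ch1
  for (i in seq_len(nrow(sim$truth$centroids[[1]]))) {
    ctr <- sim$truth$centroids[[1]][i, ]
    vox <- round(ctr)
    # the brightest voxel in a 3x3x3 neighbourhood is the rounded centroid
    nb <- a[max(1, vox[1] - 1):min(6, vox[1] + 1),
            max(1, vox[2] - 1):min(96, vox[2] + 1),
            max(1, vox[3] - 1):min(96, vox[3] + 1)]
    expect_equal(max(nb), a[vox[1], vox[2], vox[3]])
  }
})

test_that("zero-velocity time-lapse paths are constant; moving ones linear", {
  tp <- sim_params(shape = c(1L, 64L, 64L), n_channels = 2L, n_puncta = 3L,
                   noise_sd = 0, seed = 4)
  tl0 <- simulate_timelapse(tp, n_frames = 6, velocity_um_s = 0,
                            paired_fraction = 0)
  for (pp in tl0$truth$paths$ch1)
    expect_equal(max(apply(pp[, 2:3], 2, function(v) diff(range(v)))), 0)

  # planted path length equals velocity x duration
  tp2 <- sim_params(shape = c(1L, 128L, 128L), n_channels = 2L,
                    n_puncta = 3L, noise_sd = 0, seed = 4)
  tl <- simulate_timelapse(tp2, n_frames = 70, velocity_um_s = 0.0057,
                           paired_fraction = 0, frame_interval_s = 4.5)
  pp <- tl$truth$paths$ch1[[1]]
  planted_um <- sum(sqrt(rowSums(diff(pp[, 2:3])^2))) * tp2$pixel_size_um
  expect_equal(planted_um, 0.0057 * 310.5, tolerance = 1e-6)
  # and track_distance recovers it from the ground-truth path
  tr <- list(centroids = pp[, 2:3])
  g <- voxel_geometry(tp2$pixel_size_um, 0)
  expect_equal(track_distance(tr, g), planted_um)
  expect_lt(abs(track_distance(tr, g) - 1.77) / 1.77, 0.02)

  expect_error(simulate_timelapse(tp, n_frames = 1, velocity_um_s = 0,
                                  paired_fraction = 0), "n_frames")
  expect_warning(simulate_timelapse(
    sim_params(shape = c(1L, 48L, 48L), n_channels = 2L, n_puncta = 1L,
               noise_sd = 0, seed = 2),
    n_frames = 40, velocity_um_s = 0.5, paired_fraction = 1),
    "truncated")
})
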