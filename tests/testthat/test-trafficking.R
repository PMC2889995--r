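# Build a one-observation-per-frame puncta_set list from centroid matrices:
# pos[[frame]] is an n x 2 (y, x) matrix of granule positions.
frames_from_positions <- function(pos, dim = c(1L, 64L, 64L)) {
  lapply(pos, function(cm) {
    puncta <- lapply(seq_len(nrow(cm)), function(i)
      list(id = i, channel = "ch1", voxels = i, n = 1L,
           centroid = c(z = 1, y = cm[i, 1], x = cm[i, 2]), peak = 1))
    structure(list(puncta = puncta, channel = "ch1", dim = dim,
                   params = list()),
              class = "puncta_set")
  })
}

geom_px1 <- voxel_geometry(pixel_size_xy = 1, z_interval = 0,
                           frame_interval = 2)

test_that("a single drifting punctum yields one track spanning all frames", {
  pos <- lapply(0:9, function(t) cbind(10 + t, 20))
  trks <- link_tracks(frames_from_positions(pos), max_step = 5,
                      geometry = geom_px1)
  expect_length(trks, 1L)
  expect_identical(trks[[1]]$frames, 1:10)
  expect_equal(trks[[1]]$times, (0:9) * 2)
  expect_equal(track_distance(trks[[1]], geom_px1), 9)
})

test_that("puncta separated far beyond max_step never merge", {
  pos <- lapply(0:5, function(t) rbind(c(5 + t, 5), c(50, 50)))
  trks <- link_tracks(frames_from_positions(pos), max_step = 3,
                      geometry = geom_px1)
  expect_length(trks, 2L)
  lens <- sort(vapply(trks, function(tr) length(tr$frames), integer(1)))
  expect_identical(lens, c(6L, 6L))
  # a jump larger than max_step starts a new track
  pos2 <- c(lapply(0:2, function(t) cbind(10, 10)),
            lapply(0:2, function(t) cbind(40, 40)))
  trks2 <- link_tracks(frames_from_positions(pos2), max_step = 3,
                       geometry = geom_px1)
  expect_length(trks2, 2L)
  expect_error(link_tracks(frames_from_positions(pos2)[1], 3, geom_px1),
               "2 frames")
})

test_that("track distance sums consecutive displacements in um", {
  g <- voxel_geometry(pixel_size_xy = 0.22, z_interval = 0)
  tr <- list(centroids = cbind(c(10, 10, 10, 10), c(3, 4, 5, 6)))
  expect_equal(track_distance(tr, g), 3 * 0.22)
  expect_equal(track_distance(list(centroids = cbind(c(5, 5), c(9, 9))), g), 0)
  expect_error(track_distance(list(centroids = cbind(1, 1)), g), "2 observations")

  # time reversal and the straight-line lower bound
  set.seed(3)
  walk <- apply(matrix(stats::rnorm(20), 10, 2), 2, cumsum)
  d_fwd <- track_distance(list(centroids = walk), g)
  d_rev <- track_distance(list(centroids = walk[10:1, ]), g)
  expect_equal(d_fwd, d_rev)
  chord <- sqrt(sum((walk[10, ] - walk[1, ])^2)) * 0.22
  expect_gte(d_fwd, chord)
})

test_that("greedy linking matches a brute-force minimal-distance matching", {
  # oracle: full reimplementation of greedy frame-to-frame linking; tracks
  # are compared as partitions of the (frame, punctum) observations
  oracle_link <- function(pos, max_step) {
    n1 <- nrow(pos[[1]])
    tracks <- lapply(seq_len(n1), function(i) cbind(1L, i))
    live <- seq_len(n1)
    for (t in 2:length(pos)) {
      cur <- pos[[t]]
      taken_t <- rep(FALSE, length(live)); taken_c <- rep(FALSE, nrow(cur))
      ends <- do.call(rbind, lapply(live, function(k) {
        obs <- tracks[[k]]
        pos[[obs[nrow(obs), 1]]][obs[nrow(obs), 2], ]
      }))
      repeat {
        best <- Inf; bi <- bj <- 0L
        for (i in seq_along(live)) for (j in seq_len(nrow(cur))) {
          if (taken_t[i] || taken_c[j]) next
          d <- sqrt(sum((ends[i, ] - cur[j, ])^2))
          if (d <= max_step && d < best) { best <- d; bi <- i; bj <- j }
        }
        if (bi == 0L) break
        taken_t[bi] <- taken_c[bj] <- TRUE
        tracks[[live[bi]]] <- rbind(tracks[[live[bi]]], cbind(t, bj))
      }
      new_ids <- integer(0)
      for (j in which(!taken_c)) {
        tracks[[length(tracks) + 1L]] <- cbind(t, j)
        new_ids <- c(new_ids, length(tracks))
      }
      live <- c(live[taken_t], new_ids)
    }
    tracks
  }
  signature <- function(obs_list) sort(vapply(obs_list, function(m)
    paste(m[, 1], m[, 2], sep = ":", collapse = ";"), character(1)))

  set.seed(21)
  n <- 6L
  start <- cbind(stats::runif(n, 10, 54), stats::runif(n, 10, 54))
  pos <- lapply(0:7, function(t)
    start + t * cbind(stats::runif(n, -0.6, 0.6), stats::runif(n, -0.6, 0.6)))
  trks <- link_tracks(frames_from_positions(pos), max_step = 3,
                      geometry = geom_px1)
  got <- signature(lapply(trks, function(tr)
    cbind(tr$frames, tr$punctum_ids)))
  want <- signature(oracle_link(pos, 3))
  expect_identical(got, want)
})

test_that("well-separated planted tracks are recovered without switches", {
  tp <- sim_params(shape = c(1L, 96L, 96L), n_channels = 2L, n_puncta = 4L,
                   noise_sd = 0, background_gradient = 0, seed = 31,
                   pixel_size_um = 0.2)
  tl <- simulate_timelapse(tp, n_frames = 12, velocity_um_s = 0.2 / 5,
                           paired_fraction = 0, frame_interval_s = 5)
  frames <- lapply(tl$frames, function(st)
    detect_puncta(st$channels$ch1,
                  estimate_local_background(st$channels$ch1, 31L),
                  channel_name = "ch1"))
  trks <- link_tracks(frames, max_step = 0.5, geometry = tl$frames[[1]]$geometry)
  expect_length(trks, 4L)
  for (tr in trks) {
    expect_identical(tr$frames, 1:12)
    # each recovered track hugs exactly one planted path throughout
    errs <- vapply(tl$truth$paths$ch1, function(pp)
      max(sqrt(rowSums((tr$centroids - pp[, 2:3])^2))), numeric(1))
    expect_identical(sum(errs < 1), 1L)
    planted <- sum(sqrt(rowSums(diff(
      tl$truth$paths$ch1[[which.min(errs)]][, 2:3])^2))) * 0.2
    expect_lt(abs(track_distance(tr, tl$frames[[1]]$geometry) - planted) /
                planted, 0.02)
  }
})

test_that("co-trafficking fraction recovers planted pairings", {
  # identical lists give 1, disjoint halves give 0
  pos <- lapply(0:5, function(t) cbind(c(10, 30) + t, c(10, 30)))
  fr <- frames_from_positions(pos)
  trks <- link_tracks(fr, max_step = 3, geometry = geom_px1)
  expect_equal(cotrafficking_fraction(trks, trks, max_sep = 0.5,
                                      min_overlap_frames = 4,
                                      geometry = geom_px1), 1.0)
  far <- lapply(0:5, function(t) cbind(c(50, 60) + 0 * t, c(50, 60)))
  trks_far <- link_tracks(frames_from_positions(far), max_step = 3,
                          geometry = geom_px1)
  expect_equal(cotrafficking_fraction(trks, trks_far, max_sep = 2,
                                      min_overlap_frames = 4,
                                      geometry = geom_px1), 0.0)
  expect_error(cotrafficking_fraction(list(), trks, 1, 2, geom_px1), "empty")

  # end-to-end: paired granules co-move, unpaired do not
  tp <- sim_params(shape = c(1L, 128L, 128L), n_channels = 2L, n_puncta = 5L,
                   noise_sd = 0, background_gradient = 0, seed = 11)
  tl <- simulate_timelapse(tp, n_frames = 12, velocity_um_s = 0.176 / 5,
                           paired_fraction = 0.4, frame_interval_s = 5)
  g <- tl$frames[[1]]$geometry
  det <- function(chn) lapply(tl$frames, function(st)
    detect_puncta(st$channels[[chn]],
                  estimate_local_background(st$channels[[chn]], 31L),
                  channel_name = chn))
  ta <- link_tracks(det("ch1"), max_step = 0.5, geometry = g)
  tb <- link_tracks(det("ch2"), max_step = 0.5, geometry = g)
  expect_equal(cotrafficking_fraction(ta, tb, max_sep = 0.3,
                                      min_overlap_frames = 6, geometry = g),
               0.4)
})
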