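#' Parameters for the synthetic confocal simulator
#'
#' Describes an 8-bit multichannel acquisition of diffraction-limited puncta
#' over a spatially varying background, with a controllable fraction of
#' puncta co-positioned across channels. Defaults emulate a cortical-tissue
#' field: a 90 um square imaged at 512-px-equivalent lateral sampling
#' (0.176 um/px), 0.5 um optical sections, bright granules (amplitude 150 on
#' the 0-255 scale) over dim background (level 20) with mild detector noise.
#'
#' @param shape Integer `(z, y, x)` voxel counts.
#' @param n_channels 2 or 3.
#' @param n_puncta Puncta per channel.
#' @param coloc_fraction Fraction of each channel pair's puncta planted at
#'   shared positions, in [0, 1].
#' @param triple_fraction Fraction planted shared across all three channels
#'   (requires 3 channels; must not exceed `coloc_fraction`).
#' @param punctum_sigma In-plane Gaussian PSF width in px; the axial width is
#'   twice this (confocal anisotropy).
#' @param amplitude Peak intensity added by one punctum (must exceed
#'   `2 * noise_sd` for a solvable regime).
#' @param background_level Constant background intensity.
#' @param background_gradient Background slope in intensity per 100 px along
#'   x.
#' @param noise_sd Gaussian read-noise standard deviation.
#' @param pixel_size_um,z_interval_um Voxel calibration.
#' @param frame_interval_s Time between frames for time-lapse simulation.
#' @param seed Integer seed; identical parameters and seed give bit-identical
#'   output.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(shape = c(8L, 256L, 256L), n_channels = 3L,
                       n_puncta = 200L, coloc_fraction = 0.15,
                       triple_fraction = 0, punctum_sigma = 1.4,
                       amplitude = 150, background_level = 20,
                       background_gradient = 10, noise_sd = 8,
                       pixel_size_um = 0.176, z_interval_um = 0.5,
                       frame_interval_s = 5, seed = 1L) {
  stopifnot(length(shape) == 3L, all(shape >= 1L),
            n_channels %in% c(2L, 3L), n_puncta >= 1L)
  if (coloc_fraction < 0 || coloc_fraction > 1 ||
      triple_fraction < 0 || triple_fraction > 1)
    stop("fractions must lie in [0, 1]")
  if (triple_fraction > coloc_fraction)
    stop("'triple_fraction' cannot exceed 'coloc_fraction'")
  if (triple_fraction > 0 && n_channels < 3L)
    stop("triple co-localization needs 3 channels")
  if (noise_sd > 0 && amplitude <= 2 * noise_sd)
    stop("'amplitude' must exceed 2 * noise_sd")
  structure(list(shape = as.integer(shape), n_channels = as.integer(n_channels),
                 n_puncta = as.integer(n_puncta),
                 coloc_fraction = coloc_fraction,
                 triple_fraction = triple_fraction,
                 punctum_sigma = punctum_sigma, amplitude = amplitude,
                 background_level = background_level,
                 background_gradient = background_gradient,
                 noise_sd = noise_sd, pixel_size_um = pixel_size_um,
                 z_interval_um = z_interval_um,
                 frame_interval_s = frame_interval_s,
                 seed = as.integer(seed)),
            class = "sim_params")
}

# Rejection-sample `n` centers with pairwise separation >= min_sep (voxel
# units, z included) from existing ones, within the given margins.
place_centers <- function(n, shape, min_sep, margin_xy, margin_z,
                          existing = NULL) {
  nz <- shape[1]; ny <- shape[2]; nx <- shape[3]
  lo <- c(min(margin_z + 1, (nz + 1) / 2), margin_xy + 1, margin_xy + 1)
  hi <- c(max(nz - margin_z, (nz + 1) / 2), ny - margin_xy, nx - margin_xy)
  if (any(hi < lo)) stop("volume too small for the requested margins")
  pts <- if (is.null(existing)) matrix(numeric(0), 0L, 3L) else existing
  out <- matrix(numeric(0), 0L, 3L)
  attempts <- 0L
  while (nrow(out) < n) {
    attempts <- attempts + 1L
    if (attempts > 200L * n)
      stop("cannot place ", n, " puncta at minimum separation ", min_sep,
           "; the volume is too crowded")
    cand <- c(stats::runif(1, lo[1], hi[1]), stats::runif(1, lo[2], hi[2]),
              stats::runif(1, lo[3], hi[3]))
    if (nrow(pts) > 0L) {
      d2 <- (pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2 +
            (pts[, 3] - cand[3])^2
      if (min(d2) < min_sep^2) next
    }
    pts <- rbind(pts, cand)
    out <- rbind(out, cand)
  }
  out
}

# Add a 3D Gaussian punctum (in-plane sigma, axial 2*sigma) to array `a`.
render_punctum <- function(a, center, amplitude, sigma) {
  d <- dim(a)
  sz <- 2 * sigma
  rxy <- ceiling(4 * sigma); rz <- ceiling(4 * sz)
  zr <- max(1L, floor(center[1] - rz)):min(d[1], ceiling(center[1] + rz))
  yr <- max(1L, floor(center[2] - rxy)):min(d[2], ceiling(center[2] + rxy))
  xr <- max(1L, floor(center[3] - rxy)):min(d[3], ceiling(center[3] + rxy))
  gz <- exp(-((zr - center[1])^2) / (2 * sz^2))
  gy <- exp(-((yr - center[2])^2) / (2 * sigma^2))
  gx <- exp(-((xr - center[3])^2) / (2 * sigma^2))
  patch <- amplitude * outer(outer(gz, gy), gx)
  a[zr, yr, xr] <- a[zr, yr, xr, drop = FALSE] + patch
  a
}

#' Simulate a multichannel confocal stack with known ground truth
#'
#' Plants `ceiling(coloc_fraction * n_puncta)` shared sites per channel pair
#' (jitter below 0.5 px between partners; for three channels,
#' `ceiling(triple_fraction * n_puncta)` of these are shared by all three)
#' and fills each channel up to `n_puncta` with independently placed puncta.
#' Non-paired sites keep a minimum separation of 4 PSF widths so that chance
#' overlap does not contaminate the planted co-localization fraction. Each
#' punctum is rendered as a 3D Gaussian; a planar background gradient and
#' Gaussian read noise are added and the result is clamped to 8 bits.
#'
#' @param params A [sim_params()] object.
#' @return A list with `stack` (an [image_stack()], channels `ch1..chN`) and
#'   `truth`, an object of class `ground_truth`: per-channel `centroids`
#'   matrices (z, y, x), `pairings` (data frame `channel_a, index_a,
#'   channel_b, index_b, triple`), `n_puncta`, `params`.
#' @export
simulate_stack <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  p <- params
  nc <- p$n_channels
  sep <- 4 * p$punctum_sigma
  margin_xy <- ceiling(3 * p$punctum_sigma)
  margin_z <- min(ceiling(1.5 * p$punctum_sigma), (p$shape[1] - 1) %/% 2)

  pair_list <- utils::combn(nc, 2L, simplify = FALSE)
  n_pair <- ceiling(p$coloc_fraction * p$n_puncta)
  n_triple <- if (nc == 3L) ceiling(p$triple_fraction * p$n_puncta) else 0L
  n_pair_only <- n_pair - n_triple

  centers <- matrix(numeric(0), 0L, 3L)  # all base sites, for separation
  site_members <- list()                 # channels sharing each site
  add_sites <- function(n, members) {
    if (n <= 0L) return(invisible())
    new <- place_centers(n, p$shape, sep, margin_xy, margin_z, centers)
    centers <<- rbind(centers, new)
    for (i in seq_len(n))
      site_members[[length(site_members) + 1L]] <<-
        list(pos = new[i, ], channels = members)
  }
  if (n_triple > 0L) add_sites(n_triple, 1:3)
  for (pr in pair_list) add_sites(n_pair_only, pr)
  placed <- integer(nc)
  for (s in site_members)
    placed[s$channels] <- placed[s$channels] + 1L
  for (ci in seq_len(nc)) add_sites(p$n_puncta - placed[ci], ci)

  centroids <- lapply(seq_len(nc), function(ci)
    matrix(numeric(0), 0L, 3L, dimnames = list(NULL, c("z", "y", "x"))))
  site_index <- vector("list", length(site_members))
  for (si in seq_along(site_members)) {
    s <- site_members[[si]]
    idx <- integer(0)
    for (ci in s$channels) {
      jit <- stats::runif(3, -0.49, 0.49) *
        (if (length(s$channels) > 1L) 1 else 0)
      pos <- s$pos + jit
      centroids[[ci]] <- rbind(centroids[[ci]], pos)
      idx[as.character(ci)] <- nrow(centroids[[ci]])
    }
    site_index[[si]] <- idx
  }
  pairings <- do.call(rbind, lapply(seq_along(site_members), function(si) {
    chs <- site_members[[si]]$channels
    if (length(chs) < 2L) return(NULL)
    idx <- site_index[[si]]
    cmb <- utils::combn(chs, 2L)
    data.frame(channel_a = cmb[1, ], index_a = idx[as.character(cmb[1, ])],
               channel_b = cmb[2, ], index_b = idx[as.character(cmb[2, ])],
               triple = length(chs) == 3L)
  }))
  if (is.null(pairings))
    pairings <- data.frame(channel_a = integer(0), index_a = integer(0),
                           channel_b = integer(0), index_b = integer(0),
                           triple = logical(0))

  chans <- lapply(seq_len(nc), function(ci) {
    a <- array(0, dim = p$shape)
    cm <- centroids[[ci]]
    for (i in seq_len(nrow(cm)))
      a <- render_punctum(a, cm[i, ], p$amplitude, p$punctum_sigma)
    xg <- (seq_len(p$shape[3]) - 1) / 100 * p$background_gradient
    bg <- p$background_level +
      array(rep(xg, each = p$shape[1] * p$shape[2]), dim = p$shape)
    a <- a + bg
    if (p$noise_sd > 0)
      a <- a + array(stats::rnorm(prod(p$shape), 0, p$noise_sd),
                     dim = p$shape)
    array(pmin(pmax(round(a), 0), 255), dim = p$shape)
  })
  names(chans) <- paste0("ch", seq_len(nc))
  geom <- voxel_geometry(pixel_size_xy = p$pixel_size_um,
                         z_interval = p$z_interval_um,
                         field_size_xy = p$pixel_size_um * p$shape[3],
                         frame_interval = p$frame_interval_s)
  truth <- structure(list(centroids = centroids, pairings = pairings,
                          n_puncta = vapply(centroids, nrow, integer(1)),
                          params = p),
                     class = "ground_truth")
  list(stack = image_stack(chans, geometry = geom), truth = truth)
}

#' Expected directional percent co-localization of a simulation
#'
#' The recovery target for a planted simulation: for every ordered channel
#' pair, 100 times the number of planted pairings divided by the reference
#' channel's puncta count.
#'
#' @param gt A `ground_truth` from [simulate_stack()].
#' @return Data frame with columns `ref, target, percent`.
#' @export
expected_coloc <- function(gt) {
  stopifnot(inherits(gt, "ground_truth"))
  nc <- length(gt$centroids)
  out <- list()
  for (i in seq_len(nc)) for (j in seq_len(nc)) {
    if (i == j) next
    npair <- sum((gt$pairings$channel_a == i & gt$pairings$channel_b == j) |
                 (gt$pairings$channel_a == j & gt$pairings$channel_b == i))
    out[[length(out) + 1L]] <- data.frame(
      ref = paste0("ch", i), target = paste0("ch", j),
      percent = 100 * npair / gt$n_puncta[i])
  }
  do.call(rbind, out)
}

#' Simulate a two-channel time-lapse of moving granules
#'
#' Granules move with constant velocity in a random direction, plus optional
#' Gaussian positional jitter. A fraction of channel-1 granules is paired
#' with a co-moving channel-2 granule (emulating granule co-trafficking);
#' the remaining granules of each channel move independently. Paths that
#' would leave the field are truncated with a warning.
#'
#' @param params A [sim_params()]; `shape[2:3]` gives the frame size,
#'   `n_puncta` the granules per channel (single-plane imaging).
#' @param n_frames Number of frames (>= 2).
#' @param velocity_um_s Granule speed in um/s.
#' @param paired_fraction Fraction of channel-1 granules with a co-moving
#'   channel-2 partner.
#' @param frame_interval_s Seconds between frames (default from `params`).
#' @param jitter_sd_px Positional jitter SD in px per frame (default 0).
#' @return A list with `frames` (list of single-slice [image_stack()]s) and
#'   `truth` (class `ground_truth_timelapse`): per-channel `paths` (list of
#'   matrices `frame, y, x`), `pairings`, `velocity_um_s`, `params`.
#' @export
simulate_timelapse <- function(params, n_frames, velocity_um_s,
                               paired_fraction,
                               frame_interval_s = params$frame_interval_s,
                               jitter_sd_px = 0) {
  stopifnot(inherits(params, "sim_params"), n_frames >= 2L)
  if (paired_fraction < 0 || paired_fraction > 1)
    stop("'paired_fraction' must be in [0, 1]")
  set.seed(params$seed)
  p <- params
  ny <- p$shape[2]; nx <- p$shape[3]
  n <- p$n_puncta
  n_paired <- ceiling(paired_fraction * n)
  step_px <- velocity_um_s * frame_interval_s / p$pixel_size_um
  travel <- step_px * (n_frames - 1)
  # keep starts clear of the border and of each other for the whole travel,
  # as far as the field allows; longer paths truncate with a warning
  cap <- floor(min(ny, nx) / 4)
  guard <- min(ceiling(travel), cap)
  margin <- ceiling(3 * p$punctum_sigma) + guard
  sep <- 4 * p$punctum_sigma + guard

  shape2 <- c(1L, ny, nx)
  starts1 <- place_centers(n, shape2, sep, margin, 0)
  starts2_ind <- place_centers(n - n_paired, shape2, sep, margin, 0,
                               existing = starts1)
  theta <- stats::runif(n + (n - n_paired), 0, 2 * pi)

  path_of <- function(start_yx, ang) {
    fr <- seq_len(n_frames)
    y <- start_yx[1] + (fr - 1) * step_px * sin(ang)
    x <- start_yx[2] + (fr - 1) * step_px * cos(ang)
    if (jitter_sd_px > 0) {
      y <- y + stats::rnorm(n_frames, 0, jitter_sd_px)
      x <- x + stats::rnorm(n_frames, 0, jitter_sd_px)
    }
    inside <- y >= 1 & y <= ny & x >= 1 & x <= nx
    keep <- if (all(inside)) n_frames else {
      warning("granule leaves the field; path truncated")
      max(1L, which(!inside)[1] - 1L)
    }
    cbind(frame = fr[seq_len(keep)], y = y[seq_len(keep)],
          x = x[seq_len(keep)])
  }
  paths1 <- lapply(seq_len(n), function(i) path_of(starts1[i, 2:3], theta[i]))
  paths2 <- vector("list", n)
  for (i in seq_len(n_paired)) {
    off <- stats::runif(2, -0.49, 0.49)
    pp <- paths1[[i]]
    paths2[[i]] <- cbind(frame = pp[, 1], y = pp[, 2] + off[1],
                         x = pp[, 3] + off[2])
  }
  for (i in seq_len(n - n_paired)) {
    paths2[[n_paired + i]] <- path_of(starts2_ind[i, 2:3], theta[n + i])
  }

  render_frame <- function(fi) {
    chans <- lapply(list(paths1, paths2), function(paths) {
      a <- array(0, dim = c(1L, ny, nx))
      for (pp in paths) {
        row <- which(pp[, 1] == fi)
        if (length(row))
          a <- render_punctum(a, c(1, pp[row, 2], pp[row, 3]),
                              p$amplitude, p$punctum_sigma)
      }
      a <- a + p$background_level
      if (p$noise_sd > 0)
        a <- a + array(stats::rnorm(ny * nx, 0, p$noise_sd),
                       dim = c(1L, ny, nx))
      array(pmin(pmax(round(a), 0), 255), dim = c(1L, ny, nx))
    })
    names(chans) <- c("ch1", "ch2")
    image_stack(chans,
                geometry = voxel_geometry(p$pixel_size_um, 0,
                                          frame_interval = frame_interval_s))
  }
  frames <- lapply(seq_len(n_frames), render_frame)
  truth <- structure(list(paths = list(ch1 = paths1, ch2 = paths2),
                          pairings = data.frame(
                            index_a = seq_len(n_paired),
                            index_b = seq_len(n_paired)),
                          velocity_um_s = velocity_um_s,
                          frame_interval_s = frame_interval_s,
                          params = p),
                     class = "ground_truth_timelapse")
  list(frames = frames, truth = truth)
}
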