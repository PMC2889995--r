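#' Link puncta across time-lapse frames into tracks
#'
#' Greedy nearest-centroid linking: between consecutive frames, candidate
#' (track end, punctum) pairs are taken in order of increasing centroid
#' distance (ties broken by lower track id, then lower punctum id) and
#' accepted while both partners are unassigned and the step is at most
#' `max_step`. Unmatched puncta start new tracks; a missed frame terminates a
#' track (no gap tolerance). Tracking is 2D (single-plane time lapse).
#'
#' @param frames List of [detect_puncta()] results, one per frame, sharing
#'   the image shape.
#' @param max_step Maximum allowed frame-to-frame displacement in um.
#' @param geometry A [voxel_geometry()] carrying `pixel_size_xy` and,
#'   optionally, `frame_interval` (default 1 s) used to timestamp
#'   observations.
#' @return List of `track` objects: `track_id, channel, frames` (frame
#'   indices), `punctum_ids`, `centroids` (matrix of y, x in px), `times`
#'   (seconds).
#' @export
link_tracks <- function(frames, max_step, geometry) {
  if (length(frames) < 2L) stop("at least 2 frames are required")
  stopifnot(inherits(geometry, "voxel_geometry"))
  dt <- if (is.null(geometry$frame_interval)) 1 else geometry$frame_interval
  max_step_px <- max_step / geometry$pixel_size_xy
  cents <- lapply(frames, function(ps) {
    if (length(ps$puncta) == 0L)
      return(matrix(numeric(0), 0L, 2L))
    t(vapply(ps$puncta, function(p) p$centroid[c("y", "x")], numeric(2)))
  })
  ids <- lapply(frames, function(ps)
    vapply(ps$puncta, function(p) p$id, integer(1)))
  channel <- frames[[1]]$channel

  tracks <- list()       # finished + live track records
  live <- integer(0)     # indices into `tracks` extendable this frame
  new_track <- function(fi, pi) {
    tracks[[length(tracks) + 1L]] <<- list(
      frames = fi, punctum_ids = ids[[fi]][pi],
      centroids = cents[[fi]][pi, , drop = FALSE])
    length(tracks)
  }
  live <- vapply(seq_len(nrow(cents[[1]])), function(pi) new_track(1L, pi),
                 integer(1))
  for (fi in 2L:length(frames)) {
    np <- nrow(cents[[fi]])
    assigned_t <- logical(length(live)); assigned_p <- logical(np)
    if (length(live) > 0L && np > 0L) {
      ends <- t(vapply(live, function(ti) {
        cm <- tracks[[ti]]$centroids
        cm[nrow(cm), ]
      }, numeric(2)))
      cand <- expand.grid(ti = seq_along(live), pi = seq_len(np))
      cand$d <- sqrt((ends[cand$ti, 1] - cents[[fi]][cand$pi, 1])^2 +
                     (ends[cand$ti, 2] - cents[[fi]][cand$pi, 2])^2)
      cand <- cand[cand$d <= max_step_px, , drop = FALSE]
      cand <- cand[order(cand$d, cand$ti, ids[[fi]][cand$pi]), ,
                   drop = FALSE]
      for (r in seq_len(nrow(cand))) {
        ti <- cand$ti[r]; pi <- cand$pi[r]
        if (assigned_t[ti] || assigned_p[pi]) next
        assigned_t[ti] <- TRUE; assigned_p[pi] <- TRUE
        k <- live[ti]
        tracks[[k]]$frames <- c(tracks[[k]]$frames, fi)
        tracks[[k]]$punctum_ids <- c(tracks[[k]]$punctum_ids, ids[[fi]][pi])
        tracks[[k]]$centroids <- rbind(tracks[[k]]$centroids,
                                       cents[[fi]][pi, ])
      }
    }
    live <- c(live[assigned_t],
              vapply(which(!assigned_p), function(pi) new_track(fi, pi),
                     integer(1)))
  }
  lapply(seq_along(tracks), function(k) {
    tr <- tracks[[k]]
    structure(list(track_id = k, channel = channel, frames = tr$frames,
                   punctum_ids = tr$punctum_ids, centroids = tr$centroids,
                   times = (tr$frames - 1) * dt),
              class = "track")
  })
}

#' @export
print.track <- function(x, ...) {
  cat(sprintf("track %d (%s): %d observations, frames %d..%d\n",
              x$track_id, x$channel, length(x$frames), min(x$frames),
              max(x$frames)))
  invisible(x)
}

#' Total distance traveled by a tracked granule
#'
#' Sum of Euclidean centroid displacements between consecutive observations,
#' converted to um with the lateral pixel size.
#'
#' @param track A `track` from [link_tracks()] (or any list with a
#'   `centroids` matrix of at least 2 rows).
#' @param geometry A [voxel_geometry()].
#' @return Path length in um.
#' @export
track_distance <- function(track, geometry) {
  stopifnot(inherits(geometry, "voxel_geometry"))
  cm <- track$centroids
  if (is.null(cm) || nrow(cm) < 2L)
    stop("a track needs at least 2 observations")
  steps <- diff(cm)
  sum(sqrt(rowSums(steps^2))) * geometry$pixel_size_xy
}

#' Fraction of co-trafficking tracks
#'
#' A channel-a track co-traffics when some channel-b track stays within
#' `max_sep` of it for at least `min_overlap_frames` concurrent frames.
#'
#' @param tracks_a,tracks_b Lists of `track` objects sharing a time base;
#'   `tracks_a` must be non-empty.
#' @param max_sep Maximum centroid separation in um.
#' @param min_overlap_frames Minimum number of concurrent within-range
#'   frames.
#' @param geometry A [voxel_geometry()].
#' @return Fraction in [0, 1] of `tracks_a` that co-traffic.
#' @export
cotrafficking_fraction <- function(tracks_a, tracks_b, max_sep,
                                   min_overlap_frames, geometry) {
  if (length(tracks_a) == 0L) stop("'tracks_a' is empty")
  stopifnot(inherits(geometry, "voxel_geometry"))
  max_sep_px <- max_sep / geometry$pixel_size_xy
  hits <- vapply(tracks_a, function(ta) {
    for (tb in tracks_b) {
      common <- intersect(ta$frames, tb$frames)
      if (length(common) < min_overlap_frames) next
      ia <- match(common, ta$frames); ib <- match(common, tb$frames)
      dpx <- sqrt(rowSums((ta$centroids[ia, , drop = FALSE] -
                           tb$centroids[ib, , drop = FALSE])^2))
      if (sum(dpx <= max_sep_px) >= min_overlap_frames) return(TRUE)
    }
    FALSE
  }, logical(1))
  mean(hits)
}

#' Export tracks as a table
#'
#' @param tracks List of `track` objects.
#' @return Data frame with columns `track_id, channel, frame, t_s, y_px,
#'   x_px`.
#' @export
tracks_table <- function(tracks) {
  if (length(tracks) == 0L)
    return(data.frame(track_id = integer(0), channel = character(0),
                      frame = integer(0), t_s = numeric(0),
                      y_px = numeric(0), x_px = numeric(0)))
  do.call(rbind, lapply(tracks, function(tr)
    data.frame(track_id = tr$track_id, channel = tr$channel,
               frame = tr$frames, t_s = tr$times,
               y_px = tr$centroids[, 1], x_px = tr$centroids[, 2])))
}
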