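#' Fractional overlap between two puncta
#'
#' The number of shared voxels divided by the size of the smaller punctum.
#' Normalising by the smaller object makes the criterion symmetric and counts
#' a small granule sitting inside a larger protein cluster as fully
#' overlapping.
#'
#' @param a,b Puncta (elements of a [detect_puncta()] result) from different
#'   channels over the same image shape.
#' @return Overlap fraction in [0, 1].
#' @export
overlap_fraction <- function(a, b) {
  if (identical(a$channel, b$channel))
    stop("overlap is defined between puncta of different channels")
  length(intersect(a$voxels, b$voxels)) / min(length(a$voxels),
                                              length(b$voxels))
}

#' Object-pair co-localization decision
#'
#' Two puncta are co-localized when their fractional overlap strictly exceeds
#' the threshold; the conventional criterion is greater than 30%. Too little
#' overlap is not regarded as co-localization.
#'
#' @inheritParams overlap_fraction
#' @param threshold Fraction in [0, 1).
#' @return Logical.
#' @export
is_colocalized <- function(a, b, threshold = 0.30) {
  if (threshold < 0 || threshold >= 1) stop("'threshold' must be in [0, 1)")
  overlap_fraction(a, b) > threshold
}

# Map voxel linear index -> punctum id over the full volume (puncta within a
# set are disjoint, so the map is well defined).
voxel_id_map <- function(ps) {
  m <- integer(prod(ps$dim))
  for (p in ps$puncta) m[p$voxels] <- p$id
  m
}

#' Directional percent co-localization of two puncta sets
#'
#' Each reference punctum counts as one co-localization event when it is
#' co-localized (fractional overlap strictly above `threshold`) with at least
#' one target punctum. Percent co-localization is 100 times the events
#' divided by the number of reference puncta; it is directional, so A vs B
#' generally differs from B vs A.
#'
#' @param ref,target [detect_puncta()] results for two channels over the same
#'   image shape; `ref` must be non-empty.
#' @param threshold Overlap fraction threshold (default 0.30).
#' @return An object of class `coloc_result`: `ref_channel, target_channel,
#'   n_ref_events, n_coloc_events, percent`, and `pairs`, a data frame of
#'   qualifying (ref_id, target_id, overlap) pairs.
#' @export
percent_colocalization <- function(ref, target, threshold = 0.30) {
  stopifnot(inherits(ref, "puncta_set"), inherits(target, "puncta_set"))
  if (!identical(ref$dim, target$dim)) stop("image shapes differ")
  if (identical(ref$channel, target$channel))
    stop("'ref' and 'target' must be different channels")
  if (threshold < 0 || threshold >= 1) stop("'threshold' must be in [0, 1)")
  if (length(ref$puncta) == 0L) stop("reference set is empty")
  sizes_t <- vapply(target$puncta, function(p) p$n, numeric(1))
  idmap <- voxel_id_map(target)
  pr <- list(); k <- 0L; events <- 0L
  for (p in ref$puncta) {
    hit <- idmap[p$voxels]
    hit <- hit[hit > 0L]
    if (length(hit)) {
      tb <- table(hit)
      tid <- as.integer(names(tb))
      ov <- as.integer(tb) / pmin(p$n, sizes_t[tid])
      qual <- ov > threshold
      if (any(qual)) {
        events <- events + 1L
        for (j in which(qual)) {
          k <- k + 1L
          pr[[k]] <- data.frame(ref_id = p$id, target_id = tid[j],
                                overlap = ov[j])
        }
      }
    }
  }
  pairs <- if (k > 0L) do.call(rbind, pr) else
    data.frame(ref_id = integer(0), target_id = integer(0),
               overlap = numeric(0))
  structure(list(ref_channel = ref$channel, target_channel = target$channel,
                 n_ref_events = length(ref$puncta),
                 n_coloc_events = events,
                 percent = 100 * events / length(ref$puncta),
                 pairs = pairs, threshold = threshold),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("%s vs %s: %d / %d co-localized (%.1f%%, overlap > %d%%)\n",
              x$ref_channel, x$target_channel, x$n_coloc_events,
              x$n_ref_events, x$percent, round(100 * x$threshold)))
  invisible(x)
}

#' Triple co-localization across three channels
#'
#' A punctum of the first set counts toward the triple tally when it is
#' pairwise co-localized with at least one punctum of each of the other two
#' sets. Per-pair directional results are returned alongside. Double percent
#' co-localization is well defined per pair; the triple tally is a count.
#'
#' @param a,b,c [detect_puncta()] results for three distinct channels.
#' @param threshold Overlap fraction threshold (default 0.30).
#' @return An object of class `triple_coloc_result`: `channels`, `n_triple`,
#'   `triple_ids` (ids in `a`), and `per_pair`, a list of the
#'   [percent_colocalization()] results a-b, a-c, b-c.
#' @export
triple_colocalization <- function(a, b, c, threshold = 0.30) {
  chans <- c(a$channel, b$channel, c$channel)
  if (anyDuplicated(chans)) stop("the three sets must be distinct channels")
  safe_pc <- function(r, t) if (length(r$puncta) == 0L) NULL else
    percent_colocalization(r, t, threshold)
  ab <- safe_pc(a, b)
  ac <- safe_pc(a, c)
  bc <- safe_pc(b, c)
  with_b <- if (is.null(ab)) integer(0) else unique(ab$pairs$ref_id)
  with_c <- if (is.null(ac)) integer(0) else unique(ac$pairs$ref_id)
  triple_ids <- intersect(with_b, with_c)
  structure(list(channels = chans, n_triple = length(triple_ids),
                 triple_ids = sort(triple_ids),
                 per_pair = list(ab = ab, ac = ac, bc = bc),
                 threshold = threshold),
            class = "triple_coloc_result")
}

#' @export
print.triple_coloc_result <- function(x, ...) {
  cat(sprintf("triple co-localization %s: %d puncta\n",
              paste(x$channels, collapse = "/"), x$n_triple))
  for (p in x$per_pair) if (!is.null(p)) print(p)
  invisible(x)
}

#' Intensity profile along a line
#'
#' Samples every channel of a stack along the Bresenham rasterization of the
#' segment from `p0` to `p1` within one z-slice, as drawn across a merged
#' image to compare channel intensities at candidate co-localization sites.
#'
#' @param stack An [image_stack()].
#' @param p0,p1 Length-2 integer vectors `(y, x)`, 1-based, inside the image.
#' @param z Slice index (default 1).
#' @return A data frame with columns `step, y, x` and one intensity column
#'   per channel; all channels share the same sampling points.
#' @export
line_intensity_profile <- function(stack, p0, p1, z = 1L) {
  stopifnot(inherits(stack, "image_stack"),
            length(p0) == 2L, length(p1) == 2L)
  d <- stack$dim
  z <- as.integer(z)
  if (z < 1L || z > d[1]) stop("slice index out of bounds")
  pts <- rbind(as.integer(p0), as.integer(p1))
  if (any(pts[, 1] < 1L) || any(pts[, 1] > d[2]) ||
      any(pts[, 2] < 1L) || any(pts[, 2] > d[3]))
    stop("endpoint outside the image")
  seg <- bresenham(pts[1, ], pts[2, ])
  out <- data.frame(step = seq_len(nrow(seg)), y = seg[, 1], x = seg[, 2])
  for (nm in names(stack$channels)) {
    a <- stack$channels[[nm]]
    out[[nm]] <- a[cbind(z, seg[, 1], seg[, 2])]
  }
  out
}

# Integer Bresenham line from (y0, x0) to (y1, x1), inclusive.
bresenham <- function(p0, p1) {
  y0 <- p0[1]; x0 <- p0[2]; y1 <- p1[1]; x1 <- p1[2]
  dy <- abs(y1 - y0); dx <- abs(x1 - x0)
  sy <- sign(y1 - y0); sx <- sign(x1 - x0)
  n <- max(dx, dy) + 1L
  out <- matrix(0L, n, 2L)
  err <- dx - dy
  y <- y0; x <- x0
  for (i in seq_len(n)) {
    out[i, ] <- c(y, x)
    if (y == y1 && x == x1) { out <- out[seq_len(i), , drop = FALSE]; break }
    e2 <- 2L * err
    if (e2 > -dy) { err <- err - dy; x <- x + sx }
    if (e2 < dx) { err <- err + dx; y <- y + sy }
  }
  out
}
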