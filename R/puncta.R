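#' Local background model of a fluorescence channel
#'
#' Moving mean and moving standard deviation over a square `window x window`
#' neighbourhood, computed per z-slice with symmetric (mirror) padding at the
#' borders. A punctum is later defined as a region whose intensity exceeds
#' this local mean plus two local standard deviations.
#'
#' The window should be much larger than a punctum diameter but smaller than
#' the scale over which tissue background varies; the pipeline default is
#' 31 px. The standard deviation uses the sample (n - 1) convention.
#'
#' @param channel 2D matrix or 3D `[z, y, x]` array of intensities.
#' @param window Odd window side length in px, >= 3 and at most the smallest
#'   spatial dimension.
#' @return An object of class `background_model` with `mean_map`, `sd_map`
#'   (same shape as `channel`) and `window`.
#' @export
estimate_local_background <- function(channel, window = 31L) {
  a <- as_zyx(channel)
  d <- dim(a)
  window <- as.integer(window)
  if (window %% 2L == 0L || window < 3L || window > min(d[2], d[3]))
    stop("'window' must be odd, >= 3 and <= the smallest spatial dimension")
  mean_map <- array(0, d); sd_map <- array(0, d)
  for (z in seq_len(d[1])) {
    st <- box_stats(a[z, , ], window)
    mean_map[z, , ] <- st$mean
    sd_map[z, , ] <- st$sd
  }
  if (is.matrix(channel)) {
    mean_map <- mean_map[1, , ]; sd_map <- sd_map[1, , ]
  }
  structure(list(mean_map = mean_map, sd_map = sd_map, window = window),
            class = "background_model")
}

# Symmetric-padding index vector: h reflected samples on each side.
mirror_idx <- function(n, h) {
  c(seq.int(h, 1L), seq_len(n), seq.int(n, n - h + 1L))
}

# Moving mean / sample sd over a w x w box via summed-area tables.
box_stats <- function(m, w) {
  h <- (w - 1L) %/% 2L
  p <- m[mirror_idx(nrow(m), h), mirror_idx(ncol(m), h)]
  n <- as.numeric(w) * w
  boxsum <- function(x) {
    s <- apply(x, 2L, cumsum)
    s <- t(apply(s, 1L, cumsum))
    s0 <- rbind(0, cbind(0, s))
    ri <- seq_len(nrow(m)); ci <- seq_len(ncol(m))
    s0[ri + w, ci + w, drop = FALSE] + s0[ri, ci, drop = FALSE] -
      s0[ri + w, ci, drop = FALSE] - s0[ri, ci + w, drop = FALSE]
  }
  s1 <- boxsum(p)
  s2 <- boxsum(p * p)
  mu <- s1 / n
  va <- (s2 - n * mu^2) / (n - 1)
  list(mean = mu, sd = sqrt(pmax(va, 0)))
}

# Label connected components of a logical [z, y, x] mask by breadth-first
# flood fill. connectivity "face" = 6-neighbour in 3D (4 in-plane for a
# single slice), "full" = 26-neighbour.
label_components <- function(mask, connectivity = c("face", "full")) {
  connectivity <- match.arg(connectivity)
  d <- dim(mask)
  off <- if (connectivity == "face") {
    rbind(c(-1L, 0L, 0L), c(1L, 0L, 0L), c(0L, -1L, 0L),
          c(0L, 1L, 0L), c(0L, 0L, -1L), c(0L, 0L, 1L))
  } else {
    g <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
    g[rowSums(g != 0L) > 0L, , drop = FALSE]
  }
  lab <- array(0L, d)
  seeds <- which(mask)
  if (length(seeds) == 0L) return(lab)
  next_label <- 0L
  for (s in seeds) {
    if (lab[s] != 0L) next
    next_label <- next_label + 1L
    lab[s] <- next_label
    frontier <- arrayInd(s, d)
    while (nrow(frontier) > 0L) {
      nb <- do.call(rbind, lapply(seq_len(nrow(off)), function(k)
        sweep(frontier, 2L, off[k, ], "+")))
      keep <- nb[, 1] >= 1L & nb[, 1] <= d[1] &
              nb[, 2] >= 1L & nb[, 2] <= d[2] &
              nb[, 3] >= 1L & nb[, 3] <= d[3]
      nb <- nb[keep, , drop = FALSE]
      if (nrow(nb) == 0L) break
      lin <- nb[, 1] + (nb[, 2] - 1L) * d[1] + (nb[, 3] - 1L) * d[1] * d[2]
      lin <- unique(lin[mask[lin] & lab[lin] == 0L])
      if (length(lin) == 0L) break
      lab[lin] <- next_label
      frontier <- arrayInd(lin, d)
    }
  }
  lab
}

#' Detect fluorescent puncta by local-background thresholding
#'
#' A voxel belongs to the foreground when its intensity is strictly greater
#' than the local background mean plus two local standard deviations.
#' Connected foreground components of at least `min_size` voxels become
#' puncta, with intensity-weighted centroids.
#'
#' @param channel 2D matrix or 3D `[z, y, x]` array.
#' @param bg A [estimate_local_background()] model of the same shape.
#' @param min_size Minimum component size in voxels (default 4, suppressing
#'   single-voxel noise).
#' @param connectivity `"face"` (6-neighbour in 3D, 4 in 2D; the default,
#'   splitting adjacent granules conservatively) or `"full"` (26-neighbour).
#' @param channel_name Name recorded on the result.
#' @return An object of class `puncta_set`: a list with `puncta` (each a list
#'   `id, channel, voxels` (linear indices), `n`, `centroid` (z, y, x),
#'   `peak`), `channel`, `dim`, `params`.
#' @export
detect_puncta <- function(channel, bg, min_size = 4L,
                          connectivity = c("face", "full"),
                          channel_name = "ch1") {
  connectivity <- match.arg(connectivity)
  a <- as_zyx(channel)
  mu <- as_zyx(bg$mean_map); sg <- as_zyx(bg$sd_map)
  if (!identical(dim(a), dim(mu)) || !identical(dim(a), dim(sg)))
    stop("background model shape does not match the channel")
  mask <- a > mu + 2 * sg
  lab <- label_components(mask, connectivity)
  d <- dim(a)
  puncta <- list()
  if (any(lab > 0L)) {
    vox <- which(lab > 0L)
    grp <- split(vox, lab[vox])
    id <- 0L
    for (g in grp) {
      if (length(g) < min_size) next
      id <- id + 1L
      co <- arrayInd(g, d)
      wts <- a[g]
      ctr <- colSums(co * wts) / sum(wts)
      puncta[[id]] <- list(id = id, channel = channel_name, voxels = g,
                           n = length(g),
                           centroid = stats::setNames(ctr, c("z", "y", "x")),
                           peak = max(a[g]))
    }
  }
  structure(list(puncta = puncta, channel = channel_name, dim = d,
                 params = list(min_size = as.integer(min_size),
                               connectivity = connectivity,
                               window = bg$window)),
            class = "puncta_set")
}

#' @export
print.puncta_set <- function(x, ...) {
  cat(sprintf("puncta_set: %d puncta in channel '%s' (%s voxels)\n",
              length(x$puncta), x$channel, paste(x$dim, collapse = " x ")))
  invisible(x)
}

#' @export
length.puncta_set <- function(x) length(x$puncta)

#' Tabulate a set of puncta
#'
#' @param x A `puncta_set`.
#' @param row.names,optional,... Passed through for S3 compatibility; unused.
#' @return A data frame with columns `id, channel, z, y, x, size_voxels,
#'   peak` (centroid coordinates in pixel units).
#' @export
as.data.frame.puncta_set <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  if (length(x$puncta) == 0L)
    return(data.frame(id = integer(0), channel = character(0),
                      z = numeric(0), y = numeric(0), x = numeric(0),
                      size_voxels = integer(0), peak = numeric(0)))
  do.call(rbind, lapply(x$puncta, function(p)
    data.frame(id = p$id, channel = p$channel,
               z = p$centroid[["z"]], y = p$centroid[["y"]],
               x = p$centroid[["x"]], size_voxels = p$n, peak = p$peak)))
}

#' Estimate total event count by grid averaging
#'
#' Events counted in a sample of grid squares are extrapolated to the full
#' grid: total = mean count per sampled square times the number of squares.
#'
#' @param counts Numeric vector of per-square event counts (>= 1 square).
#' @param n_squares Total number of squares, at least `length(counts)`.
#' @return Estimated total event count.
#' @examples
#' count_total_events(c(2, 4), 6)  # 18
#' @export
count_total_events <- function(counts, n_squares) {
  if (length(counts) < 1L) stop("at least one sampled square is required")
  if (n_squares < length(counts))
    stop("'n_squares' must be at least the number of sampled squares")
  mean(counts) * n_squares
}
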