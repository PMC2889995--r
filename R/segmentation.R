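#' The seven edge vectors of the RGB color cube
#'
#' Vector-angle segmentation classifies each pixel of a three-channel
#' composite into one of seven color classes by picking the minimal angular
#' deviation between the pixel's RGB vector and seven reference "edge"
#' vectors: the three primaries (single targets), the three secondaries
#' (pairwise overlap) and white (255, 255, 255), the additive product of all
#' three channels (triple overlap). The order returned here is the fixed
#' tie-breaking order used throughout.
#'
#' @return A 7 x 3 numeric matrix, rows named
#'   `red, green, blue, yellow, magenta, cyan, white`, columns `R, G, B`.
#' @export
edge_vectors <- function() {
  m <- rbind(red     = c(255, 0, 0),
             green   = c(0, 255, 0),
             blue    = c(0, 0, 255),
             yellow  = c(255, 255, 0),
             magenta = c(255, 0, 255),
             cyan    = c(0, 255, 255),
             white   = c(255, 255, 255))
  colnames(m) <- c("R", "G", "B")
  m
}

#' Angular deviation between two RGB vectors
#'
#' The angle, in degrees, between a pixel's RGB vector and an edge vector:
#' `acos` of their cosine similarity. For non-negative vectors the result
#' lies in [0, 90].
#'
#' @param pixel,edge Numeric length-3 RGB vectors with positive norm.
#' @return Angle in degrees.
#' @export
angular_deviation <- function(pixel, edge) {
  stopifnot(length(pixel) == 3L, length(edge) == 3L)
  np <- sqrt(sum(pixel^2)); ne <- sqrt(sum(edge^2))
  if (np == 0 || ne == 0)
    stop("angular deviation is undefined for a zero-norm vector")
  cosv <- sum(pixel * edge) / (np * ne)
  acos(min(1, max(-1, cosv))) * 180 / pi
}

# Vectorised classifier: rows of `v` (n x 3, RGB) -> integer codes 1..7 into
# edge_vectors() order, 0 for zero-norm rows. Ties within `tol` on the cosine
# go to the earliest class in the fixed order.
classify_rgb <- function(v, tol = 1e-9) {
  ev <- edge_vectors()
  evn <- ev / sqrt(rowSums(ev^2))
  nrm <- sqrt(rowSums(v^2))
  code <- integer(nrow(v))
  ok <- nrm > 0
  if (any(ok)) {
    cosm <- (v[ok, , drop = FALSE] %*% t(evn)) / nrm[ok]
    best <- cosm[, 1]
    for (j in 2:7) best <- pmax(best, cosm[, j])
    pick <- integer(sum(ok))
    for (j in 7:1) pick[cosm[, j] >= best - tol] <- j
    code[ok] <- pick
  }
  code
}

#' Classify a single RGB pixel into one of seven color classes
#'
#' Assigns the class whose edge vector has minimal angular deviation from the
#' pixel vector. Ties (within a 1e-9 cosine tolerance) are broken by the
#' fixed order of [edge_vectors()]; a zero pixel, where the angle is
#' undefined, is returned as `"unclassified"`.
#'
#' @param pixel Numeric length-3 RGB vector with components in [0, 255].
#' @return One of `"red", "green", "blue", "yellow", "magenta", "cyan",
#'   "white", "unclassified"`.
#' @examples
#' segment_pixel(c(255, 0, 0))    # "red"
#' segment_pixel(c(100, 100, 100))  # any gray is parallel to white
#' @export
segment_pixel <- function(pixel) {
  stopifnot(is.numeric(pixel), length(pixel) == 3L)
  if (any(!is.finite(pixel)) || any(pixel < 0) || any(pixel > 255))
    stop("pixel components must lie in [0, 255]")
  code <- classify_rgb(matrix(pixel, 1L, 3L))
  if (code == 0L) "unclassified" else rownames(edge_vectors())[code]
}

#' Seven-color segmentation of a three-channel composite
#'
#' Every pixel whose (post-subtraction) RGB vector norm exceeds
#' `background_threshold` is assigned to the color class of minimal angular
#' deviation; the rest are left unclassified. The result carries seven binary
#' pseudo-channel masks that are pairwise disjoint and jointly cover exactly
#' the classified pixels.
#'
#' @param composite An [image_stack()] with exactly three channels (taken as
#'   R, G, B in order), or a list of three equal-shape arrays.
#' @param background_threshold Pixels with vector norm at or below this value
#'   are unclassified. Default 0, i.e. only exact-zero pixels are excluded;
#'   raise it if background was not subtracted beforehand (see
#'   [subtract_background()]).
#' @return An object of class `segmentation_map`: `labels` (integer array,
#'   0 = unclassified, 1..7 indexing `classes`), `classes` (the seven class
#'   names), `pseudo_channels` (named list of logical arrays), `dim`.
#' @export
segment_image <- function(composite, background_threshold = 0) {
  if (inherits(composite, "image_stack")) {
    chans <- composite$channels
  } else if (is.list(composite)) {
    chans <- lapply(composite, as_zyx)
  } else stop("'composite' must be an image_stack or a list of 3 arrays")
  if (length(chans) != 3L)
    stop("seven-color segmentation needs exactly 3 channels, got ",
         length(chans))
  d <- dim(chans[[1]])
  if (!all(vapply(chans, function(a) identical(dim(a), d), logical(1))))
    stop("channel shapes differ")
  v <- cbind(as.vector(chans[[1]]), as.vector(chans[[2]]),
             as.vector(chans[[3]]))
  nrm <- sqrt(rowSums(v^2))
  code <- classify_rgb(v)
  code[nrm <= background_threshold] <- 0L
  labels <- array(code, dim = d)
  classes <- rownames(edge_vectors())
  pseudo <- lapply(seq_along(classes), function(j) array(code == j, dim = d))
  names(pseudo) <- classes
  structure(list(labels = labels, classes = classes,
                 pseudo_channels = pseudo, dim = d),
            class = "segmentation_map")
}

#' @export
print.segmentation_map <- function(x, ...) {
  counts <- vapply(x$pseudo_channels, sum, numeric(1))
  cat("segmentation_map over", paste(x$dim, collapse = " x "), "voxels\n")
  print(c(counts, unclassified = sum(x$labels == 0L)))
  invisible(x)
}

#' Subtract image background
#'
#' Two estimators are offered. `constant_percentile` subtracts a global
#' intensity percentile (a flat dark-level estimate) and clamps at zero.
#' `rolling_ball` removes smoothly varying background as the residue of a
#' grayscale morphological opening with a disc structuring element, applied
#' per z-slice.
#'
#' @param channel A 2D matrix or 3D `[z, y, x]` array of intensities.
#' @param method `"constant_percentile"` or `"rolling_ball"`.
#' @param param Percentile in [0, 100], or ball (disc) radius in px (> 0).
#' @return Array of the same shape, non-negative.
#' @export
subtract_background <- function(channel,
                                method = c("constant_percentile",
                                           "rolling_ball"),
                                param) {
  method <- match.arg(method)
  a <- as_zyx(channel)
  out <- switch(method,
    constant_percentile = {
      if (param < 0 || param > 100) stop("percentile must be in [0, 100]")
      q <- stats::quantile(a, param / 100, names = FALSE)
      pmax(a - q, 0)
    },
    rolling_ball = {
      if (param <= 0) stop("ball radius must be > 0")
      sz <- 2L * as.integer(ceiling(param)) + 1L
      brush <- EBImage::makeBrush(sz, shape = "disc")
      r <- a
      for (z in seq_len(dim(a)[1])) {
        sl <- a[z, , ]
        mx <- max(sl, 1)  # morphology expects [0, 1]; scaling is exact
        opened <- EBImage::opening(sl / mx, brush) * mx
        r[z, , ] <- pmax(sl - opened, 0)
      }
      r
    })
  if (is.matrix(channel)) out[1, , ] else out
}
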