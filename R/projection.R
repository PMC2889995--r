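#' Maximum-intensity projection along z
#'
#' Each output pixel is the maximum over the optical sections, computed per
#' channel independently.
#'
#' @param stack An [image_stack()] with at least one slice.
#' @return Named list of 2D `[y, x]` matrices, one per channel.
#' @export
max_projection <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  if (stack$dim[1] < 1L) stop("empty stack")
  lapply(stack$channels, function(a) {
    m <- a[1, , ]
    nz <- dim(a)[1]
    if (nz > 1L) for (z in 2:nz) m <- pmax(m, a[z, , ])
    m
  })
}

#' Rotation series of brightest-point projections
#'
#' Renders a z-stack as a series of brightest-point (maximum) projections
#' viewed at successive rotation angles about the y-axis. Before rotation the
#' z-axis is rescaled to lateral-pixel units using [slice_spacing()], so the
#' rendered volume is isotropic. The 0-degree frame (and any multiple of
#' 360) is the plain z maximum projection, computed exactly.
#'
#' @param stack An [image_stack()] with at least 2 slices and a geometry
#'   carrying `z_interval` and `field_size_xy`.
#' @param axis Rotation axis; only `"y"` is supported.
#' @param n_views Number of frames (default 64).
#' @param angle_increment Degrees between frames (default 10).
#' @param interpolate Trilinear interpolation when `TRUE` (default);
#'   nearest-neighbour otherwise.
#' @param depth_cue Linear intensity attenuation along the viewing axis in
#'   [0, 1]; 0 (default) disables depth cueing, which is cosmetic only.
#' @return An object of class `projection_series`: `frames` (list of
#'   per-channel 2D matrix lists), `angles` (degrees), `axis`,
#'   `slice_spacing_px`.
#' @export
rotation_series <- function(stack, axis = "y", n_views = 64L,
                            angle_increment = 10, interpolate = TRUE,
                            depth_cue = 0) {
  stopifnot(inherits(stack, "image_stack"))
  if (!identical(axis, "y")) stop("only rotation about the y-axis is supported")
  if (stack$dim[1] < 2L) stop("rotation needs at least 2 slices")
  g <- stack$geometry
  if (is.null(g) || is.null(g$field_size_xy) || g$z_interval <= 0)
    stop("stack geometry with z_interval and field_size_xy is required")
  s <- slice_spacing(stack$dim[3], g$z_interval, g$field_size_xy)
  angles <- (seq_len(n_views) - 1L) * angle_increment
  mip <- max_projection(stack)
  frames <- lapply(angles, function(theta) {
    if (theta %% 360 == 0) return(mip)
    lapply(stack$channels, function(a)
      rotated_mip(a, s, theta, interpolate, depth_cue))
  })
  structure(list(frames = frames, angles = angles, axis = axis,
                 slice_spacing_px = s),
            class = "projection_series")
}

#' @export
print.projection_series <- function(x, ...) {
  cat(sprintf("projection_series: %d frame(s), %g deg increment, slice spacing %.2f px\n",
              length(x$frames), if (length(x$angles) > 1)
                diff(x$angles[1:2]) else 0, x$slice_spacing_px))
  invisible(x)
}

# Brightest-point projection of one channel viewed at `theta` degrees about
# the y-axis. The volume lives in (x, zs) with zs = (z - 1) * s; the viewing
# ray grid (u = output x offset, d = depth) is rotated into volume
# coordinates, shared by every y row.
rotated_mip <- function(a, s, theta, interpolate = TRUE, depth_cue = 0) {
  d3 <- dim(a); nz <- d3[1]; ny <- d3[2]; nx <- d3[3]
  th <- theta * pi / 180
  cx <- (nx + 1) / 2
  cz <- (nz - 1) * s / 2            # zs ranges over [0, (nz-1)*s]
  zext <- (nz - 1) * s + 1
  dmax <- ceiling(sqrt(nx^2 + zext^2) / 2)  # integer grid: axis-aligned
  depths <- seq(-dmax, dmax, by = 1)        # views sample voxel planes
  u <- seq_len(nx) - cx
  out <- matrix(0, ny, nx)
  yidx <- (seq_len(ny) - 1L) * nz
  for (i in seq_along(depths)) {
    dd <- depths[i]
    xs <- cos(th) * u - sin(th) * dd + cx
    zs <- (sin(th) * u + cos(th) * dd + cz) / s + 1
    if (interpolate) {
      x0 <- floor(xs); z0 <- floor(zs)
      fx <- xs - x0; fz <- zs - z0
      plane <- matrix(0, ny, nx)
      for (corner in list(c(0, 0), c(0, 1), c(1, 0), c(1, 1))) {
        xi <- x0 + corner[1]; zi <- z0 + corner[2]
        wt <- (if (corner[1] == 1) fx else 1 - fx) *
              (if (corner[2] == 1) fz else 1 - fz)
        ok <- xi >= 1 & xi <= nx & zi >= 1 & zi <= nz & wt > 0
        if (!any(ok)) next
        lin <- outer(yidx, zi + (xi - 1) * nz * ny, "+")  # ny x nx
        vals <- matrix(0, ny, nx)
        vals[, ok] <- a[as.vector(lin[, ok, drop = FALSE])]
        plane <- plane + sweep(vals, 2L, ifelse(ok, wt, 0), "*")
      }
    } else {
      xi <- round(xs); zi <- round(zs)
      ok <- xi >= 1 & xi <= nx & zi >= 1 & zi <= nz
      plane <- matrix(0, ny, nx)
      if (any(ok)) {
        lin <- outer(yidx, zi + (xi - 1) * nz * ny, "+")
        plane[, ok] <- a[as.vector(lin[, ok, drop = FALSE])]
      }
    }
    if (depth_cue > 0) {
      atten <- 1 - depth_cue * (dd + dmax) / (2 * dmax)
      plane <- plane * atten
    }
    out <- pmax(out, plane)
  }
  out
}

#' Write a projection series to multipage TIFF
#'
#' One file per channel, frames in rotation order. Intensities are rounded
#' and clamped to the declared bit depth.
#'
#' @param series A [rotation_series()] result.
#' @param out_dir Output directory (created if absent).
#' @param prefix Filename prefix (default `"rot_"`).
#' @param bits_per_sample 8 or 16.
#' @return Named character vector of paths, invisibly.
#' @export
write_projection_series <- function(series, out_dir, prefix = "rot_",
                                    bits_per_sample = 8L) {
  stopifnot(inherits(series, "projection_series"))
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create directory: ", out_dir)
  top <- 2^bits_per_sample - 1
  chans <- names(series$frames[[1]])
  paths <- character(0)
  for (ch in chans) {
    pages <- lapply(series$frames, function(fr)
      pmin(pmax(round(fr[[ch]]), 0), top) / top)
    p <- file.path(out_dir, paste0(prefix, ch, ".tif"))
    tiff::writeTIFF(pages, p, bits.per.sample = bits_per_sample,
                    compression = "none")
    paths[ch] <- p
  }
  invisible(paths)
}
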