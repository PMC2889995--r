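#' Multichannel image stack
#'
#' Container for a fixed- or live-imaging acquisition: one intensity array per
#' channel, all of identical shape, indexed `[z, y, x]` (1-based; a 2D matrix
#' is promoted to a single-slice stack), plus the voxel geometry and an
#' optional role tag per channel (e.g. `mRNA`, `protein_1`).
#'
#' @param channels Named list of numeric arrays, each `[z, y, x]` or a 2D
#'   `[y, x]` matrix. Names must be unique and non-empty.
#' @param geometry A [voxel_geometry()], or `NULL`.
#' @param roles Optional named character vector mapping channel names to role
#'   tags.
#' @return An object of class `image_stack` with elements `channels`,
#'   `geometry`, `roles`, `dim` (`c(z, y, x)`).
#' @export
image_stack <- function(channels, geometry = NULL, roles = NULL) {
  if (!is.list(channels) || length(channels) < 1L)
    stop("'channels' must be a non-empty list of arrays")
  nm <- names(channels)
  if (is.null(nm) || any(!nzchar(nm)) || anyDuplicated(nm))
    stop("channels must have unique non-empty names")
  channels <- lapply(channels, as_zyx)
  dims <- lapply(channels, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("all channels must share an identical shape")
  if (!is.null(geometry))
    validate_geometry(geometry, dims[[1]][3])
  if (!is.null(roles)) {
    if (is.null(names(roles)) || !all(names(roles) %in% nm))
      stop("'roles' must be named by channel")
  }
  structure(list(channels = channels, geometry = geometry, roles = roles,
                 dim = dims[[1]]),
            class = "image_stack")
}

# Promote a 2D [y, x] matrix to a [1, y, x] array; pass 3D through.
as_zyx <- function(a) {
  if (is.matrix(a)) {
    array(a, dim = c(1L, nrow(a), ncol(a)))
  } else if (is.array(a) && length(dim(a)) == 3L) {
    a
  } else stop("each channel must be a 2D matrix or 3D [z, y, x] array")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- x$dim
  cat(sprintf("image_stack: %d channel(s) [%s], %d slice(s) of %d x %d px\n",
              length(x$channels), paste(names(x$channels), collapse = ", "),
              d[1], d[2], d[3]))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) x$dim

#' Read a multichannel stack from a multipage TIFF
#'
#' Pages are assumed interleaved by slice with channel fastest: page order is
#' (z1 c1, z1 c2, ..., z1 cN, z2 c1, ...). Intensities are read as stored
#' (8- or 16-bit integers), preserved bit-exactly.
#'
#' @param path Path to a multipage grayscale TIFF.
#' @param geometry A [voxel_geometry()] describing the acquisition.
#' @param channel_names Character vector naming the channels in interleave
#'   order.
#' @return An [image_stack()].
#' @seealso [write_stack()] for the inverse operation.
#' @export
read_stack <- function(path, geometry, channel_names) {
  if (!file.exists(path)) stop("no such file: ", path)
  stopifnot(is.character(channel_names), length(channel_names) >= 1L)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) {
      if (dim(p)[3] != 1L)
        stop("multi-sample TIFF pages are not supported; ",
             "write channels as separate grayscale pages")
      p <- p[, , 1L]
    }
    p
  })
  nc <- length(channel_names)
  np <- length(pages)
  if (np %% nc != 0L)
    stop(sprintf("page count (%d) is not divisible by channel count (%d)",
                 np, nc))
  shp <- dim(pages[[1]])
  if (!all(vapply(pages, function(p) identical(dim(p), shp), logical(1))))
    stop("TIFF pages differ in shape")
  nz <- np %/% nc
  chans <- lapply(seq_len(nc), function(ci) {
    a <- array(0, dim = c(nz, shp[1], shp[2]))
    for (z in seq_len(nz)) a[z, , ] <- pages[[(z - 1L) * nc + ci]]
    a
  })
  names(chans) <- channel_names
  image_stack(chans, geometry = geometry)
}

#' Write a multichannel stack as a multipage TIFF
#'
#' Inverse of [read_stack()]: pages are interleaved by slice, channel fastest.
#' Values must be integers within the declared bit depth; they are stored
#' losslessly.
#'
#' @param stack An [image_stack()].
#' @param path Output file path.
#' @param bits_per_sample 8 or 16.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bits_per_sample = 8L) {
  stopifnot(inherits(stack, "image_stack"),
            bits_per_sample %in% c(8L, 16L))
  top <- 2^bits_per_sample - 1
  rng <- range(unlist(lapply(stack$channels, range)))
  if (rng[1] < 0 || rng[2] > top)
    stop("intensities outside [0, ", top, "] cannot be written at ",
         bits_per_sample, " bits")
  nz <- stack$dim[1]
  pages <- vector("list", nz * length(stack$channels))
  k <- 0L
  for (z in seq_len(nz)) {
    for (ch in stack$channels) {
      k <- k + 1L
      pages[[k]] <- round(ch[z, , ]) / top
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = bits_per_sample,
                  compression = "none")
  invisible(path)
}

#' Write the seven pseudo-channels of a segmentation as binary TIFF masks
#'
#' One single-channel file per color class (red ... white), nonzero (255)
#' exactly where that class was assigned. Multi-slice segmentations produce
#' multipage files.
#'
#' @param segmap A `segmentation_map` from [segment_image()].
#' @param out_dir Output directory (created if absent).
#' @param prefix Optional filename prefix.
#' @return Named character vector of the seven file paths, invisibly.
#' @export
write_pseudo_channels <- function(segmap, out_dir, prefix = "") {
  stopifnot(inherits(segmap, "segmentation_map"))
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create directory: ", out_dir)
  paths <- character(0)
  for (cls in segmap$classes) {
    mask <- segmap$pseudo_channels[[cls]]
    st <- image_stack(stats::setNames(list(mask * 255), cls))
    p <- file.path(out_dir, paste0(prefix, cls, ".tif"))
    write_stack(st, p, bits_per_sample = 8L)
    paths[cls] <- p
  }
  invisible(paths)
}
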