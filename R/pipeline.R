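#' Read a pipeline configuration file
#'
#' Configuration is YAML with keys: `input` (multipage TIFF path),
#' `channels` (names in interleave order), `pixel_size_um`, `z_interval_um`,
#' `field_size_um`, and optionally `frame_interval_s`,
#' `background_window_px` (default 31), `overlap_threshold` (default 0.30),
#' `min_punctum_voxels` (default 4), `segmentation_background_percentile`
#' (default 50), `seed` (default 1), `out` (output directory).
#'
#' @param path Path to a YAML config file.
#' @return Named list of validated configuration values.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- yaml::read_yaml(path)
  for (key in c("input", "channels", "pixel_size_um"))
    if (is.null(cfg[[key]])) stop("config is missing required key '", key, "'")
  if (is.null(cfg$z_interval_um)) stop("config is missing geometry key 'z_interval_um'")
  defaults <- list(background_window_px = 31L, overlap_threshold = 0.30,
                   min_punctum_voxels = 4L,
                   segmentation_background_percentile = 50,
                   seed = 1L, field_size_um = NULL, frame_interval_s = NULL,
                   out = NULL)
  for (key in names(defaults))
    if (is.null(cfg[[key]])) cfg[key] <- list(defaults[[key]])
  cfg
}

#' Run the full co-localization pipeline from a configuration
#'
#' Reads the stack, performs seven-color segmentation of the first three
#' channels (writing the seven pseudo-channel masks), detects puncta per
#' channel against the local background model, computes directional percent
#' co-localization for every ordered channel pair (and the triple tally for
#' three channels), and writes maximum-intensity projections. A warning is
#' issued when fewer than 1500 puncta enter the analysis, the conventional
#' minimum sample size for reliable percentages.
#'
#' The run is deterministic: the same configuration and seed produce a
#' byte-identical report.
#'
#' @param config Path to a YAML configuration file or a list from
#'   [read_pipeline_config()].
#' @param out_dir Output directory; overrides the config `out` key. Default
#'   a `granuloc_out` sibling of the input.
#' @return Invisibly, the report data frame (columns `pair, n_ref_events,
#'   n_coloc_events, percent`), also written to `report.tsv`; puncta go to
#'   `puncta.tsv`, pseudo-channels and projections to TIFF files.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) read_pipeline_config(config) else config
  if (is.null(out_dir)) out_dir <- cfg$out
  if (is.null(out_dir))
    out_dir <- file.path(dirname(cfg$input), "granuloc_out")
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir)
  set.seed(as.integer(cfg$seed))

  geom <- voxel_geometry(pixel_size_xy = cfg$pixel_size_um,
                         z_interval = cfg$z_interval_um,
                         field_size_xy = cfg$field_size_um,
                         frame_interval = cfg$frame_interval_s)
  stack <- read_stack(cfg$input, geom, cfg$channels)
  nc <- length(stack$channels)

  # seven-color segmentation of the composite (missing third channel = 0)
  comp <- stack$channels
  if (nc == 2L) comp <- c(comp, list(.zero = array(0, dim = stack$dim)))
  seg <- segment_image(comp[1:3],
                       background_threshold = stats::quantile(
                         sqrt(Reduce(`+`, lapply(comp[1:3], function(a) a^2))),
                         cfg$segmentation_background_percentile / 100,
                         names = FALSE))
  write_pseudo_channels(seg, out_dir)

  psets <- lapply(names(stack$channels), function(nm) {
    ch <- stack$channels[[nm]]
    bg <- estimate_local_background(ch, cfg$background_window_px)
    detect_puncta(ch, bg, min_size = cfg$min_punctum_voxels,
                  channel_name = nm)
  })
  names(psets) <- names(stack$channels)
  total <- sum(vapply(psets, length, integer(1)))
  if (total < 1500L)
    warning(sprintf(paste0("only %d puncta analyzed; more than 1500 are ",
                           "recommended for reliable percentages"), total))

  rows <- list()
  for (i in seq_len(nc)) for (j in seq_len(nc)) {
    if (i == j) next
    if (length(psets[[i]]$puncta) == 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        pair = paste0(names(psets)[i], "->", names(psets)[j]),
        n_ref_events = 0L, n_coloc_events = 0L, percent = NA_real_)
      next
    }
    cr <- percent_colocalization(psets[[i]], psets[[j]],
                                 threshold = cfg$overlap_threshold)
    rows[[length(rows) + 1L]] <- data.frame(
      pair = paste0(cr$ref_channel, "->", cr$target_channel),
      n_ref_events = cr$n_ref_events, n_coloc_events = cr$n_coloc_events,
      percent = cr$percent)
  }
  if (nc == 3L && all(vapply(psets, length, integer(1)) > 0L)) {
    tri <- triple_colocalization(psets[[1]], psets[[2]], psets[[3]],
                                 threshold = cfg$overlap_threshold)
    rows[[length(rows) + 1L]] <- data.frame(
      pair = paste(tri$channels, collapse = "+"),
      n_ref_events = length(psets[[1]]$puncta),
      n_coloc_events = tri$n_triple,
      percent = 100 * tri$n_triple / length(psets[[1]]$puncta))
  }
  report <- do.call(rbind, rows)
  report$percent <- round(report$percent, 4)

  write_table <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  write_table(report, "report.tsv")
  write_table(do.call(rbind, lapply(psets, as.data.frame)), "puncta.tsv")

  mip <- max_projection(stack)
  for (nm in names(mip)) {
    st <- image_stack(stats::setNames(list(mip[[nm]]), nm))
    write_stack(st, file.path(out_dir, paste0("mip_", nm, ".tif")),
                bits_per_sample = 8L)
  }
  invisible(report)
}
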