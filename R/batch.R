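#' Batch analysis configuration
#'
#' One configuration drives a whole image set, mirroring the
#' threshold-persistence workflow: the detection threshold set for (or
#' overridden at) one image carries forward to all subsequent images of
#' the batch.
#'
#' @param images character vector of image paths or glob patterns.
#' @param out_dir output directory for the exported tables.
#' @param channel name of the analysed channel (e.g. `"G"` for a PSD-95
#'   stain imaged in green, or `"GRAY"`).
#' @param t_min,t_start,step,min_size,connectivity detection parameters,
#'   see [detection_params()].
#' @param marker_channel transfection-marker channel name, or `NULL` to
#'   skip marker filtering. Must differ from `channel`.
#' @param marker_threshold marker intensity cutoff (default 50).
#' @param min_overlap_fraction see [filter_by_marker()] (default 0 =
#'   any overlap).
#' @param pixel_size micrometres per pixel (default 1 = uncalibrated; a
#'   warning marks densities as per-pixel units).
#' @param spine_rules a [spine_rules()] object.
#' @param roi_suffix sidecar naming convention: for image `img.tif` the
#'   ROI file is `img.rois.json` next to it (extension replaced by
#'   `roi_suffix`).
#' @param overrides named list mapping image ids (file names without
#'   extension) to replacement `t_min` values; see
#'   [override_threshold()].
#' @param timestamp include a wall-clock timestamp in the run metadata
#'   (disable for byte-reproducible output).
#' @return Object of class `batch_config`.
#' @export
batch_config <- function(images, out_dir, channel = "G", t_min = 70L,
                         t_start = 255L, step = 1L, min_size = 4L,
                         connectivity = 8L, marker_channel = NULL,
                         marker_threshold = 50L, min_overlap_fraction = 0,
                         pixel_size = 1, spine_rules = punctanal::spine_rules(),
                         roi_suffix = ".rois.json", overrides = list(),
                         timestamp = TRUE) {
  params <- detection_params(t_min, t_start, step, min_size, connectivity)
  if (!is.null(marker_channel) && identical(marker_channel, channel))
    stop("marker_channel must differ from the analysed channel")
  if (pixel_size == 1)
    warning("pixel_size = 1 (uncalibrated): densities are per pixel / per 10 px")
  structure(list(images = images, out_dir = out_dir, channel = channel,
                 params = params, marker_channel = marker_channel,
                 marker_threshold = as.integer(marker_threshold),
                 min_overlap_fraction = min_overlap_fraction,
                 pixel_size = pixel_size, spine_rules = spine_rules,
                 roi_suffix = roi_suffix, overrides = overrides,
                 timestamp = timestamp),
            class = "batch_config")
}

#' Read a batch configuration from JSON
#'
#' @param path JSON file with the fields of [batch_config()] (detection
#'   parameters may be nested under `"detection"`, rule thresholds under
#'   `"spine_rules"`).
#' @return A [batch_config()].
#' @export
read_batch_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  det <- j$detection %||% j
  sr <- if (!is.null(j$spine_rules)) do.call(spine_rules, j$spine_rules)
        else spine_rules()
  batch_config(
    images = j$images, out_dir = j$out_dir %||% ".",
    channel = j$channel %||% "G",
    t_min = det$t_min %||% 70L, t_start = det$t_start %||% 255L,
    step = det$step %||% 1L, min_size = det$min_size %||% 4L,
    connectivity = det$connectivity %||% 8L,
    marker_channel = j$marker_channel,
    marker_threshold = j$marker_threshold %||% 50L,
    min_overlap_fraction = j$min_overlap_fraction %||% 0,
    pixel_size = j$pixel_size %||% 1, spine_rules = sr,
    roi_suffix = j$roi_suffix %||% ".rois.json",
    overrides = as.list(j$overrides %||% list()),
    timestamp = j$timestamp %||% TRUE)
}

#' Override the detection threshold from one image onward
#'
#' Mirrors interactive re-thresholding during a batch: the override applies
#' to `image_id` and becomes the persistent default for every subsequent
#' image (batch order), until the next override. Recorded per image in the
#' run metadata.
#'
#' @param config a [batch_config()].
#' @param image_id image identifier (file name without extension).
#' @param t_min replacement threshold, 0-255.
#' @return The updated config.
#' @export
override_threshold <- function(config, image_id, t_min) {
  stopifnot(inherits(config, "batch_config"))
  t_min <- as.integer(t_min)
  if (is.na(t_min) || t_min < 0L || t_min > 255L)
    stop("override t_min must be an integer in [0, 255]")
  config$overrides[[as.character(image_id)]] <- t_min
  config
}

.image_id <- function(path) tools::file_path_sans_ext(basename(path))

.rbind_rows <- function(lst) {
  lst <- unname(lst)
  if (length(lst) == 0L) return(NULL)
  do.call(rbind, c(lst, list(make.row.names = FALSE)))
}

# analyse one image against its ROI sidecar; returns per-object tables
.analyze_image <- function(path, config, t_min) {
  frame <- load_image(path, pixel_size = config$pixel_size)
  id <- .image_id(path)
  roi_path <- file.path(dirname(path), paste0(id, config$roi_suffix))
  if (!file.exists(roi_path)) {
    warning("no ROI sidecar for ", path, " (expected ", roi_path,
            "); image skipped")
    return(NULL)
  }
  rois <- load_rois(roi_path, pixel_size = config$pixel_size,
                    image_shape = c(frame$height, frame$width))
  channel <- get_channel(frame, config$channel)
  params <- config$params
  params$t_min <- as.integer(t_min)
  spines_all <- classify_spines(rois$spines, config$pixel_size,
                                config$spine_rules)
  dend_rows <- list(); punc_rows <- list(); spine_rows <- list()
  region_rows <- list()
  for (d in rois$dendrites) {
    det <- detect_puncta(channel, d$mask, params, config$pixel_size)
    if (!is.null(config$marker_channel))
      det <- filter_by_marker(det, get_channel(frame, config$marker_channel),
                             config$marker_threshold,
                             config$min_overlap_fraction)
    d <- attach_puncta(d, det)
    sp <- spines_all[!is.na(spines_all$dendrite_id) &
                     spines_all$dendrite_id == d$id, , drop = FALSE]
    d <- attach_spines(d, sp)
    dend_rows[[d$id]] <- dendrite_stats(d, image = id)
    if (nrow(det$puncta)) {
      p <- det$puncta
      p <- cbind(image = id, dendrite_id = d$id, group = d$group, p)
      punc_rows[[d$id]] <- p
    }
    if (nrow(sp))
      spine_rows[[d$id]] <- cbind(image = id, group = d$group, sp)
  }
  for (g in rois$generics)
    region_rows[[g$id]] <- cbind(image = id, region_intensity(g, channel))
  list(dendrites = .rbind_rows(dend_rows), puncta = .rbind_rows(punc_rows),
       spines = .rbind_rows(spine_rows), regions = .rbind_rows(region_rows))
}

#' Run a batch analysis over an image set
#'
#' Resolves the configured image patterns, processes every image that has
#' an ROI sidecar (threshold overrides carry forward in batch order),
#' aggregates per-dendrite and per-group statistics, and exports the
#' combined tables plus a run-metadata JSON recording the exact threshold
#' used for each image. Per-image failures are warnings, not errors, so a
#' corrupt file does not abort a large batch.
#'
#' @param config a [batch_config()].
#' @param out_dir optional override of `config$out_dir`.
#' @return Invisibly, a list with the combined tables (`dendrites`,
#'   `puncta`, `spines`, `groups`, `regions`), the per-image thresholds,
#'   the files written and `status` (0 on success).
#' @export
run_batch <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "batch_config"))
  out_dir <- out_dir %||% config$out_dir
  paths <- unlist(lapply(config$images, function(p) {
    if (grepl("[*?[]", p)) Sys.glob(p) else p
  }))
  paths <- paths[file.exists(paths)]
  if (length(paths) == 0L) stop("no images match the configured patterns")
  current_t <- config$params$t_min
  used_t <- list()
  acc <- list(dendrites = NULL, puncta = NULL, spines = NULL, regions = NULL)
  for (p in paths) {
    id <- .image_id(p)
    if (!is.null(config$overrides[[id]]))
      current_t <- config$overrides[[id]] # persists for subsequent images
    res <- tryCatch(.analyze_image(p, config, current_t),
                    error = function(e) {
                      warning("image '", p, "' failed and was skipped: ",
                              conditionMessage(e))
                      NULL
                    })
    if (is.null(res)) next
    used_t[[id]] <- current_t
    for (k in names(acc))
      acc[[k]] <- rbind(acc[[k]], res[[k]])
  }
  dend <- acc$dendrites %||% dendrite_stats_schema()
  groups <- if (nrow(dend)) group_stats(dend) else
    data.frame(group = character(), n_dendrites = integer())
  cfg_echo <- config
  cfg_echo$params <- unclass(cfg_echo$params)
  cfg_echo$spine_rules <- unclass(cfg_echo$spine_rules)
  files <- export_results(groups, dend,
                          acc$puncta %||% puncta_table_schema(),
                          acc$spines %||% spine_table_schema(),
                          out_dir, config = unclass(cfg_echo),
                          per_image_thresholds = used_t,
                          timestamp = config$timestamp)
  if (!is.null(acc$regions)) {
    .write_tsv(acc$regions, file.path(out_dir, "regions.tsv"))
    files <- c(files, file.path(out_dir, "regions.tsv"))
  }
  invisible(list(status = 0L, dendrites = dend, puncta = acc$puncta,
                 spines = acc$spines, groups = groups,
                 regions = acc$regions, per_image_thresholds = used_t,
                 files = files))
}

# header-only schemas for empty exports
dendrite_stats_schema <- function() {
  d <- dendrite_region("x", rbind(c(0, 0), c(0, 9)), half_width_um = 2,
                       image_shape = c(12L, 12L))
  dendrite_stats(d)[0, , drop = FALSE]
}
puncta_table_schema <- function() {
  cbind(image = character(), dendrite_id = character(), group = character(),
        .punctum_table(matrix(0L, 1, 1), matrix(0L, 1, 1), 1)$puncta)
}
spine_table_schema <- function() {
  cbind(image = character(), group = character(), classify_spines(list()))
}
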