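#' Per-dendrite puncta and spine statistics
#'
#' Computes the per-dendrite summary row: puncta count and density (per
#' micrometre and per 10 micrometres), both intensity summaries (the mean
#' over puncta of the per-punctum average intensity, and the mean of the
#' per-punctum integrated intensity), total puncta intensity per unit
#' length, spine count/density and puncta per spine. Densities use the
#' physical centerline length.
#'
#' @param region a [dendrite_region()] with attached puncta/spines.
#' @param image image identifier for the output tables.
#' @return One-row data frame (class `data.frame`).
#' @export
dendrite_stats <- function(region, image = NA_character_) {
  stopifnot(inherits(region, "dendrite_region"))
  len <- region$length_um
  if (len <= 0) stop("dendrite length must be positive")
  p <- if (is.null(region$puncta)) NULL else region$puncta$puncta
  np <- if (is.null(p)) 0L else nrow(p)
  s <- region$spines
  ns <- if (is.null(s)) 0L else nrow(s)
  sp <- if (!is.null(s)) spine_summary(s, len) else NULL
  data.frame(
    image = image,
    dendrite_id = region$id,
    group = region$group,
    length_um = len,
    puncta_count = np,
    puncta_density_per_um = np / len,
    puncta_density_per_10um = 10 * np / len,
    mean_avg_intensity = if (np) mean(p$average_intensity) else NA_real_,
    mean_integrated_intensity = if (np) mean(p$integrated_intensity) else NA_real_,
    total_puncta_intensity_per_um =
      if (np) sum(p$integrated_intensity) / len else 0,
    spine_count = ns,
    spine_density_per_um = ns / len,
    mushroom_density_per_um = if (is.null(sp)) 0 else sp$density_by_type[1],
    thin_density_per_um = if (is.null(sp)) 0 else sp$density_by_type[2],
    stubby_density_per_um = if (is.null(sp)) 0 else sp$density_by_type[3],
    filopodia_density_per_um = if (is.null(sp)) 0 else sp$density_by_type[4],
    mean_spine_length_um = if (is.null(sp)) NA_real_ else sp$mean_length_um,
    mean_spine_head_um = if (is.null(sp)) NA_real_ else sp$mean_head_width_um,
    puncta_per_spine = if (ns > 0) np / ns else NA_real_)
}

#' Per-group summary across dendrites
#'
#' The dendrite is the statistical unit: each metric is summarised as the
#' unweighted mean and standard deviation across the dendrites of a group.
#' Pooled puncta density (total count over total length) is also exported,
#' clearly labelled, because the mean of per-dendrite densities differs
#' from the pooled ratio when dendrite lengths differ.
#'
#' @param dendrites data frame of [dendrite_stats()] rows.
#' @return Data frame with one row per group: `n_dendrites`, `mean_*` and
#'   `sd_*` for every numeric metric, and `pooled_puncta_density_per_um`.
#' @export
group_stats <- function(dendrites) {
  if (nrow(dendrites) == 0L) {
    warning("no dendrites to aggregate")
    return(data.frame(group = character(), n_dendrites = integer()))
  }
  metrics <- setdiff(names(dendrites)[vapply(dendrites, is.numeric, TRUE)],
                     NULL)
  out <- lapply(split(dendrites, dendrites$group), function(d) {
    row <- data.frame(group = d$group[1], n_dendrites = nrow(d))
    for (m in metrics) {
      v <- d[[m]][!is.na(d[[m]])]
      row[[paste0("mean_", m)]] <- if (length(v)) mean(v) else NA_real_
      row[[paste0("sd_", m)]] <- if (length(v) > 1) sd(v) else
        if (length(v) == 1) 0 else NA_real_
    }
    row$pooled_puncta_density_per_um <-
      sum(d$puncta_count) / sum(d$length_um)
    row
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Integrated and average intensity over a generic region
#'
#' @param region a [generic_region()] (or any object with a logical
#'   `mask`).
#' @param channel intensity matrix, same shape as the mask.
#' @return One-row data frame: region id, group, pixel area, integrated and
#'   average intensity.
#' @export
region_intensity <- function(region, channel) {
  mask <- region$mask
  if (!identical(dim(mask), dim(channel)))
    stop("channel shape does not match the region mask")
  a <- sum(mask)
  if (a == 0L) stop("region mask is empty")
  integ <- sum(as.numeric(channel[mask]))
  data.frame(region_id = region$id, group = region$group,
             area_px = a, integrated_intensity = integ,
             average_intensity = integ / a)
}

# full-precision numeric formatting so exported tables re-parse exactly
.fmt_table <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      x <- sprintf("%.17g", df[[j]])
      x[is.na(df[[j]])] <- "NA"
      df[[j]] <- x
    }
  }
  df
}

.write_tsv <- function(df, path) {
  write.table(.fmt_table(df), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
}

#' Export analysis results as TSV tables plus run metadata
#'
#' Writes `puncta.tsv`, `dendrites.tsv`, `spines.tsv` and `groups.tsv`
#' (tab-separated, UTF-8, `.` decimal separator, full 17-significant-digit
#' precision so values re-parse exactly) and `run_metadata.json` echoing
#' the configuration, schema version and per-image thresholds. Empty
#' analyses produce header-only files.
#'
#' @param groups,dendrites,puncta,spines data frames (may have zero rows).
#' @param out_dir output directory (created if needed).
#' @param config configuration list echoed into the metadata.
#' @param per_image_thresholds named list/vector recording the exact
#'   `t_min` used for every image (audit trail).
#' @param timestamp logical: include a wall-clock timestamp in the
#'   metadata (disable for byte-reproducible runs).
#' @return Invisibly, the vector of files written.
#' @export
export_results <- function(groups, dendrites, puncta, spines, out_dir,
                           config = NULL, per_image_thresholds = NULL,
                           timestamp = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  files <- file.path(out_dir, c("puncta.tsv", "dendrites.tsv",
                                "spines.tsv", "groups.tsv"))
  .write_tsv(puncta, files[1])
  .write_tsv(dendrites, files[2])
  .write_tsv(spines, files[3])
  .write_tsv(groups, files[4])
  meta <- list(schema_version = PUNCTANAL_SCHEMA_VERSION,
               software = "punctanal",
               version = as.character(utils::packageVersion("punctanal")),
               config = config,
               per_image_thresholds = per_image_thresholds)
  if (timestamp) meta$timestamp <- format(Sys.time(), tz = "UTC")
  meta_path <- file.path(out_dir, "run_metadata.json")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(c(files, meta_path))
}
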