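#' Detection parameters for multi-threshold puncta detection
#'
#' @param t_min final (lowest) threshold of the descending sweep, 0-255.
#'   Pixels below `t_min` never belong to a punctum.
#' @param t_start initial threshold (default 255).
#' @param step per-round threshold decrement (default 1). The final round
#'   always runs at exactly `t_min` even if the step overshoots it.
#' @param min_size minimum pixel count for a newly formed punctum
#'   (default 4, the classical "4 or more adjacent pixels" rule).
#' @param connectivity pixel adjacency, 4 or 8 (default 8).
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(t_min, t_start = 255L, step = 1L,
                             min_size = 4L, connectivity = 8L) {
  t_min <- as.integer(t_min); t_start <- as.integer(t_start)
  step <- as.integer(step); min_size <- as.integer(min_size)
  connectivity <- as.integer(connectivity)
  if (is.na(t_min) || t_min < 0L || t_min > 255L)
    stop("t_min must be an integer in [0, 255]")
  if (t_start < t_min || t_start > 255L)
    stop("t_start must satisfy t_min <= t_start <= 255")
  if (step < 1L) stop("step must be >= 1")
  if (min_size < 1L) stop("min_size must be >= 1")
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  structure(list(t_min = t_min, t_start = t_start, step = step,
                 min_size = min_size, connectivity = connectivity),
            class = "detection_params")
}

# per-punctum statistics + 0-based pixel sets from a label map
.punctum_table <- function(label_map, channel, pixel_size) {
  idx <- which(label_map > 0L)
  if (length(idx) == 0L) {
    tab <- data.frame(label = integer(), area_px = integer(),
                      area_phys = numeric(), integrated_intensity = numeric(),
                      average_intensity = numeric(), min_intensity = integer(),
                      centroid_row = numeric(), centroid_col = numeric())
    return(list(puncta = tab, pixel_sets = list()))
  }
  lab <- label_map[idx]
  vals <- channel[idx]
  nr <- nrow(label_map)
  rows0 <- (idx - 1L) %% nr          # 0-based row
  cols0 <- (idx - 1L) %/% nr         # 0-based col
  labs <- sort(unique(lab))
  f <- factor(lab, levels = labs)
  area <- as.integer(table(f))
  integ <- as.numeric(rowsum(as.numeric(vals), f))
  tab <- data.frame(
    label = labs,
    area_px = area,
    area_phys = area * pixel_size^2,
    integrated_intensity = integ,
    average_intensity = integ / area,
    min_intensity = as.integer(tapply(vals, f, min)),
    centroid_row = as.numeric(rowsum(as.numeric(rows0), f)) / area,
    centroid_col = as.numeric(rowsum(as.numeric(cols0), f)) / area,
    row.names = NULL)
  ord <- order(lab, rows0 * ncol(label_map) + cols0)
  pixel_sets <- split.data.frame(cbind(row = rows0, col = cols0)[ord, , drop = FALSE],
                                 lab[ord])
  names(pixel_sets) <- NULL
  list(puncta = tab, pixel_sets = pixel_sets)
}

.new_detection <- function(label_map, channel, params, pixel_size, method) {
  st <- .punctum_table(label_map, channel, pixel_size)
  structure(list(puncta = st$puncta, pixel_sets = st$pixel_sets,
                 label_map = label_map, params = params,
                 pixel_size = pixel_size, method = method),
            class = "puncta_detection")
}

#' Detect puncta by descending multi-threshold region growing
#'
#' Runs rounds of detection from `t_start` down to `t_min`. In each round,
#' existing puncta first expand into adjacent above-threshold pixels (a
#' contested pixel joins the punctum of its brightest assigned neighbour,
#' ties to the lowest label; expansion runs to a fixed point within the
#' round), then remaining isolated clusters of at least `min_size`
#' above-threshold pixels become new puncta. Because puncta are seeded at
#' high thresholds, adjacent bright puncta that merge into one component at
#' the final threshold are still reported as distinct objects.
#'
#' @param channel integer matrix of intensities 0-255 (from
#'   [get_channel()]).
#' @param region_mask logical matrix restricting detection, or `NULL` for
#'   the whole image. Pixels outside the mask are never candidates, so
#'   puncta crossing the region boundary are clipped to it.
#' @param params a [detection_params()] object.
#' @param pixel_size micrometres per pixel, used for physical areas.
#' @return An object of class `puncta_detection` with components `puncta`
#'   (data frame of per-punctum statistics: pixel area, physical area,
#'   integrated and average intensity, minimum intensity, centroid),
#'   `pixel_sets` (list of 0-based `(row, col)` matrices), `label_map`
#'   (integer matrix, 0 = background) and the parameters used.
#' @export
detect_puncta <- function(channel, region_mask = NULL, params,
                          pixel_size = 1) {
  stopifnot(inherits(params, "detection_params"))
  channel <- .as_intensity_matrix(channel)
  region_mask <- .check_mask(region_mask, dim(channel))
  lm <- .detect_puncta_cpp(channel, region_mask, params$t_start,
                           params$t_min, params$step, params$min_size,
                           params$connectivity)
  .new_detection(lm, channel, params, pixel_size, "multi_threshold")
}

#' Detect puncta at a single fixed threshold
#'
#' The classical baseline: connected components of in-mask pixels with
#' intensity at or above `t`; components with at least `min_size` pixels
#' become puncta. Adjacent bright puncta whose connecting saddle exceeds
#' `t` are merged into one object here, which is exactly what the
#' multi-threshold sweep of [detect_puncta()] avoids. Implemented as a
#' graph connected-components labelling, independent of the sweep code
#' path.
#'
#' @inheritParams detect_puncta
#' @param t intensity threshold, 0-255.
#' @param min_size minimum component pixel count (default 4).
#' @param connectivity 4 or 8 (default 8).
#' @return A `puncta_detection` object (see [detect_puncta()]).
#' @export
single_threshold_detect <- function(channel, region_mask = NULL, t,
                                    min_size = 4L, connectivity = 8L,
                                    pixel_size = 1) {
  channel <- .as_intensity_matrix(channel)
  region_mask <- .check_mask(region_mask, dim(channel))
  params <- detection_params(t_min = t, t_start = t, step = 1L,
                             min_size = min_size,
                             connectivity = connectivity)
  nr <- nrow(channel); nc <- ncol(channel)
  fg <- region_mask & channel >= t
  idx <- which(fg)
  lm <- matrix(0L, nr, nc)
  if (length(idx)) {
    vmap <- integer(nr * nc)
    vmap[idx] <- seq_along(idx)
    # half-neighbourhood offsets in column-major linear index space
    offs <- list(c(1L, 0L), c(0L, 1L))
    if (connectivity == 8L) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
    from <- integer(0); to <- integer(0)
    i0 <- (idx - 1L) %% nr; j0 <- (idx - 1L) %/% nr
    for (o in offs) {
      i2 <- i0 + o[1]; j2 <- j0 + o[2]
      ok <- i2 >= 0L & i2 < nr & j2 >= 0L & j2 < nc
      nidx <- i2[ok] + j2[ok] * nr + 1L
      keep <- fg[nidx]
      from <- c(from, vmap[idx[ok][keep]])
      to <- c(to, vmap[nidx[keep]])
    }
    g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
    if (length(from))
      g <- igraph::add_edges(g, rbind(from, to))
    memb <- igraph::components(g)$membership
    sizes <- tabulate(memb)
    # deterministic labels: row-major order of each component's
    # topmost-leftmost pixel
    rm_key <- i0 * nc + j0
    first_key <- tapply(rm_key, memb, min)
    big <- which(sizes >= min_size)
    big <- big[order(first_key[big])]
    relab <- integer(length(sizes))
    relab[big] <- seq_along(big)
    lm[idx] <- relab[memb]
  }
  .new_detection(lm, channel, params, pixel_size, "single_threshold")
}

#' Remove puncta that do not overlap the transfection marker
#'
#' Puncta belonging to neighbouring, non-transfected neurons are excluded
#' by requiring overlap with the transfection marker channel (e.g. a GFP or
#' beta-galactosidase cell fill): a punctum is kept iff the fraction of its
#' pixels whose marker intensity is at least `marker_threshold` reaches
#' `min_overlap_fraction`. With the default `min_overlap_fraction = 0`, any
#' single overlapping pixel suffices (the fraction must be strictly
#' positive).
#'
#' @param detection a `puncta_detection` object.
#' @param marker_channel integer matrix, same shape as the analysed channel.
#' @param marker_threshold marker intensity cutoff, 0-255.
#' @param min_overlap_fraction required overlapping fraction in `[0, 1]`;
#'   0 means "any overlap".
#' @return The filtered `puncta_detection`; removed puncta are also cleared
#'   from the label map. Surviving puncta keep their original labels.
#' @export
filter_by_marker <- function(detection, marker_channel, marker_threshold,
                             min_overlap_fraction = 0) {
  stopifnot(inherits(detection, "puncta_detection"))
  marker_channel <- .as_intensity_matrix(marker_channel)
  if (!identical(dim(marker_channel), dim(detection$label_map)))
    stop("marker channel shape does not match the detection image")
  if (min_overlap_fraction < 0 || min_overlap_fraction > 1)
    stop("min_overlap_fraction must be in [0, 1]")
  mk <- marker_channel >= marker_threshold
  nr <- nrow(mk)
  frac <- vapply(detection$pixel_sets, function(px) {
    mean(mk[px[, "row"] + 1L + px[, "col"] * nr])
  }, numeric(1))
  keep <- if (min_overlap_fraction > 0) frac >= min_overlap_fraction
          else frac > 0
  detection$puncta <- detection$puncta[keep, , drop = FALSE]
  rownames(detection$puncta) <- NULL
  detection$pixel_sets <- detection$pixel_sets[keep]
  lm <- detection$label_map
  lm[!(lm %in% detection$puncta$label)] <- 0L
  detection$label_map <- lm
  detection
}

#' @export
print.puncta_detection <- function(x, ...) {
  cat(sprintf("puncta_detection (%s): %d puncta\n", x$method,
              nrow(x$puncta)))
  if (nrow(x$puncta)) {
    cat(sprintf("  thresholds %d..%d, min_size %d, %d-connectivity\n",
                x$params$t_start, x$params$t_min, x$params$min_size,
                x$params$connectivity))
    cat(sprintf("  area: %d-%d px; average intensity: %.1f-%.1f\n",
                min(x$puncta$area_px), max(x$puncta$area_px),
                min(x$puncta$average_intensity),
                max(x$puncta$average_intensity)))
  }
  invisible(x)
}

#' @export
summary.puncta_detection <- function(object, ...) {
  p <- object$puncta
  out <- list(
    n_puncta = nrow(p),
    total_area_px = sum(p$area_px),
    mean_area_px = if (nrow(p)) mean(p$area_px) else NA_real_,
    mean_average_intensity = if (nrow(p)) mean(p$average_intensity) else NA_real_,
    mean_integrated_intensity = if (nrow(p)) mean(p$integrated_intensity) else NA_real_)
  class(out) <- "summary.puncta_detection"
  out
}

#' @export
print.summary.puncta_detection <- function(x, ...) {
  cat(sprintf(paste0("%d puncta; total area %d px; mean area %.2f px\n",
                     "mean per-punctum average intensity %.2f\n",
                     "mean per-punctum integrated intensity %.2f\n"),
              x$n_puncta, x$total_area_px, x$mean_area_px,
              x$mean_average_intensity, x$mean_integrated_intensity))
  invisible(x)
}

.as_intensity_matrix <- function(channel) {
  if (!is.matrix(channel)) stop("channel must be a 2D intensity matrix")
  if (anyNA(channel) || min(channel) < 0 || max(channel) > 255)
    stop("channel intensities must lie in [0, 255]")
  storage.mode(channel) <- "integer"
  channel
}

.check_mask <- function(region_mask, shape) {
  if (is.null(region_mask))
    return(matrix(TRUE, shape[1], shape[2]))
  if (!is.logical(region_mask) || !is.matrix(region_mask))
    stop("region_mask must be a logical matrix or NULL")
  if (!identical(dim(region_mask), shape))
    stop("region_mask shape does not match channel shape")
  region_mask
}
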