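# shared helpers for building fixtures and comparing detections

# canonical form of a detection's pixel-set partition (label-independent)
canonical_partition <- function(det) {
  sets <- lapply(det$pixel_sets, function(p) {
    p <- p[order(p[, "row"], p[, "col"]), , drop = FALSE]
    paste(p[, "row"], p[, "col"], sep = ",", collapse = ";")
  })
  sort(unlist(sets))
}

# independent per-pixel point-in-polygon (even-odd ray crossing), scalar code
brute_point_in_polygon <- function(y, x, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    y1 <- poly[i, 1]; x1 <- poly[i, 2]
    y2 <- poly[j, 1]; x2 <- poly[j, 2]
    if ((y1 > y) != (y2 > y)) {
      xc <- x1 + (y - y1) * (x2 - x1) / (y2 - y1)
      if (x < xc) inside <- !inside
    }
    j <- i
  }
  inside
}

# random star-shaped simple polygon around a center
random_simple_polygon <- function(center, r_range = c(3, 12), n_vert = 8) {
  ang <- sort(runif(n_vert, 0, 2 * pi))
  rad <- runif(n_vert, r_range[1], r_range[2])
  cbind(center[1] + rad * sin(ang), center[2] + rad * cos(ang))
}

# fixture image whose blobs all sit inside a horizontal dendrite band,
# written to <dir>/<id>.tif with a matching <id>.rois.json sidecar
write_batch_image <- function(dir, id, seed, n_blobs = 6, shape = c(64L, 200L),
                              group = "transfected", with_spines = TRUE) {
  mid <- (shape[1] - 1) / 2
  set.seed(seed)
  cols <- sort(runif(n_blobs, 15, shape[2] - 15))
  while (n_blobs > 1 && min(diff(cols)) < 18) {
    cols <- sort(runif(n_blobs, 15, shape[2] - 15))
  }
  blobs <- lapply(cols, function(cc) list(
    center = c(mid + runif(1, -4, 4), cc),
    amp = runif(1, 150, 250), sigma = runif(1, 1.5, 2.5)))
  spec <- fixture_spec(shape, blobs, background = 10, seed = seed)
  fx <- generate_fixture(spec)
  img_path <- file.path(dir, paste0(id, ".tif"))
  save_image(fx$frame, img_path)
  regions <- list(list(
    id = paste0(id, "_d1"), kind = "dendrite", mode = "fixed_width",
    centerline = list(c(mid, 2), c(mid, shape[2] - 3)),
    half_width_um = 14, group = group))
  if (with_spines) {
    for (k in 1:3) {
      regions[[length(regions) + 1L]] <- list(
        id = paste0(id, "_sp", k), kind = "spine",
        dendrite = paste0(id, "_d1"),
        landmarks = list(base = c(mid, 20 * k), tip = c(mid + 1.2 + k, 20 * k),
                         head = list(c(mid + 1 + k, 20 * k - 0.4),
                                     c(mid + 1 + k, 20 * k + 0.4)),
                         neck = list(c(mid + 0.5, 20 * k - 0.15),
                                     c(mid + 0.5, 20 * k + 0.15))))
    }
  }
  jsonlite::write_json(list(regions = regions),
                       file.path(dir, paste0(id, ".rois.json")),
                       auto_unbox = TRUE, digits = NA)
  list(image = img_path, truth = fx$truth, spec = spec)
}

# quiet wrapper: batch_config warns when pixel_size is uncalibrated
quiet_batch_config <- function(...) suppressWarnings(batch_config(...))
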