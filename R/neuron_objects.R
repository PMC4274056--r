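#' Arc length of a polyline in physical units
#'
#' @param centerline numeric matrix of `(row, col)` vertices (>= 2).
#' @param pixel_size micrometres per pixel.
#' @return Sum of Euclidean segment lengths times `pixel_size`.
#' @export
polyline_length <- function(centerline, pixel_size = 1) {
  centerline <- .as_vertex_matrix(centerline)
  if (nrow(centerline) < 2L)
    stop("centerline needs at least 2 vertices")
  d <- diff(centerline)
  sum(sqrt(rowSums(d^2))) * pixel_size
}

#' Fixed-width outline around a dendrite centerline
#'
#' Returns the polygon outline of all points within `half_width` of the
#' polyline: per-segment rectangles with round joins at elbows and round
#' end caps, discretized with `n_arc` points per half circle. On the inner
#' side of an elbow the two offset edges meet at their miter point (capped
#' at four half-widths for near-reversals).
#'
#' @param centerline numeric matrix of `(row, col)` vertices.
#' @param half_width half of the band width, in pixels (> 0).
#' @param n_arc arc discretization: points per half circle (default 24).
#' @return Polygon vertex matrix `(row, col)`, not closed (first vertex is
#'   not repeated).
#' @export
buffer_centerline <- function(centerline, half_width, n_arc = 24L) {
  centerline <- .as_vertex_matrix(centerline)
  if (half_width <= 0) stop("half_width must be > 0")
  # drop zero-length segments
  keep <- c(TRUE, rowSums(diff(centerline)^2) > 0)
  centerline <- centerline[keep, , drop = FALSE]
  if (nrow(centerline) < 2L)
    stop("degenerate (zero-length) centerline")
  # work in (x, y) = (col, row)
  p <- centerline[, c(2, 1)]
  ns <- nrow(p) - 1L
  d <- diff(p)
  d <- d / sqrt(rowSums(d^2))
  nrm <- cbind(-d[, 2], d[, 1]) # left normal per segment
  w <- half_width

  arc <- function(center, from_vec, ang, k) {
    # points center + rotate(from_vec, ang * t), t in (0,1)
    if (k < 1L || abs(ang) < 1e-9) return(NULL)
    t <- seq_len(k) / (k + 1L)
    a <- ang * t
    base_a <- atan2(from_vec[2], from_vec[1])
    r <- sqrt(sum(from_vec^2))
    cbind(center[1] + r * cos(base_a + a), center[2] + r * sin(base_a + a))
  }
  side_pts <- function(sgn) {
    # walk segments 1..ns on the side with normal sgn * nrm
    out <- list()
    out[[length(out) + 1L]] <- rbind(p[1, ] + sgn * w * nrm[1, ])
    if (ns > 1L) for (i in seq_len(ns - 1L)) {
      P <- p[i + 1L, ]
      alpha <- atan2(d[i, 1] * d[i + 1L, 2] - d[i, 2] * d[i + 1L, 1],
                     sum(d[i, ] * d[i + 1L, ]))
      outer_side <- (sgn > 0 && alpha < 0) || (sgn < 0 && alpha > 0)
      if (outer_side) {
        out[[length(out) + 1L]] <- rbind(P + sgn * w * nrm[i, ])
        k <- max(1L, ceiling(abs(alpha) / pi * n_arc))
        out[[length(out) + 1L]] <- arc(P, sgn * w * nrm[i, ], alpha, k)
        out[[length(out) + 1L]] <- rbind(P + sgn * w * nrm[i + 1L, ])
      } else {
        m <- sgn * (nrm[i, ] + nrm[i + 1L, ])
        mlen <- sqrt(sum(m^2))
        ca <- cos(alpha / 2)
        if (mlen > 1e-9 && abs(ca) > 0.25) {
          out[[length(out) + 1L]] <- rbind(P + (w / ca) * m / mlen)
        } else {
          out[[length(out) + 1L]] <- rbind(P + sgn * w * nrm[i, ],
                                           P + sgn * w * nrm[i + 1L, ])
        }
      }
    }
    out[[length(out) + 1L]] <- rbind(p[ns + 1L, ] + sgn * w * nrm[ns, ])
    do.call(rbind, out)
  }
  left <- side_pts(1)
  right <- side_pts(-1)
  right <- right[rev(seq_len(nrow(right))), , drop = FALSE]
  cap_end <- arc(p[ns + 1L, ], w * nrm[ns, ], -pi, n_arc)
  cap_start <- arc(p[1, ], -w * nrm[1, ], -pi, n_arc)
  poly <- rbind(left, cap_end, right, cap_start)
  poly[, c(2, 1), drop = FALSE] # back to (row, col)
}

#' Signed-area magnitude of a polygon (shoelace formula)
#'
#' @param polygon vertex matrix `(row, col)`.
#' @return Absolute enclosed area in square pixels.
#' @export
polygon_area <- function(polygon) {
  polygon <- .as_vertex_matrix(polygon)
  y <- polygon[, 1]; x <- polygon[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Rasterize a polygon to a pixel mask
#'
#' A pixel belongs to the mask iff its center lies inside the polygon under
#' the even-odd rule. Pixel centers sit at integer 0-based `(row, col)`
#' coordinates; the mask is clipped to the image bounds.
#'
#' @param polygon vertex matrix `(row, col)`, >= 3 vertices, simple.
#' @param image_shape integer vector `c(height, width)`.
#' @return Logical matrix `height x width`.
#' @export
rasterize_region <- function(polygon, image_shape) {
  polygon <- .as_vertex_matrix(polygon)
  if (nrow(polygon) < 3L) stop("polygon needs at least 3 vertices")
  H <- as.integer(image_shape[1]); W <- as.integer(image_shape[2])
  cnt <- matrix(0L, H, W)
  yv <- polygon[, 1]; xv <- polygon[, 2]
  n <- length(yv)
  rows <- 0:(H - 1L)
  cols <- 0:(W - 1L)
  for (e in seq_len(n)) {
    e2 <- if (e == n) 1L else e + 1L
    y1 <- yv[e]; x1 <- xv[e]; y2 <- yv[e2]; x2 <- xv[e2]
    if (y1 == y2) next
    sel <- (y1 > rows) != (y2 > rows)
    if (!any(sel)) next
    xc <- rep(-Inf, H)
    xc[sel] <- x1 + (rows[sel] - y1) * (x2 - x1) / (y2 - y1)
    cnt <- cnt + outer(xc, cols, ">")
  }
  inside <- cnt %% 2L == 1L
  if (!any(inside))
    warning("polygon does not cover any pixel center in the image")
  inside
}

.as_vertex_matrix <- function(v) {
  if (is.list(v) && !is.data.frame(v)) v <- do.call(rbind, v)
  v <- as.matrix(v)
  if (ncol(v) != 2L || !is.numeric(v) || anyNA(v))
    stop("vertices must be a numeric (row, col) matrix without NAs")
  colnames(v) <- c("row", "col")
  v
}

#' Generic measurement region
#'
#' A freehand polygon region (e.g. a cell body) used for plain fluorescent
#' intensity measurements.
#'
#' @param id region identifier.
#' @param polygon vertex matrix `(row, col)`, >= 3 vertices.
#' @param group category name (default `"default"`).
#' @param image_shape `c(height, width)` used to rasterize the mask.
#' @return Object of class `generic_region` with a rasterized `mask`.
#' @export
generic_region <- function(id, polygon, group = "default", image_shape) {
  polygon <- .as_vertex_matrix(polygon)
  if (nrow(polygon) < 3L) stop("polygon needs at least 3 vertices")
  structure(list(id = as.character(id), polygon = polygon,
                 group = as.character(group),
                 mask = rasterize_region(polygon, image_shape)),
            class = "generic_region")
}

#' Dendrite region: puncta/spine container along a centerline
#'
#' Either a fixed-width band around the centerline (`mode = "fixed_width"`,
#' the outline is derived with [buffer_centerline()]) or a user-supplied
#' freehand polygon plus centerline (`mode = "freehand"`). The centerline
#' carries the dendrite length; the polygon is rasterized to the mask in
#' which puncta are detected.
#'
#' @param id region identifier.
#' @param centerline `(row, col)` polyline of >= 2 vertices.
#' @param mode `"fixed_width"` or `"freehand"`.
#' @param half_width_um half band width in micrometres (fixed-width mode).
#' @param polygon outline for freehand mode.
#' @param group category name.
#' @param pixel_size micrometres per pixel.
#' @param image_shape `c(height, width)`.
#' @return Object of class `dendrite_region` with `mask`, `length_um`, and
#'   empty `puncta`/`spines` slots.
#' @export
dendrite_region <- function(id, centerline, mode = c("fixed_width", "freehand"),
                            half_width_um = NULL, polygon = NULL,
                            group = "default", pixel_size = 1, image_shape) {
  mode <- match.arg(mode)
  centerline <- .as_vertex_matrix(centerline)
  len <- polyline_length(centerline, pixel_size)
  if (len <= 0) stop("dendrite length must be positive")
  if (mode == "fixed_width") {
    if (is.null(half_width_um) || half_width_um <= 0)
      stop("fixed_width mode requires a positive half_width_um")
    polygon <- buffer_centerline(centerline, half_width_um / pixel_size)
  } else {
    if (is.null(polygon)) stop("freehand mode requires a polygon")
    polygon <- .as_vertex_matrix(polygon)
  }
  structure(list(id = as.character(id), centerline = centerline,
                 mode = mode, polygon = polygon,
                 group = as.character(group), pixel_size = pixel_size,
                 length_um = len,
                 mask = rasterize_region(polygon, image_shape),
                 puncta = NULL, spines = NULL),
            class = "dendrite_region")
}

#' @export
print.dendrite_region <- function(x, ...) {
  cat(sprintf("dendrite_region '%s' (%s, group '%s'): %.2f um, %d mask px",
              x$id, x$mode, x$group, x$length_um, sum(x$mask)),
      sprintf(", %s puncta, %s spines\n",
              if (is.null(x$puncta)) 0L else nrow(x$puncta$puncta),
              if (is.null(x$spines)) 0L else nrow(x$spines)))
  invisible(x)
}

#' Attach detected puncta to a dendrite region
#'
#' Every punctum pixel must lie inside the region's rasterized mask;
#' detection is normally run with `region_mask = region$mask` so this holds
#' by construction (the mask clips candidate pixels at the boundary).
#'
#' @param region a [dendrite_region()].
#' @param detection a `puncta_detection` whose puncta lie inside the mask.
#' @return The region with `puncta` set.
#' @export
attach_puncta <- function(region, detection) {
  stopifnot(inherits(region, "dendrite_region"),
            inherits(detection, "puncta_detection"))
  nr <- nrow(region$mask)
  for (px in detection$pixel_sets) {
    if (!all(region$mask[px[, "row"] + 1L + px[, "col"] * nr]))
      stop("punctum has pixels outside the region mask")
  }
  region$puncta <- list(puncta = detection$puncta,
                        pixel_sets = detection$pixel_sets)
  region
}

#' Attach measured spines to a dendrite region
#'
#' @param region a [dendrite_region()].
#' @param spines a spine data frame from [spine_from_landmarks()] /
#'   [classify_spines()].
#' @return The region with `spines` set.
#' @export
attach_spines <- function(region, spines) {
  stopifnot(inherits(region, "dendrite_region"), is.data.frame(spines))
  region$spines <- spines
  region
}

#' Read a region-of-interest sidecar file
#'
#' Parses the JSON ROI schema: a top-level `regions` array whose entries
#' have `kind` `"dendrite"` (centerline, mode, `half_width_um` or polygon),
#' `"generic"` (polygon) or `"spine"` (owning dendrite id plus landmark
#' points). Coordinates are 0-based `(row, col)` pairs.
#'
#' @param path path to the `.rois.json` sidecar.
#' @param pixel_size micrometres per pixel.
#' @param image_shape `c(height, width)` of the image the ROIs refer to.
#' @return List with elements `dendrites` (list of [dendrite_region()]),
#'   `generics` (list of [generic_region()]) and `spines` (list of raw
#'   spine records: `id`, `dendrite`, `landmarks`).
#' @export
load_rois <- function(path, pixel_size = 1, image_shape) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("malformed ROI JSON '", path,
                                           "': ", conditionMessage(e)))
  if (is.null(doc$regions)) stop("ROI file has no 'regions' array: ", path)
  dendrites <- list(); generics <- list(); spines <- list()
  to_mat <- function(x) do.call(rbind, lapply(x, unlist))
  for (r in doc$regions) {
    kind <- r$kind %||% "generic"
    if (kind == "dendrite") {
      dendrites[[r$id]] <- dendrite_region(
        id = r$id, centerline = to_mat(r$centerline),
        mode = r$mode %||% "fixed_width",
        half_width_um = r$half_width_um,
        polygon = if (!is.null(r$polygon)) to_mat(r$polygon),
        group = r$group %||% "default",
        pixel_size = pixel_size, image_shape = image_shape)
    } else if (kind == "generic") {
      generics[[r$id]] <- generic_region(
        id = r$id, polygon = to_mat(r$polygon),
        group = r$group %||% "default", image_shape = image_shape)
    } else if (kind == "spine") {
      lmk <- lapply(r$landmarks, function(p) {
        if (is.list(p[[1]])) to_mat(p) else unlist(p)
      })
      spines[[r$id]] <- list(id = r$id, dendrite = r$dendrite,
                             landmarks = lmk,
                             category = r$category %||% NULL)
    } else stop("unknown region kind '", kind, "' in ", path)
  }
  list(dendrites = dendrites, generics = generics, spines = spines)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
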