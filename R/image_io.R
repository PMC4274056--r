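#' Construct an image frame
#'
#' An `image_frame` is a 2D multi-channel 8-bit image: an integer array of
#' shape `height x width x channels` with values in 0-255, ordered channel
#' names, and a physical calibration (micrometres per pixel edge).
#'
#' @param pixels numeric matrix (single channel) or 3D array
#'   (`height x width x channels`) of intensities in `[0, 255]`.
#' @param channels character vector of channel names. Defaults to `"GRAY"`
#'   for 1 channel, `c("R","G","B")` for 3 and `c("R","G","B","A")` for 4.
#' @param pixel_size physical length of one pixel edge in micrometres
#'   (default 1, i.e. uncalibrated).
#' @return An object of class `image_frame`.
#' @export
image_frame <- function(pixels, channels = NULL, pixel_size = 1) {
  if (is.matrix(pixels)) pixels <- array(pixels, dim = c(dim(pixels), 1L))
  if (!is.array(pixels) || length(dim(pixels)) != 3L)
    stop("'pixels' must be a matrix or a height x width x channels array")
  d <- dim(pixels)
  if (d[1] < 1L || d[2] < 1L || d[3] < 1L)
    stop("image must have height >= 1, width >= 1 and >= 1 channel")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("pixel intensities must lie in [0, 255]")
  if (is.null(channels)) {
    channels <- switch(as.character(d[3]),
      "1" = "GRAY", "2" = c("GRAY", "A"),
      "3" = c("R", "G", "B"), "4" = c("R", "G", "B", "A"),
      paste0("C", seq_len(d[3])))
  }
  if (length(channels) != d[3])
    stop("length(channels) must equal the number of planes")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("'pixel_size' must be a single positive number")
  storage.mode(pixels) <- "integer"
  structure(
    list(pixels = pixels, height = d[1], width = d[2],
         channels = as.character(channels), pixel_size = pixel_size),
    class = "image_frame")
}

#' @export
print.image_frame <- function(x, ...) {
  cat(sprintf("image_frame: %d x %d px, channels [%s], pixel_size %g um/px\n",
              x$height, x$width, paste(x$channels, collapse = ","),
              x$pixel_size))
  invisible(x)
}

#' Load a raster image as an 8-bit image frame
#'
#' Reads TIFF, PNG or JPEG files. Sources with more than 8 bits per channel
#' are rescaled to 0-255 linearly by the container's declared bit depth (not
#' by the data range), so thresholds stay comparable across the images of a
#' batch. JPEG input is accepted with a warning because lossy compression
#' perturbs intensities.
#'
#' @param path path to a TIFF, PNG or JPEG file.
#' @param pixel_size calibration in micrometres per pixel (supplied by the
#'   analysis config, never parsed from TIFF tags).
#' @return An [image_frame()].
#' @export
load_image <- function(path, pixel_size = 1) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  # tiff/png/jpeg readers all return data normalised by declared bit depth
  raw <- tryCatch(switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    jpg = , jpeg = {
      warning("JPEG is lossy; intensities may be perturbed: ", path)
      jpeg::readJPEG(path)
    },
    stop("unsupported image format '", ext, "': ", path)
  ), error = function(e) stop("cannot read image '", path, "': ",
                              conditionMessage(e)))
  if (length(raw) == 0L) stop("zero-size image: ", path)
  image_frame(round(raw * 255), pixel_size = pixel_size)
}

#' Write an image frame as an 8-bit TIFF or PNG
#'
#' @param frame an [image_frame()].
#' @param path output path ending in `.tif`/`.tiff` or `.png`.
#' @return `path`, invisibly.
#' @export
save_image <- function(frame, path) {
  stopifnot(inherits(frame, "image_frame"))
  x <- frame$pixels / 255
  if (dim(x)[3] == 1L) x <- x[, , 1]
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(x, path, bits.per.sample = 8L),
    png = png::writePNG(x, path),
    stop("unsupported output format '", ext, "'"))
  invisible(path)
}

#' Maximum intensity projection of an image stack
#'
#' Collapses a z-stack to a single frame by taking, per pixel and channel,
#' the maximum across frames. All frames must share dimensions and channel
#' names; the calibration of the first frame is kept.
#'
#' @param stack a list of [image_frame()] objects.
#' @return An [image_frame()].
#' @export
max_project <- function(stack) {
  if (!is.list(stack) || length(stack) == 0L)
    stop("stack must be a non-empty list of image frames")
  f1 <- stack[[1]]
  stopifnot(inherits(f1, "image_frame"))
  for (f in stack[-1]) {
    stopifnot(inherits(f, "image_frame"))
    if (!identical(dim(f$pixels), dim(f1$pixels)) ||
        !identical(f$channels, f1$channels))
      stop("all frames must have identical dimensions and channels")
  }
  out <- Reduce(pmax, lapply(stack, `[[`, "pixels"))
  image_frame(out, channels = f1$channels, pixel_size = f1$pixel_size)
}

#' Extract a single channel as a 2D intensity matrix
#'
#' @param frame an [image_frame()].
#' @param name channel name, e.g. `"G"`.
#' @return Integer matrix of intensities (`height x width`).
#' @export
get_channel <- function(frame, name) {
  stopifnot(inherits(frame, "image_frame"))
  k <- match(name, frame$channels)
  if (is.na(k))
    stop("unknown channel '", name, "'; available: ",
         paste(frame$channels, collapse = ", "))
  frame$pixels[, , k]
}

#' Write a label map as a 16-bit single-channel TIFF for inspection
#'
#' @param label_map integer matrix of punctum labels (0 = background).
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
save_label_map <- function(label_map, path) {
  if (max(label_map) > 65535L) stop("more than 65535 labels")
  tiff::writeTIFF(label_map / 65535, path, bits.per.sample = 16L)
  invisible(path)
}
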