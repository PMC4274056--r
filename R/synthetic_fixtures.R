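# evaluate expr with a fixed RNG seed, leaving the caller's RNG untouched
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Specification of a synthetic ground-truth image
#'
#' Describes an image of 2D isotropic Gaussian blobs (stand-ins for
#' fluorescent puncta) on a constant background with optional bounded
#' uniform noise. The same spec and seed always generate a bit-identical
#' image.
#'
#' @param shape `c(height, width)` in pixels.
#' @param blobs list of blobs, each `list(center = c(row, col), amp, sigma)`
#'   with peak amplitude in 0-255 and isotropic sigma in pixels.
#' @param background constant background level 0-255.
#' @param noise `"none"` or `"uniform"` (i.i.d. uniform on
#'   `[-noise_amp, noise_amp]`).
#' @param noise_amp noise half-amplitude in intensity units.
#' @param seed mandatory RNG seed; generation never touches global RNG
#'   state.
#' @param pixel_size micrometres per pixel for the generated frame.
#' @param marker optional transfection-marker geometry,
#'   `list(centerline = , half_width = )` (pixels): the generated frame
#'   then has channels R (marker band at 255), G (blob signal) and B
#'   (zero), emulating a cell fill co-stained with the analysed protein.
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(shape, blobs = list(), background = 0,
                         noise = c("none", "uniform"), noise_amp = 0,
                         seed = 1L, pixel_size = 1, marker = NULL) {
  noise <- match.arg(noise)
  shape <- as.integer(shape)
  stopifnot(length(shape) == 2L, all(shape >= 1L))
  for (b in blobs) {
    if (length(b$center) != 2L || b$amp < 0 || b$amp > 255 || b$sigma <= 0)
      stop("each blob needs center=c(row,col), amp in [0,255], sigma > 0")
    if (b$center[1] < 0 || b$center[1] > shape[1] - 1 ||
        b$center[2] < 0 || b$center[2] > shape[2] - 1)
      stop("blob center outside the image")
  }
  structure(list(shape = shape, blobs = blobs, background = background,
                 noise = noise, noise_amp = noise_amp,
                 seed = as.integer(seed), pixel_size = pixel_size,
                 marker = marker),
            class = "fixture_spec")
}

# continuous Gaussian-sum intensity field of a spec at points (r, c)
.blob_field <- function(spec, r, c) {
  v <- rep(spec$background, length(r))
  for (b in spec$blobs) {
    d2 <- (r - b$center[1])^2 + (c - b$center[2])^2
    v <- v + b$amp * exp(-d2 / (2 * b$sigma^2))
  }
  v
}

# minimum of the continuous field along the segment between blob centers
.pair_saddle <- function(spec, i, j) {
  p1 <- spec$blobs[[i]]$center; p2 <- spec$blobs[[j]]$center
  f <- function(t) .blob_field(spec, p1[1] + t * (p2[1] - p1[1]),
                               p1[2] + t * (p2[2] - p1[2]))
  optimize(f, c(0, 1))$objective
}

#' Generate a synthetic image with known ground truth
#'
#' Pixel values are `clip(background + sum of Gaussian blobs + noise,
#' 0, 255)` rounded to integers (clipping can flatten very bright
#' overlapping blobs; the returned truth reports unclipped peak values).
#'
#' @param spec a [fixture_spec()].
#' @return List with `frame` (a single-channel [image_frame()]) and
#'   `truth`: blob centers/amplitudes/sigmas, the continuous peak value at
#'   each center, and for every blob pair the saddle (minimum of the
#'   continuous blob field along the segment joining the centers).
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  H <- spec$shape[1]; W <- spec$shape[2]
  rr <- matrix(0:(H - 1L), H, W)
  cc <- matrix(0:(W - 1L), H, W, byrow = TRUE)
  img <- matrix(.blob_field(spec, as.vector(rr), as.vector(cc)), H, W)
  if (spec$noise == "uniform" && spec$noise_amp > 0) {
    img <- img + .with_seed(spec$seed,
      matrix(runif(H * W, -spec$noise_amp, spec$noise_amp), H, W))
  }
  img <- round(pmin(pmax(img, 0), 255)) # matrix first so dims survive pmin/pmax
  nb <- length(spec$blobs)
  saddles <- NULL
  if (nb >= 2L) {
    pr <- t(utils::combn(nb, 2L))
    saddles <- data.frame(i = pr[, 1], j = pr[, 2],
                          saddle = apply(pr, 1, function(p)
                            .pair_saddle(spec, p[1], p[2])))
  }
  centers <- do.call(rbind, lapply(spec$blobs, `[[`, "center"))
  truth <- list(
    n_blobs = nb,
    centers = centers,
    amp = vapply(spec$blobs, `[[`, numeric(1), "amp"),
    sigma = vapply(spec$blobs, `[[`, numeric(1), "sigma"),
    peak_value = if (nb) .blob_field(spec, centers[, 1], centers[, 2])
                 else numeric(0),
    saddles = saddles)
  frame <- if (is.null(spec$marker)) {
    image_frame(img, pixel_size = spec$pixel_size)
  } else {
    band <- rasterize_region(
      buffer_centerline(spec$marker$centerline, spec$marker$half_width),
      spec$shape)
    px <- array(0L, c(H, W, 3L))
    px[, , 1] <- 255L * band
    px[, , 2] <- img
    image_frame(px, pixel_size = spec$pixel_size)
  }
  list(frame = frame, truth = truth)
}

#' Random multi-blob fixture spec
#'
#' Places `n_blobs` Gaussian blobs uniformly at random (with a margin of 4
#' maximal sigmas from the border), optionally enforcing a minimum
#' pairwise center distance by rejection, so that saddles between blobs
#' stay below the detection threshold and ground-truth counts are exact.
#'
#' @param n_blobs number of blobs.
#' @param shape image shape `c(height, width)` (default 256 x 256).
#' @param seed RNG seed.
#' @param amp_range,sigma_range uniform sampling ranges for peak amplitude
#'   and sigma.
#' @param background constant background level.
#' @param noise,noise_amp noise model passed to [fixture_spec()].
#' @param min_separation minimum pairwise center distance in pixels
#'   (0 = unconstrained).
#' @return A [fixture_spec()].
#' @export
random_fixture_spec <- function(n_blobs, shape = c(256L, 256L), seed = 1L,
                                amp_range = c(150, 250),
                                sigma_range = c(1, 3), background = 0,
                                noise = "none", noise_amp = 0,
                                min_separation = 0) {
  .with_seed(seed, {
    m <- 4 * max(sigma_range)
    centers <- matrix(NA_real_, 0, 2)
    tries <- 0L
    while (nrow(centers) < n_blobs) {
      p <- c(runif(1, m, shape[1] - 1 - m), runif(1, m, shape[2] - 1 - m))
      ok <- nrow(centers) == 0L ||
        min(sqrt(rowSums((centers - matrix(p, nrow(centers), 2,
                                           byrow = TRUE))^2))) >= min_separation
      if (ok) centers <- rbind(centers, p)
      tries <- tries + 1L
      if (tries > 10000L) stop("cannot place blobs with the requested separation")
    }
    blobs <- lapply(seq_len(n_blobs), function(i) list(
      center = centers[i, ],
      amp = runif(1, amp_range[1], amp_range[2]),
      sigma = runif(1, sigma_range[1], sigma_range[2])))
    fixture_spec(shape, blobs, background = background, noise = noise,
                 noise_amp = noise_amp, seed = seed)
  })
}

#' Engineered two-blob case for threshold-merge behaviour
#'
#' Builds a two-Gaussian fixture whose detection outcome is known by
#' construction. When the saddle between the peaks lies strictly between
#' `t_min` and the lower peak, a single fixed threshold at `t_min` merges
#' the pair into one component while the descending multi-threshold sweep
#' resolves two puncta (the classic under-counting of adjacent bright
#' puncta). When the peaks are far apart (saddle at or below `t_min`) the
#' case is a well-separated control and both detectors report two.
#'
#' Feasibility is verified on the actual discrete image, not only on the
#' continuous field: the pixel saddle along the inter-peak line must agree
#' with the intended regime, and each peak must carry a component of at
#' least `min_size` pixels at the decisive threshold (otherwise an
#' under-resolved blob could never form a punctum). Infeasible parameter
#' combinations raise an error reporting the computed saddle.
#'
#' @param separation_px center-to-center distance in pixels (> 0).
#' @param peaks length-2 vector of peak amplitudes, 0-255.
#' @param sigma common isotropic sigma in pixels.
#' @param t_min final detection threshold.
#' @param min_size minimum punctum pixel count (default 4).
#' @return List with `spec` (the [fixture_spec()]), `expected_single` and
#'   `expected_multi` (expected puncta counts for single-threshold and
#'   multi-threshold detection at `t_min`), the continuous `saddle`, the
#'   discrete `saddle_px`, and `t_min`.
#' @export
two_blob_merge_case <- function(separation_px, peaks, sigma, t_min,
                                min_size = 4L) {
  if (separation_px <= 0) stop("separation must be > 0")
  stopifnot(length(peaks) == 2L, sigma > 0)
  margin <- ceiling(4 * sigma) + 2
  H <- 2L * margin + 1L
  W <- as.integer(ceiling(separation_px) + 2L * margin + 1L)
  r0 <- margin
  c1 <- margin; c2 <- margin + separation_px
  spec <- fixture_spec(c(H, W), list(
    list(center = c(r0, c1), amp = peaks[1], sigma = sigma),
    list(center = c(r0, c2), amp = peaks[2], sigma = sigma)))
  fx <- generate_fixture(spec)
  saddle <- fx$truth$saddles$saddle[1]
  peak_vals <- pmin(255, fx$truth$peak_value)
  if (saddle >= min(peak_vals))
    stop(sprintf(paste0("infeasible: saddle %.1f is not below the lower ",
                        "peak %.1f; blobs are not distinct"),
                 saddle, min(peak_vals)))
  ch <- get_channel(fx$frame, "GRAY")
  # discrete saddle: minimum pixel value on the straight line between the
  # (integer) peak pixels
  cols <- round(c1):round(c2)
  saddle_px <- min(ch[r0 + 1L, cols + 1L])
  merge_case <- saddle_px >= t_min
  t_check <- if (merge_case) saddle_px + 1L else t_min
  chk <- single_threshold_detect(ch, t = t_check, min_size = min_size)
  peak_labels <- chk$label_map[cbind(r0 + 1L, round(c(c1, c2)) + 1L)]
  if (any(peak_labels == 0L) || peak_labels[1] == peak_labels[2])
    stop(sprintf(paste0("infeasible: at threshold %d the two peaks do not ",
                        "carry distinct components of >= %d pixels ",
                        "(saddle %.1f, discrete saddle %d)"),
                 t_check, min_size, saddle, saddle_px))
  list(spec = spec,
       expected_single = if (merge_case) 1L else 2L,
       expected_multi = 2L,
       saddle = saddle, saddle_px = saddle_px, t_min = as.integer(t_min))
}
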