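#' Spine classification rule thresholds
#'
#' Rule constants for the four-way spine typing (mushroom, thin, stubby,
#' filopodia). The literature offers several criterion sets; these defaults
#' are this package's own, are fully configurable, and are echoed into the
#' run metadata so exported results are self-describing.
#'
#' @param mushroom_head_neck_ratio head/neck width ratio at or above which a
#'   spine is a mushroom (default 1.5).
#' @param filopodia_max_head_neck_ratio head/neck ratio below which a long
#'   protrusion counts as a filopodium (default 1.2; must be smaller than
#'   `mushroom_head_neck_ratio`).
#' @param filopodia_min_length_um minimum filopodium length in micrometres
#'   (default 2.0).
#' @param stubby_max_length_head_ratio length/head ratio at or below which a
#'   spine is stubby (default 1.0).
#' @param mushroom_min_head_um absolute head-width fallback (micrometres)
#'   used for the mushroom rule when no neck width was measured
#'   (default 0.6).
#' @return Object of class `spine_rules`.
#' @export
spine_rules <- function(mushroom_head_neck_ratio = 1.5,
                        filopodia_max_head_neck_ratio = 1.2,
                        filopodia_min_length_um = 2.0,
                        stubby_max_length_head_ratio = 1.0,
                        mushroom_min_head_um = 0.6) {
  vals <- c(mushroom_head_neck_ratio, filopodia_max_head_neck_ratio,
            filopodia_min_length_um, stubby_max_length_head_ratio,
            mushroom_min_head_um)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all spine rule thresholds must be positive")
  if (filopodia_max_head_neck_ratio >= mushroom_head_neck_ratio)
    stop("filopodia_max_head_neck_ratio must be < mushroom_head_neck_ratio")
  structure(list(mushroom_head_neck_ratio = mushroom_head_neck_ratio,
                 filopodia_max_head_neck_ratio = filopodia_max_head_neck_ratio,
                 filopodia_min_length_um = filopodia_min_length_um,
                 stubby_max_length_head_ratio = stubby_max_length_head_ratio,
                 mushroom_min_head_um = mushroom_min_head_um),
            class = "spine_rules")
}

SPINE_TYPES <- c("mushroom", "thin", "stubby", "filopodia")

#' Spine dimensions from landmark points
#'
#' Landmarks are 0-based `(row, col)` points placed on the image: `base`
#' and `tip` (mandatory) define the spine length; the optional `head` and
#' `neck` point pairs define head and neck widths as the distance within
#' each pair.
#'
#' @param landmarks list with `base`, `tip` (length-2 vectors) and optional
#'   `head`, `neck` (2 x 2 matrices, one point per row).
#' @param pixel_size micrometres per pixel.
#' @return List with `length_um`, `head_width_um`, `neck_width_um`
#'   (missing pairs yield `NA`).
#' @export
spine_from_landmarks <- function(landmarks, pixel_size = 1) {
  base <- as.numeric(landmarks$base); tip <- as.numeric(landmarks$tip)
  if (length(base) != 2L || length(tip) != 2L)
    stop("landmarks must include 'base' and 'tip' points")
  len <- sqrt(sum((tip - base)^2)) * pixel_size
  if (len <= 0) stop("spine base and tip coincide")
  pair_dist <- function(p) {
    if (is.null(p)) return(NA_real_)
    p <- .as_vertex_matrix(p)
    if (nrow(p) != 2L) stop("width landmarks must be a pair of points")
    sqrt(sum((p[1, ] - p[2, ])^2)) * pixel_size
  }
  list(length_um = len,
       head_width_um = pair_dist(landmarks$head),
       neck_width_um = pair_dist(landmarks$neck))
}

#' Classify one spine from its dimensions
#'
#' Rules are applied in a fixed order so ties are deterministic:
#' (1) filopodia if head/neck `<` `filopodia_max_head_neck_ratio` and
#' length `>=` `filopodia_min_length_um`; (2) mushroom if head/neck `>=`
#' `mushroom_head_neck_ratio`; (3) stubby if length/head `<=`
#' `stubby_max_length_head_ratio`; (4) thin otherwise. Without a neck
#' width, the ratio rules are skipped and the mushroom rule fires only when
#' the head width alone reaches `mushroom_min_head_um`; without a head
#' width, a protrusion of filopodial length is a filopodium, else thin.
#'
#' @param length_um spine length in micrometres (required).
#' @param head_width_um,neck_width_um widths in micrometres, `NA` if not
#'   measured.
#' @param rules a [spine_rules()] object.
#' @return One of `"mushroom"`, `"thin"`, `"stubby"`, `"filopodia"`.
#' @export
classify_spine <- function(length_um, head_width_um = NA,
                           neck_width_um = NA, rules = spine_rules()) {
  if (is.na(length_um) || length_um <= 0)
    stop("spine length is required for classification")
  has_head <- !is.na(head_width_um) && head_width_um > 0
  has_neck <- !is.na(neck_width_um) && neck_width_um > 0
  ratio <- if (has_head && has_neck) head_width_um / neck_width_um else NA
  if (!has_head)
    return(if (length_um >= rules$filopodia_min_length_um) "filopodia"
           else "thin")
  # (1) filopodia: long, no distinct head
  if (!is.na(ratio) && ratio < rules$filopodia_max_head_neck_ratio &&
      length_um >= rules$filopodia_min_length_um)
    return("filopodia")
  # (2) mushroom: pronounced head
  if ((!is.na(ratio) && ratio >= rules$mushroom_head_neck_ratio) ||
      (is.na(ratio) && head_width_um >= rules$mushroom_min_head_um))
    return("mushroom")
  # (3) stubby: short relative to head
  if (length_um / head_width_um <= rules$stubby_max_length_head_ratio)
    return("stubby")
  "thin"
}

#' Measure and classify a set of spines
#'
#' Builds the spine table from raw landmark records (as produced by
#' [load_rois()]). Spines carrying a user-assigned category keep it
#' (`category_source = "manual"`); the rest are auto-classified. Re-running
#' classification never overwrites manual categories unless
#' `overwrite_manual = TRUE`.
#'
#' @param spine_records list of records with `id`, `dendrite`, `landmarks`
#'   and optional `category`.
#' @param pixel_size micrometres per pixel.
#' @param rules a [spine_rules()] object.
#' @param overwrite_manual replace manual categories with automatic ones.
#' @return Data frame with one row per spine: id, dendrite_id, length and
#'   widths (micrometres), category and category_source.
#' @export
classify_spines <- function(spine_records, pixel_size = 1,
                            rules = spine_rules(),
                            overwrite_manual = FALSE) {
  if (length(spine_records) == 0L)
    return(data.frame(id = character(), dendrite_id = character(),
                      length_um = numeric(), head_width_um = numeric(),
                      neck_width_um = numeric(), category = character(),
                      category_source = character()))
  rows <- lapply(spine_records, function(s) {
    dims <- spine_from_landmarks(s$landmarks, pixel_size)
    manual <- !is.null(s$category) && !overwrite_manual
    if (manual && !s$category %in% SPINE_TYPES)
      stop("unknown spine category '", s$category, "'")
    data.frame(id = s$id,
               dendrite_id = s$dendrite %||% NA_character_,
               length_um = dims$length_um,
               head_width_um = dims$head_width_um,
               neck_width_um = dims$neck_width_um,
               category = if (manual) s$category
                          else classify_spine(dims$length_um,
                                              dims$head_width_um,
                                              dims$neck_width_um, rules),
               category_source = if (manual) "manual" else "auto")
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Per-dendrite spine summary
#'
#' @param spines spine data frame (see [classify_spines()]).
#' @param dendrite_length_um dendrite length in micrometres (> 0).
#' @return List with total spine density (per micrometre), per-type
#'   densities (which sum to the total), and mean length/head/neck over the
#'   measured values.
#' @export
spine_summary <- function(spines, dendrite_length_um) {
  if (dendrite_length_um <= 0) stop("dendrite length must be positive")
  n <- nrow(spines)
  by_type <- table(factor(spines$category, levels = SPINE_TYPES))
  mean_or_na <- function(x) if (any(!is.na(x))) mean(x, na.rm = TRUE) else NA_real_
  list(n_spines = n,
       density_per_um = n / dendrite_length_um,
       density_by_type = as.numeric(by_type) / dendrite_length_um,
       type_levels = SPINE_TYPES,
       mean_length_um = mean_or_na(spines$length_um),
       mean_head_width_um = mean_or_na(spines$head_width_um),
       mean_neck_width_um = mean_or_na(spines$neck_width_um))
}
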