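#' Parameters for a synthetic slide cohort
#'
#' Defines the statistical structure of a generated whole-slide cohort: slides
#' are square lattices of fixed-size tiles; every tile is background
#' (near-white), benign tissue texture, or lesion texture. Slides belonging to
#' a diseased class carry only a minority `lesion_fraction` of lesion-texture
#' tiles planted as one contiguous region, with the remaining tissue drawn
#' from a shared benign filler texture; benign-class slides contain no lesion
#' texture at all. Slides come in patient groups (every patient carries a
#' single diagnosis shared by all of their slides).
#'
#' Each class texture is an oriented sinusoid grating with a class-specific
#' spatial frequency, orientation and mean intensity (diseased texture is the
#' darkest, mimicking nuclear hyperchromasia). `texture_noise` is the
#' separability knob: it scales additive pixel noise as well as per-tile
#' jitter of the grating orientation and log-frequency, so raising it blends
#' the class-conditional texture distributions into each other.
#'
#' @param n_patients number of patients.
#' @param slides_per_patient length-2 integer range; each patient receives a
#'   uniformly drawn number of slides in this range (inclusive).
#' @param grid_side tiles per slide edge; a slide has `grid_side^2` tiles.
#' @param tile_size pixels per tile edge (must be a multiple of 4).
#' @param class_names ordered slide classes (K >= 2).
#' @param diseased_classes classes whose slides contain only a minority of
#'   class-discriminative tiles.
#' @param benign_filler_class texture used for the non-lesion tissue of
#'   diseased slides; must not itself be diseased.
#' @param lesion_fraction fraction (0,1] of a diseased slide's tissue tiles
#'   carrying the lesion texture.
#' @param background_fraction fraction of near-white tiles per slide.
#' @param texture_noise nonnegative noise scale (see Details).
#' @param color_mode `"grayscale"` or `"rgb"`; RGB mode tints each slide with
#'   a random per-slide stain vector whose luminance matches the grayscale
#'   texture, so grayscale conversion largely cancels it.
#' @param seed integer seed; cohort generation is a pure function of the
#'   parameter set.
#'
#' @return An object of class `cohort_params`.
#' @export
cohort_params <- function(n_patients = 30,
                          slides_per_patient = c(2, 4),
                          grid_side = 8,
                          tile_size = 64,
                          class_names = c("squamous", "ndbe", "dysplastic"),
                          diseased_classes = "dysplastic",
                          benign_filler_class = "ndbe",
                          lesion_fraction = 0.3,
                          background_fraction = 0.2,
                          texture_noise = 0.08,
                          color_mode = c("grayscale", "rgb"),
                          seed = 1L) {
  color_mode <- match.arg(color_mode)
  stop_if_not_scalar_count(n_patients, "n_patients")
  if (length(slides_per_patient) != 2L || any(slides_per_patient < 1) ||
      slides_per_patient[1] > slides_per_patient[2])
    stop("`slides_per_patient` must be an increasing range of counts")
  if (grid_side < 2) stop("`grid_side` must be >= 2")
  if (tile_size < 8 || tile_size %% 4 != 0)
    stop("`tile_size` must be a multiple of 4 and >= 8")
  if (length(class_names) < 2) stop("at least two classes are required")
  if (anyDuplicated(class_names)) stop("`class_names` must be unique")
  if (!all(diseased_classes %in% class_names))
    stop("`diseased_classes` must be a subset of `class_names`")
  if (!(benign_filler_class %in% setdiff(class_names, diseased_classes)))
    stop("`benign_filler_class` must be a benign member of `class_names`")
  if (!(lesion_fraction > 0 && lesion_fraction <= 1))
    stop("`lesion_fraction` must lie in (0, 1]")
  if (background_fraction < 0 || background_fraction + lesion_fraction > 1)
    stop("`background_fraction` + `lesion_fraction` must not exceed 1")
  if (texture_noise < 0) stop("`texture_noise` must be nonnegative")

  k <- length(class_names)
  textures <- data.frame(
    class = class_names,
    # class-specific grating parameters: geometrically spaced frequencies
    # (cycles per tile), fanned orientations, darkening mean intensity
    freq = 4 * 1.8^(seq_len(k) - 1),
    orient = pi * (seq_len(k) - 1) / k,
    base = 0.62 - 0.18 * (seq_len(k) - 1) / (k - 1),
    amplitude = 0.16,
    stringsAsFactors = FALSE
  )

  structure(list(
    n_patients = as.integer(n_patients),
    slides_per_patient = as.integer(slides_per_patient),
    grid_side = as.integer(grid_side),
    tile_size = as.integer(tile_size),
    class_names = class_names,
    diseased_classes = diseased_classes,
    benign_filler_class = benign_filler_class,
    lesion_fraction = lesion_fraction,
    background_fraction = background_fraction,
    texture_noise = texture_noise,
    color_mode = color_mode,
    seed = as.integer(seed),
    textures = textures
  ), class = "cohort_params")
}

#' @export
print.cohort_params <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort parameters: %d patients, %d-%d slides each, %dx%d tiles of %d px\n",
    x$n_patients, x$slides_per_patient[1], x$slides_per_patient[2],
    x$grid_side, x$grid_side, x$tile_size))
  cat(sprintf("  classes: %s (diseased: %s, filler: %s)\n",
              paste(x$class_names, collapse = ", "),
              paste(x$diseased_classes, collapse = ", "),
              x$benign_filler_class))
  cat(sprintf("  lesion fraction %.2f, background fraction %.2f, noise %.2f, %s\n",
              x$lesion_fraction, x$background_fraction, x$texture_noise,
              x$color_mode))
  invisible(x)
}
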