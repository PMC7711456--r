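#' Generate one synthetic slide
#'
#' Builds a slide as a `grid_side x grid_side` lattice of rendered tiles.
#' `round(background_fraction * n_tiles)` lattice cells become near-white
#' background. If `label` is a diseased class, exactly
#' `round(lesion_fraction * n_tissue)` tissue cells carry the lesion texture,
#' planted as a contiguous lattice region (grown by randomized breadth-first
#' search, mirroring the spatial coherence of annotated lesion regions), and
#' the remaining tissue carries the benign filler texture; otherwise all
#' tissue tiles carry the label's own texture. A per-pixel annotation mask is
#' produced alongside (pixel value = 0-based class index, 255 = background).
#'
#' @param label slide class name.
#' @param params a [cohort_params()] object.
#' @param seed integer seed for this slide.
#' @return A list with components `slide` (a `slide_record`: `label`,
#'   `image`, `mask`, `stain`) and `truth` (data.frame `row`, `col`, `truth`
#'   with 0-based lattice coordinates).
#' @export
generate_slide <- function(label, params, seed) {
  stopifnot(inherits(params, "cohort_params"))
  if (!(label %in% params$class_names))
    stop(sprintf("unknown slide label '%s'", label))
  gs <- params$grid_side
  ts <- params$tile_size
  n_tiles <- gs * gs

  withr::with_seed(seed, {
    n_bg <- round(params$background_fraction * n_tiles)
    bg_cells <- sample.int(n_tiles, n_bg)
    tissue_cells <- setdiff(seq_len(n_tiles), bg_cells)

    truth <- rep(label, n_tiles)
    truth[bg_cells] <- "background"
    if (label %in% params$diseased_classes) {
      n_lesion <- round(params$lesion_fraction * length(tissue_cells))
      lesion <- grow_region(tissue_cells, gs, n_lesion)
      truth[tissue_cells] <- params$benign_filler_class
      truth[lesion] <- label
    }

    tile_seeds <- draw_seeds(n_tiles)
    stain <- if (params$color_mode == "rgb") stats::runif(3, 0.6, 1.4) else NULL

    image <- matrix(0, gs * ts, gs * ts)
    mask <- matrix(255L, gs * ts, gs * ts)
    for (i in seq_len(n_tiles)) {
      r <- (i - 1L) %/% gs
      c_ <- (i - 1L) %% gs
      tile <- render_tile_texture(truth[i], params, tile_seeds[i])
      rows <- r * ts + seq_len(ts)
      cols <- c_ * ts + seq_len(ts)
      image[rows, cols] <- tile
      if (truth[i] != "background")
        mask[rows, cols] <- match(truth[i], params$class_names) - 1L
    }
    if (!is.null(stain)) image <- apply_stain(image, stain)

    list(
      slide = structure(list(label = label, image = image, mask = mask,
                             stain = stain), class = "slide_record"),
      truth = data.frame(
        row = (seq_len(n_tiles) - 1L) %/% gs,
        col = (seq_len(n_tiles) - 1L) %% gs,
        truth = truth,
        stringsAsFactors = FALSE
      )
    )
  })
}

# grow a contiguous region of `size` cells over the tissue subset of the
# lattice; falls back to a fresh random seed cell if the current component
# is exhausted, so the requested count is always met exactly
grow_region <- function(tissue_cells, gs, size) {
  if (size <= 0) return(integer(0))
  tissue <- logical(gs * gs)
  tissue[tissue_cells] <- TRUE
  in_region <- logical(gs * gs)
  region <- integer(0)
  frontier <- sample(tissue_cells, 1L)
  while (length(region) < size) {
    if (length(frontier) == 0L) {
      left <- tissue_cells[!in_region[tissue_cells]]
      frontier <- sample(left, 1L)
    }
    pick <- if (length(frontier) == 1L) frontier else sample(frontier, 1L)
    frontier <- setdiff(frontier, pick)
    if (in_region[pick]) next
    in_region[pick] <- TRUE
    region <- c(region, pick)
    nb <- lattice_neighbors(pick, gs)
    frontier <- union(frontier, nb[tissue[nb] & !in_region[nb]])
  }
  region
}

lattice_neighbors <- function(cell, gs) {
  r <- (cell - 1L) %/% gs
  c_ <- (cell - 1L) %% gs
  nb <- rbind(c(r - 1L, c_), c(r + 1L, c_), c(r, c_ - 1L), c(r, c_ + 1L))
  nb <- nb[nb[, 1] >= 0 & nb[, 1] < gs & nb[, 2] >= 0 & nb[, 2] < gs, , drop = FALSE]
  nb[, 1] * gs + nb[, 2] + 1L
}

# tint a grayscale image with a per-slide stain vector, luminance-preserving:
# the optical density (1 - intensity) is scaled per channel by a vector whose
# luminance-weighted mean is 1, so grayscale conversion recovers the input
# up to clipping of very dark pixels
apply_stain <- function(gray, stain) {
  w <- c(0.299, 0.587, 0.114)
  s <- stain / sum(w * stain)
  out <- array(0, c(nrow(gray), ncol(gray), 3))
  for (ch in 1:3) out[, , ch] <- clip01(1 - (1 - gray) * s[ch])
  out
}

#' Generate a synthetic slide cohort
#'
#' Assigns each patient a diagnosis (classes balanced across patients, order
#' shuffled), draws the number of slides per patient, and renders every slide
#' with [generate_slide()]. All of a patient's slides share the patient's
#' class, which is what makes patient-grouped cross-validation meaningful.
#' Generation is a pure function of `params` (including `params$seed`).
#'
#' @param params a [cohort_params()] object.
#' @return An object of class `wsi_cohort`: list with `params`, `slides`
#'   (named list of `slide_record`s carrying `slide_id`, `patient_id`),
#'   `manifest` (data.frame: `slide_id`, `patient_id`, `label`, `image`,
#'   `mask` relative paths) and `truth` (per-tile ground truth table).
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  withr::with_seed(params$seed, {
    pat_labels <- sample(rep(params$class_names,
                             length.out = params$n_patients))
    rng <- seq(params$slides_per_patient[1], params$slides_per_patient[2])
    n_slides <- if (length(rng) == 1L) rep(rng, params$n_patients)
                else sample(rng, params$n_patients, replace = TRUE)
    total <- sum(n_slides)
    slide_seeds <- draw_seeds(total)

    slides <- vector("list", total)
    rows <- vector("list", total)
    truths <- vector("list", total)
    i <- 0L
    for (p in seq_len(params$n_patients)) {
      for (s in seq_len(n_slides[p])) {
        i <- i + 1L
        sid <- sprintf("S%03d", i)
        pid <- sprintf("P%03d", p)
        gen <- generate_slide(pat_labels[p], params, slide_seeds[i])
        gen$slide$slide_id <- sid
        gen$slide$patient_id <- pid
        slides[[i]] <- gen$slide
        rows[[i]] <- data.frame(
          slide_id = sid, patient_id = pid, label = pat_labels[p],
          image = file.path("images", paste0(sid, ".png")),
          mask = file.path("masks", paste0(sid, ".png")),
          stringsAsFactors = FALSE)
        truths[[i]] <- cbind(slide_id = sid, gen$truth)
      }
    }
    names(slides) <- vapply(slides, `[[`, "", "slide_id")
    structure(list(
      params = params,
      slides = slides,
      manifest = do.call(rbind, rows),
      truth = do.call(rbind, truths)
    ), class = "wsi_cohort")
  })
}

#' @export
print.wsi_cohort <- function(x, ...) {
  cat(sprintf("Synthetic WSI cohort: %d slides / %d patients\n",
              nrow(x$manifest), length(unique(x$manifest$patient_id))))
  print(table(x$manifest$label))
  invisible(x)
}

#' Write a cohort to disk as PNG images plus delimited tables
#'
#' Writes slide images under `dir/images/`, annotation masks under
#' `dir/masks/` (8-bit gray PNG, pixel value = 0-based class index, 255 =
#' background), the slide manifest as `manifest.csv` and the per-tile ground
#' truth as `truth.csv`.
#'
#' @param cohort a `wsi_cohort`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the manifest with paths relative to `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "wsi_cohort"))
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$slides) {
    png::writePNG(s$image, file.path(dir, "images", paste0(s$slide_id, ".png")))
    png::writePNG(s$mask / 255, file.path(dir, "masks", paste0(s$slide_id, ".png")))
  }
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(cohort$manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `manifest.csv`, `truth.csv`, `images/`,
#'   `masks/`.
#' @param params optionally, the [cohort_params()] the cohort was generated
#'   with (re-attached for downstream defaults).
#' @return A `wsi_cohort` (mask pixel values restored to integer class codes).
#' @export
read_cohort <- function(dir, params = NULL) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  truth <- utils::read.csv(file.path(dir, "truth.csv"),
                           stringsAsFactors = FALSE)
  slides <- lapply(seq_len(nrow(manifest)), function(i) {
    img <- png::readPNG(file.path(dir, manifest$image[i]))
    msk <- round(png::readPNG(file.path(dir, manifest$mask[i])) * 255)
    structure(list(slide_id = manifest$slide_id[i],
                   patient_id = manifest$patient_id[i],
                   label = manifest$label[i],
                   image = img, mask = msk, stain = NULL),
              class = "slide_record")
  })
  names(slides) <- manifest$slide_id
  structure(list(params = params, slides = slides, manifest = manifest,
                 truth = truth), class = "wsi_cohort")
}
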