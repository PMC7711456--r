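#' Extract and index the retained tiles of a whole cohort
#'
#' Runs [extract_and_filter_tiles()] over every slide of a cohort and stacks
#' the results, attaching patient id, slide label and (when the cohort
#' carries a ground-truth table and the stride equals the tile size) the
#' per-tile truth class.
#'
#' @param cohort a `wsi_cohort`.
#' @param tile_size,stride,min_tissue,background_threshold tiling options;
#'   tile size defaults to the cohort's generating parameters.
#' @return A `cohort_tiles` object: list with `tiles` (grayscale matrices)
#'   and `index` (data.frame `slide_id`, `patient_id`, `label`, `row`, `col`,
#'   `tissue_fraction`, optionally `truth`); attribute `lattice_dim`.
#' @export
cohort_tiles <- function(cohort, tile_size = NULL, stride = NULL,
                         min_tissue = 0.5, background_threshold = 0.9) {
  stopifnot(inherits(cohort, "wsi_cohort"))
  tile_size <- tile_size %||% cohort$params$tile_size
  if (is.null(tile_size)) stop("`tile_size` is required when the cohort carries no params")
  stride <- stride %||% tile_size
  tiles <- list()
  idx <- vector("list", length(cohort$slides))
  ld <- NULL
  for (i in seq_along(cohort$slides)) {
    s <- cohort$slides[[i]]
    tset <- extract_and_filter_tiles(s$image, tile_size, stride, min_tissue,
                                     background_threshold, s$slide_id)
    ld <- attr(tset, "lattice_dim")
    n <- length(tset$tiles)
    tiles <- c(tiles, tset$tiles)
    idx[[i]] <- cbind(tset$index,
                      data.frame(patient_id = rep(s$patient_id, n),
                                 label = rep(s$label, n),
                                 stringsAsFactors = FALSE))
  }
  index <- do.call(rbind, idx)
  if (!is.null(cohort$truth) && stride == tile_size) {
    key <- paste(index$slide_id, index$row, index$col)
    tkey <- paste(cohort$truth$slide_id, cohort$truth$row, cohort$truth$col)
    index$truth <- cohort$truth$truth[match(key, tkey)]
  }
  structure(list(tiles = tiles, index = index),
            class = "cohort_tiles", lattice_dim = ld, tile_size = tile_size)
}

as_cohort_tiles <- function(x, ...) {
  if (inherits(x, "cohort_tiles")) x else cohort_tiles(x, ...)
}

#' Label tiles from a pixel-wise annotation mask
#'
#' A tile is labeled with class `c` iff at least `min_coverage` of its pixels
#' carry mask value `c`; tiles reaching no class at `min_coverage` get `NA`.
#' Mask values are 0-based class indices into `class_names`; 255 marks
#' background and never contributes a label.
#'
#' @param mask integer mask matrix.
#' @param index data.frame with 0-based lattice `row`, `col`.
#' @param tile_size tile edge in pixels (also the lattice stride).
#' @param class_names ordered class vocabulary.
#' @param min_coverage minimum pixel fraction, default 0.5.
#' @return Character vector of labels (NA = excluded).
#' @export
tile_mask_labels <- function(mask, index, tile_size, class_names,
                             min_coverage = 0.5) {
  vapply(seq_len(nrow(index)), function(i) {
    win <- mask[index$row[i] * tile_size + seq_len(tile_size),
                index$col[i] * tile_size + seq_len(tile_size)]
    cov <- vapply(seq_along(class_names) - 1L,
                  function(k) mean(win == k), numeric(1))
    if (max(cov) >= min_coverage) class_names[which.max(cov)]
    else NA_character_
  }, character(1))
}

#' Build the fully supervised tile training set
#'
#' Labels every retained tissue tile from its slide's pixel-wise annotation
#' mask (see [tile_mask_labels()]); tiles without sufficient single-class
#' coverage are excluded. Every slide must carry a mask.
#'
#' @param x a `wsi_cohort` whose slides have masks.
#' @param min_coverage minimum within-tile mask coverage for a label.
#' @param ... tiling options passed to [cohort_tiles()].
#' @return List with `tiles`, `labels` (factor) and `index`.
#' @export
build_fs_tileset <- function(x, min_coverage = 0.5, ...) {
  stopifnot(inherits(x, "wsi_cohort"))
  if (any(vapply(x$slides, function(s) is.null(s$mask), logical(1))))
    stop("every slide needs an annotation mask for the fully supervised route")
  ct <- cohort_tiles(x, ...)
  ts <- attr(ct, "tile_size")
  classes <- x$params$class_names %||% sort(unique(x$manifest$label))
  labels <- rep(NA_character_, nrow(ct$index))
  for (sid in unique(ct$index$slide_id)) {
    sel <- ct$index$slide_id == sid
    labels[sel] <- tile_mask_labels(x$slides[[sid]]$mask, ct$index[sel, ],
                                    ts, classes, min_coverage)
  }
  keep <- !is.na(labels)
  list(tiles = ct$tiles[keep], labels = factor(labels[keep]),
       index = ct$index[keep, , drop = FALSE])
}

#' Build the MIL tile training set
#'
#' Every retained tile inherits its slide's label (bags are labeled,
#' instances are not); the tile count is preserved.
#'
#' @param x a `wsi_cohort` or `cohort_tiles`.
#' @param ... tiling options when `x` is a cohort.
#' @return List with `tiles`, `labels` (factor) and `index`.
#' @export
build_mil_tileset <- function(x, ...) {
  ct <- as_cohort_tiles(x, ...)
  if (any(is.na(ct$index$label)))
    stop("every slide needs a label for the MIL route")
  list(tiles = ct$tiles, labels = factor(ct$index$label), index = ct$index)
}

#' Gaussian smoothing of a lattice probability map
#'
#' Convolves a per-tile value grid with a 2-D Gaussian kernel of standard
#' deviation `sigma` lattice units (truncated at 3 sigma). Cells removed by
#' the tissue filter are `NA`: they contribute nothing and stay `NA`, and the
#' kernel weights are renormalized over the present cells, so a constant map
#' is reproduced exactly. `sigma = 0` is the identity.
#'
#' @param grid numeric matrix, `NA` = missing cell.
#' @param sigma kernel standard deviation in lattice units (>= 0).
#' @return Smoothed grid, same shape and `NA` pattern.
#' @export
smooth_probability_map <- function(grid, sigma = 1) {
  stopifnot(is.matrix(grid))
  if (sigma < 0) stop("`sigma` must be nonnegative")
  if (sigma == 0) return(grid)
  r <- ceiling(3 * sigma)
  present <- !is.na(grid)
  vals <- ifelse(present, grid, 0)
  num <- matrix(0, nrow(grid), ncol(grid))
  den <- matrix(0, nrow(grid), ncol(grid))
  nr <- nrow(grid); nc <- ncol(grid)
  for (dy in -r:r) for (dx in -r:r) {
    w <- exp(-(dx^2 + dy^2) / (2 * sigma^2))
    src_r <- max(1, 1 - dy):min(nr, nr - dy)
    src_c <- max(1, 1 - dx):min(nc, nc - dx)
    dst_r <- src_r + dy
    dst_c <- src_c + dx
    num[dst_r, dst_c] <- num[dst_r, dst_c] + w * vals[src_r, src_c]
    den[dst_r, dst_c] <- den[dst_r, dst_c] + w * present[src_r, src_c]
  }
  out <- num / den
  out[!present] <- NA
  out
}

#' Select discriminative tiles by thresholding a smoothed map
#'
#' A tile is discriminative (`z = 1`) iff its smoothed value for the slide's
#' own class lies strictly above `threshold`. If no tile qualifies the single
#' maximum-value tile is kept, so a slide never contributes an empty bag.
#'
#' @param smoothed numeric grid (`NA` = missing cell), values in \[0, 1\].
#' @param threshold selection threshold.
#' @return Logical grid (`NA` preserved).
#' @export
select_discriminative <- function(smoothed, threshold) {
  stopifnot(is.matrix(smoothed))
  z <- smoothed > threshold
  if (!any(z, na.rm = TRUE)) {
    top <- which(smoothed == max(smoothed, na.rm = TRUE))[1]
    z[top] <- TRUE
  }
  z
}

#' EM configuration for discriminative-patch training
#'
#' @param threshold selection threshold on the smoothed own-class
#'   probability. Default 0.5: a tile is kept iff its (smoothed) support for
#'   the slide's class outweighs all alternatives combined, which separates
#'   planted lesion tissue from benign filler shared with benign slides.
#' @param sigma Gaussian smoothing bandwidth in lattice units.
#' @param epsilon convergence threshold on the fraction of tiles whose
#'   indicator changed between E-steps.
#' @param max_iters maximum EM iterations (>= 1).
#' @param classifier a [classifier_config()] for the M-step (its seed is
#'   advanced by one per iteration).
#' @return A config list.
#' @export
em_config <- function(threshold = 0.5, sigma = 1, epsilon = 0.01,
                      max_iters = 10L, classifier = classifier_config()) {
  if (max_iters < 1) stop("`max_iters` must be at least 1")
  as.list(environment())
}

# lattice grid of per-tile values for one slide (NA where filtered)
lattice_grid <- function(values, rows, cols, dim) {
  g <- matrix(NA_real_, dim[1], dim[2])
  g[cbind(rows + 1L, cols + 1L)] <- values
  g
}

#' EM training over discriminative patches
#'
#' Implements discriminative-patch selection for weakly supervised training.
#' Iteration 0 marks every retained tissue tile discriminative (`z = 1`).
#' Each M-step retrains the tile classifier on the currently discriminative
#' tiles under MIL labels (slide label per tile); each E-step predicts the
#' slide-class probability of every tile, smooths it over the slide lattice
#' ([smooth_probability_map()]) and rethresholds
#' ([select_discriminative()]). The loop stops when the fraction of tiles
#' whose indicator changed drops below `epsilon`, or at `max_iters`. With
#' `max_iters = 1` and `threshold = 0` this reduces exactly to plain MIL
#' training.
#'
#' @param x a `wsi_cohort` or `cohort_tiles` with slide labels.
#' @param config an [em_config()].
#' @param ... tiling options when `x` is a cohort.
#' @return An `em_fit`: list with `classifier` (final M-step model), `masks`
#'   (data.frame `slide_id`, `row`, `col`, `z`, `smoothed_value`,
#'   `iteration`), `log` (per-iteration changed fraction and selected count)
#'   and `index`.
#' @export
em_train <- function(x, config = em_config(), ...) {
  ct <- as_cohort_tiles(x, ...)
  if (length(unique(ct$index$label)) < 2)
    stop("EM training needs slides from at least two classes")
  ld <- attr(ct, "lattice_dim")
  desc <- tile_descriptors(ct$tiles, config$classifier$n_freq,
                           config$classifier$n_orient)
  labels <- factor(ct$index$label)
  n <- nrow(desc)
  z <- rep(TRUE, n)
  smoothed <- rep(NA_real_, n)
  log_rows <- list()
  clf <- NULL
  slide_ids <- unique(ct$index$slide_id)
  slide_rows <- split(seq_len(n), ct$index$slide_id)[slide_ids]

  for (it in seq_len(config$max_iters)) {
    cfg <- config$classifier
    cfg$seed <- cfg$seed + it - 1L
    clf <- train_tile_classifier(desc[z, , drop = FALSE],
                                 droplevels(labels[z]), cfg)
    P <- predict_concept_probabilities(clf, desc)
    z_new <- logical(n)
    for (sid in slide_ids) {
      rows <- slide_rows[[sid]]
      lab <- ct$index$label[rows[1]]
      pcol <- match(lab, colnames(P))
      if (is.na(pcol)) {            # class dropped from the training bag
        smoothed[rows] <- 0
        z_new[rows[which.max(rep(1, length(rows)))]] <- TRUE
        next
      }
      g <- lattice_grid(P[rows, pcol], ct$index$row[rows],
                        ct$index$col[rows], ld)
      sm <- smooth_probability_map(g, config$sigma)
      zg <- select_discriminative(sm, config$threshold)
      smoothed[rows] <- sm[cbind(ct$index$row[rows] + 1L,
                                 ct$index$col[rows] + 1L)]
      z_new[rows] <- zg[cbind(ct$index$row[rows] + 1L,
                              ct$index$col[rows] + 1L)]
    }
    changed <- mean(z != z_new)
    log_rows[[it]] <- data.frame(iteration = it, changed_fraction = changed,
                                 n_selected = sum(z_new))
    z <- z_new
    if (changed < config$epsilon) break
  }

  structure(list(
    classifier = clf,
    masks = data.frame(slide_id = ct$index$slide_id,
                       row = ct$index$row, col = ct$index$col,
                       z = as.integer(z), smoothed_value = smoothed,
                       iteration = length(log_rows),
                       stringsAsFactors = FALSE),
    log = do.call(rbind, log_rows),
    index = ct$index
  ), class = "em_fit")
}
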