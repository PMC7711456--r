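#' Per-concept permutation importance for one class
#'
#' Importance of concept m for class C is the mean increase, over `repeats`
#' random shuffles of histogram column m across slides, of the model's
#' one-vs-rest prediction error for class C relative to the unshuffled
#' baseline. The default error functional is the one-vs-rest Brier score
#' (squared error of the class-C score against the class indicator; SVM
#' decision values pass through a logistic link first). The 0/1
#' misclassification functional (`error = "zero_one"`) is also available,
#' but with many redundant codeblocks shuffling a single column rarely flips
#' a hard label, which drives every importance to exactly zero; the graded
#' functional preserves class-specific ranking information in that regime.
#' A constant column yields importance exactly 0 under either functional.
#' Deterministic given the seed.
#'
#' @param model a `fusion_classifier`.
#' @param histograms matrix `n_slides x K` (the evaluation set).
#' @param labels slide labels.
#' @param class_c the class whose error functional is used.
#' @param repeats number of shuffles per concept (R >= 1).
#' @param seed integer seed.
#' @param error `"brier"` (default) or `"zero_one"`.
#' @return Numeric vector of length K.
#' @export
permutation_importance <- function(model, histograms, labels, class_c,
                                   repeats = 10L, seed = 1L,
                                   error = c("brier", "zero_one")) {
  error <- match.arg(error)
  h <- as.matrix(histograms)
  labels <- as.character(labels)
  stopifnot(nrow(h) >= 1, repeats >= 1)
  if (!class_c %in% labels) stop(sprintf("class '%s' not present in labels", class_c))
  y <- as.numeric(labels == class_c)
  err_c <- function(hm) {
    out <- predict_slide(model, hm)
    if (error == "zero_one") {
      mean((out$label == class_c) != (labels == class_c))
    } else {
      s <- out$scores[, class_c]
      if (model$kind == "svm") s <- stats::plogis(s)
      mean((s - y)^2)
    }
  }
  base <- err_c(h)
  withr::with_seed(seed, {
    vapply(seq_len(ncol(h)), function(m) {
      mean(vapply(seq_len(repeats), function(r) {
        h2 <- h
        h2[, m] <- h[sample.int(nrow(h)), m]
        err_c(h2)
      }, numeric(1))) - base
    }, numeric(1))
  })
}

#' Permutation-importance table over all classes
#'
#' @param model a `fusion_classifier`.
#' @param histograms,labels evaluation set.
#' @param classes classes to score (default: the model's).
#' @param repeats,seed,error as in [permutation_importance()].
#' @return Matrix `n_classes x K` (rows named by class).
#' @export
importance_table <- function(model, histograms, labels,
                             classes = model$classes, repeats = 10L,
                             seed = 1L, error = c("brier", "zero_one")) {
  error <- match.arg(error)
  out <- t(vapply(seq_along(classes), function(i)
    permutation_importance(model, histograms, labels, classes[i],
                           repeats = repeats, seed = seed + i - 1L,
                           error = error),
    numeric(ncol(as.matrix(histograms)))))
  rownames(out) <- classes
  out
}

#' Propagate concept importances onto tiles
#'
#' A tile's importance for class C is the posterior-weighted sum of the
#' codeblock importances, `I_x = sum_m p(c_m | f(x)) * I[C, m]` — a convex
#' combination when the posterior sums to one, and linear in the posterior.
#'
#' @param posteriors matrix `n_tiles x K` of codeblock posteriors.
#' @param importances numeric length-K importance row for one class.
#' @return Numeric vector of per-tile importances.
#' @export
tile_importance <- function(posteriors, importances) {
  P <- as.matrix(posteriors)
  if (ncol(P) != length(importances))
    stop("posterior and importance lengths differ")
  drop(P %*% importances)
}

#' Class-probability heatmap of one slide
#'
#' For class-based mappers (FS/MIL/EM) the heatmap cell for a retained tile
#' is its predicted probability of class C; filtered cells are `NA`.
#'
#' @param model a `tile_classifier`.
#' @param tiles a `tile_set` for one slide (from
#'   [extract_and_filter_tiles()]).
#' @param class_c class name.
#' @return Numeric lattice matrix (values in \[0, 1\], `NA` = filtered cell).
#' @export
class_probability_heatmap <- function(model, tiles, class_c) {
  stopifnot(inherits(tiles, "tile_set"))
  if (!class_c %in% model$classes)
    stop(sprintf("class '%s' is outside the model vocabulary", class_c))
  P <- predict_concept_probabilities(model, tiles)
  lattice_grid(P[, class_c], tiles$index$row, tiles$index$col,
               attr(tiles, "lattice_dim"))
}

#' Importance map on the slide lattice
#'
#' Arranges per-tile importance values (e.g. from [tile_importance()]) onto
#' the slide's tile lattice.
#'
#' @param values per-tile values.
#' @param index data.frame with 0-based `row`, `col` for each value.
#' @param lattice_dim c(rows, cols) of the lattice.
#' @return Numeric lattice matrix with `NA` at missing cells.
#' @export
importance_map <- function(values, index, lattice_dim) {
  lattice_grid(values, index$row, index$col, lattice_dim)
}

#' Render a lattice importance map as a raster overlay
#'
#' Min-max normalizes the map per slide (an all-equal map renders at uniform
#' mid-scale), applies a blue-to-red colormap (red = high attention), and
#' expands each lattice cell to a `tile_size` pixel block so the overlay has
#' the slide's dimensions. Missing cells are fully transparent.
#'
#' @param map lattice matrix (`NA` = missing).
#' @param tile_size pixels per lattice cell.
#' @param alpha overlay opacity for present cells.
#' @param path optional PNG output path.
#' @return H x W x 4 RGBA array in \[0, 1\] (invisibly when written to
#'   `path`).
#' @export
render_heatmap <- function(map, tile_size, alpha = 0.6, path = NULL) {
  stopifnot(is.matrix(map), any(!is.na(map)))
  rng <- range(map, na.rm = TRUE)
  norm <- if (diff(rng) < 1e-12) {
    m <- map; m[!is.na(m)] <- 0.5; m
  } else (map - rng[1]) / diff(rng)
  ramp <- grDevices::colorRamp(c("#313695", "#ffffbf", "#a50026"))
  h <- nrow(map) * tile_size; w <- ncol(map) * tile_size
  out <- array(0, c(h, w, 4))
  for (r in seq_len(nrow(map))) for (c_ in seq_len(ncol(map))) {
    rows <- (r - 1) * tile_size + seq_len(tile_size)
    cols <- (c_ - 1) * tile_size + seq_len(tile_size)
    if (is.na(norm[r, c_])) next
    rgb <- ramp(norm[r, c_]) / 255
    out[rows, cols, 1] <- rgb[1]
    out[rows, cols, 2] <- rgb[2]
    out[rows, cols, 3] <- rgb[3]
    out[rows, cols, 4] <- alpha
  }
  if (!is.null(path)) {
    png::writePNG(out, path)
    return(invisible(out))
  }
  out
}
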