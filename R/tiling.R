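#' Convert an RGB raster or tile to grayscale
#'
#' Uses the standard luminance weighting 0.299 R + 0.587 G + 0.114 B.
#' Grayscale input (a plain matrix) passes through unchanged.
#'
#' @param img numeric matrix (grayscale) or H x W x 3 array in \[0, 1\].
#' @return Numeric matrix in \[0, 1\].
#' @export
to_grayscale <- function(img) {
  if (is.matrix(img)) return(img)
  if (length(dim(img)) == 3 && dim(img)[3] >= 3)
    return(matrix(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3],
                  dim(img)[1], dim(img)[2]))
  if (length(dim(img)) == 3 && dim(img)[3] == 1)
    return(matrix(img[, , 1], dim(img)[1], dim(img)[2]))
  stop("expected a matrix or an H x W x 3 array")
}

#' Fraction of tissue pixels in a tile
#'
#' A pixel counts as tissue iff its grayscale intensity lies strictly below
#' `background_threshold` (near-white pixels are background).
#'
#' @param tile numeric matrix or RGB array.
#' @param background_threshold intensity cut-off, default 0.9.
#' @return Fraction in \[0, 1\].
#' @export
tissue_fraction <- function(tile, background_threshold = 0.9) {
  mean(to_grayscale(tile) < background_threshold)
}

#' Sliding-window tile extraction with tissue filtering
#'
#' Enumerates tile windows row-major over the lattice defined by `stride`
#' (top-left origin, 0-based lattice coordinates), drops partial edge
#' windows, computes each window's tissue fraction on the grayscale image,
#' and discards windows whose tissue fraction falls below `min_tissue`.
#'
#' @param image raster: numeric matrix or H x W x 3 array in \[0, 1\].
#' @param tile_size tile edge in pixels.
#' @param stride window step in pixels; defaults to `tile_size`
#'   (non-overlapping partition).
#' @param min_tissue minimum tissue fraction for a tile to be retained.
#' @param background_threshold grayscale intensity above which a pixel is
#'   background.
#' @param slide_id optional id recorded in the index.
#' @return A `tile_set`: list with `tiles` (list of grayscale pixel matrices;
#'   RGB input is converted once here so all downstream stages see
#'   luminance), `index` (data.frame `slide_id`, `row`, `col`,
#'   `tissue_fraction`) and attributes `lattice_dim` (full lattice rows/cols
#'   before filtering) and `tile_size`.
#' @export
extract_and_filter_tiles <- function(image, tile_size, stride = tile_size,
                                     min_tissue = 0.5,
                                     background_threshold = 0.9,
                                     slide_id = NA_character_) {
  gray <- to_grayscale(image)
  h <- nrow(gray); w <- ncol(gray)
  if (h < tile_size || w < tile_size)
    stop("image is smaller than one tile")
  if (!(min_tissue > 0 && min_tissue <= 1))
    stop("`min_tissue` must lie in (0, 1]")
  n_r <- (h - tile_size) %/% stride + 1L
  n_c <- (w - tile_size) %/% stride + 1L

  tiles <- list()
  rows <- integer(0); cols <- integer(0); tf <- numeric(0)
  for (r in seq_len(n_r) - 1L) {
    for (c_ in seq_len(n_c) - 1L) {
      win <- gray[r * stride + seq_len(tile_size),
                  c_ * stride + seq_len(tile_size)]
      frac <- mean(win < background_threshold)
      if (frac >= min_tissue) {
        tiles[[length(tiles) + 1L]] <- win
        rows <- c(rows, r); cols <- c(cols, c_); tf <- c(tf, frac)
      }
    }
  }
  structure(list(
    tiles = tiles,
    index = data.frame(slide_id = rep(slide_id, length(tiles)),
                       row = rows, col = cols, tissue_fraction = tf,
                       stringsAsFactors = FALSE)
  ), class = "tile_set", lattice_dim = c(n_r, n_c), tile_size = tile_size)
}

# rotate a matrix 90 degrees clockwise
rot90cw <- function(m) t(m[nrow(m):1, , drop = FALSE])

#' Apply a dihedral transform to a square tile
#'
#' @param tile square numeric matrix.
#' @param flip logical; horizontal flip (columns reversed) applied first.
#' @param rot number of 90-degree clockwise rotations (0-3).
#' @return Transformed tile.
#' @export
dihedral_transform <- function(tile, flip = FALSE, rot = 0L) {
  stopifnot(nrow(tile) == ncol(tile))
  if (flip) tile <- tile[, ncol(tile):1, drop = FALSE]
  rot <- as.integer(rot) %% 4L
  for (i in seq_len(rot)) tile <- rot90cw(tile)
  tile
}

#' Random training-time tile augmentation
#'
#' Draws one of the eight symmetries generated by an optional horizontal
#' flip and a random 0/90/180/270-degree rotation. The pixel-intensity
#' multiset is preserved exactly.
#'
#' @param tile square numeric matrix.
#' @param seed integer seed.
#' @return Augmented tile.
#' @export
augment_tile <- function(tile, seed) {
  withr::with_seed(seed, {
    dihedral_transform(tile, flip = sample(c(FALSE, TRUE), 1L),
                       rot = sample(0:3, 1L))
  })
}

#' Per-tile intensity standardization (optional preprocessing)
#'
#' Subtracts the tile mean, divides by the tile standard deviation, and
#' re-clips to \[0, 1\]. Off by default throughout the pipeline; provided as a
#' configurable alternative to stain handling by grayscale conversion alone.
#'
#' @param tile numeric matrix.
#' @return Standardized tile in \[0, 1\].
#' @export
standardize_intensity <- function(tile) {
  s <- stats::sd(tile)
  if (s < 1e-12) return(clip01(tile - mean(tile)))
  clip01((tile - mean(tile)) / s)
}
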