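.descriptor_cache <- new.env(parent = emptyenv())

# Precompute the spectral bin layout for a tile size: each non-DC Fourier
# coefficient is assigned to one of n_freq log-spaced radial bands crossed
# with n_orient orientation bins over [0, pi).
descriptor_bins <- function(tile_size, n_freq = 8L, n_orient = 6L) {
  key <- sprintf("%d_%d_%d", tile_size, n_freq, n_orient)
  if (!is.null(.descriptor_cache[[key]])) return(.descriptor_cache[[key]])
  idx <- seq_len(tile_size) - 1
  f <- ifelse(idx > tile_size / 2, idx - tile_size, idx)
  fy <- matrix(f, tile_size, tile_size)          # row frequencies
  fx <- matrix(f, tile_size, tile_size, byrow = TRUE)
  r <- sqrt(fx^2 + fy^2)
  ang <- atan2(fy, fx) %% pi
  edges <- exp(seq(log(1.5), log(tile_size / 2), length.out = n_freq + 1))
  band <- findInterval(as.vector(r), edges, rightmost.closed = TRUE)
  obin <- pmin(floor(as.vector(ang) / (pi / n_orient)) + 1L, n_orient)
  valid <- band >= 1L & band <= n_freq
  cell <- integer(length(band))
  cell[valid] <- (band[valid] - 1L) * n_orient + obin[valid]
  out <- list(cell = cell, valid = valid, n_cells = n_freq * n_orient,
              n_freq = n_freq, n_orient = n_orient)
  .descriptor_cache[[key]] <- out
  out
}

#' Fixed spectral texture descriptors for tiles
#'
#' The tile backbone's filter-bank stage: each grayscale tile is mapped to
#' the log energies of its 2-D Fourier power spectrum binned into
#' `n_freq` log-spaced radial frequency bands times `n_orient` orientation
#' bins, plus the tile mean and standard deviation. The representation is
#' invariant to grating phase (translation) and equivariant under the
#' dihedral augmentation group: 90-degree rotations and flips act on the
#' descriptor as a permutation of its orientation bins (see
#' [descriptor_dihedral_perms()]), which is what makes feature-space
#' augmentation exact.
#'
#' @param x a `tile_set`, a list of grayscale tile matrices, or one matrix.
#' @param n_freq number of radial frequency bands.
#' @param n_orient number of orientation bins (must be even).
#' @return Numeric matrix, one row per tile, `n_freq * n_orient + 2` columns.
#' @export
tile_descriptors <- function(x, n_freq = 8L, n_orient = 6L) {
  tiles <- if (inherits(x, "tile_set")) x$tiles
           else if (is.matrix(x)) list(x) else x
  stopifnot(length(tiles) >= 1)
  ts <- nrow(tiles[[1]])
  bins <- descriptor_bins(ts, n_freq, n_orient)
  out <- matrix(0, length(tiles), bins$n_cells + 2L)
  for (i in seq_along(tiles)) {
    m <- tiles[[i]]
    if (nrow(m) != ts || ncol(m) != ts) stop("tiles differ in shape")
    pv <- as.vector(Mod(stats::fft(m))^2)
    rs <- rowsum(pv[bins$valid], bins$cell[bins$valid])
    e <- numeric(bins$n_cells)
    e[as.integer(rownames(rs))] <- rs
    out[i, ] <- c(log(e + 1e-12), mean(m), stats::sd(m))
  }
  colnames(out) <- c(sprintf("E_f%d_o%d",
                             rep(seq_len(n_freq), each = n_orient),
                             rep(seq_len(n_orient), n_freq)),
                     "mean", "sd")
  out
}

#' Descriptor-space action of the dihedral augmentation group
#'
#' Rotating a tile by 90 degrees shifts every Fourier orientation by pi/2,
#' i.e. cycles the orientation bins by `n_orient / 2`; a horizontal flip
#' reflects them. The four distinct actions (180-degree rotation acts
#' trivially on the power spectrum) are returned as permutations of the
#' descriptor columns, used for training-time augmentation in feature space.
#'
#' @param n_freq,n_orient descriptor layout (as in [tile_descriptors()]).
#' @return List of 4 integer permutation vectors (first one the identity).
#' @export
descriptor_dihedral_perms <- function(n_freq = 8L, n_orient = 6L) {
  if (n_orient %% 2L != 0L) stop("`n_orient` must be even")
  n_cells <- n_freq * n_orient
  shift <- function(o) ((o - 1L + n_orient %/% 2L) %% n_orient) + 1L
  reflect <- function(o) n_orient - o + 1L
  actions <- list(function(o) o, shift, reflect, function(o) shift(reflect(o)))
  lapply(actions, function(a) {
    perm <- seq_len(n_cells + 2L)
    for (b in seq_len(n_freq)) {
      o <- seq_len(n_orient)
      perm[(b - 1L) * n_orient + a(o)] <- (b - 1L) * n_orient + o
    }
    perm
  })
}
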