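#' Training configuration for the tile classifier
#'
#' The desk-scale backbone: a fixed oriented band-pass filter bank in the
#' Fourier domain ([tile_descriptors()]) feeding a trainable dense hidden
#' layer (ReLU) with dropout and a softmax head over the class vocabulary.
#' Training uses seeded Adam on the cross-entropy loss; augmentation (the
#' dihedral flip/rotation group) is applied during training only, acting on
#' descriptors as exact orientation-bin permutations.
#'
#' @param hidden dense hidden units.
#' @param epochs,batch,lr Adam schedule.
#' @param dropout dropout probability on the dense head (0.5 as in the
#'   reference preset).
#' @param l2 weight decay.
#' @param seed training seed; training is bit-reproducible given the seed
#'   and data order.
#' @param augment apply dihedral augmentation during training.
#' @param n_freq,n_orient descriptor layout.
#' @return A config list.
#' @export
classifier_config <- function(hidden = 64L, epochs = 60L, batch = 64L,
                              lr = 5e-3, dropout = 0.5, l2 = 1e-4,
                              seed = 1L, augment = TRUE,
                              n_freq = 8L, n_orient = 6L) {
  as.list(environment())
}

resolve_descriptors <- function(x, n_freq, n_orient, tile_size = NA_integer_) {
  if (inherits(x, "tile_set") || is.list(x)) {
    tiles <- if (inherits(x, "tile_set")) x$tiles else x
    list(desc = tile_descriptors(tiles, n_freq, n_orient),
         tile_size = nrow(tiles[[1]]))
  } else if (is.matrix(x)) {
    nf <- n_freq * n_orient + 2L
    if (ncol(x) == nf) {
      list(desc = x, tile_size = tile_size)
    } else if (nrow(x) == ncol(x) &&
               (is.na(tile_size) || nrow(x) == tile_size)) {
      list(desc = tile_descriptors(x, n_freq, n_orient), tile_size = nrow(x))
    } else {
      stop("input shape matches neither the descriptor layout nor the training tile shape")
    }
  } else stop("expected a tile_set, a list of tiles, or a matrix")
}

#' Train the tile-level concept classifier
#'
#' Fits the softmax tile classifier used by the fully supervised, MIL and EM
#' routes: the concept vocabulary is the set of tile classes, and the model
#' outputs `p(c_k | f(x))` for every tile.
#'
#' @param x tiles: a `tile_set`, a list of grayscale tile matrices, or a
#'   precomputed descriptor matrix from [tile_descriptors()].
#' @param labels tile labels (length = number of tiles; at least 2 classes).
#' @param config a [classifier_config()].
#' @return A `tile_classifier` object.
#' @export
train_tile_classifier <- function(x, labels, config = classifier_config()) {
  labels <- factor(labels)
  if (nlevels(labels) < 2)
    stop("tile training set must contain at least two classes")
  rd <- resolve_descriptors(x, config$n_freq, config$n_orient)
  if (nrow(rd$desc) != length(labels))
    stop("labels must match the number of tiles")
  aug <- if (isTRUE(config$augment))
    descriptor_dihedral_perms(config$n_freq, config$n_orient) else NULL
  fit <- mlp_softmax_train(rd$desc, as.integer(labels), nlevels(labels),
                           hidden = config$hidden, epochs = config$epochs,
                           batch = config$batch, lr = config$lr,
                           dropout = config$dropout, l2 = config$l2,
                           seed = config$seed, aug_perms = aug)
  structure(list(fit = fit, classes = levels(labels),
                 tile_size = rd$tile_size, config = config),
            class = "tile_classifier")
}

#' Concept probabilities for tiles
#'
#' Evaluation-mode (deterministic, dropout off) softmax output of the tile
#' classifier: one probability vector over the class vocabulary per tile.
#'
#' @param model a `tile_classifier`.
#' @param x tiles in any form accepted by [train_tile_classifier()]; a single
#'   tile matrix yields a single row.
#' @return Matrix `n_tiles x K` with rows summing to 1; column names are the
#'   class vocabulary.
#' @export
predict_concept_probabilities <- function(model, x) {
  stopifnot(inherits(model, "tile_classifier"))
  rd <- resolve_descriptors(x, model$config$n_freq, model$config$n_orient,
                            model$tile_size)
  if (ncol(rd$desc) != length(model$fit$center))
    stop("descriptor length does not match the trained model")
  P <- mlp_softmax_predict(model$fit, rd$desc)
  colnames(P) <- model$classes
  P
}

#' @export
print.tile_classifier <- function(x, ...) {
  cat(sprintf("Tile classifier: %d classes (%s), %d descriptor features, %d hidden units\n",
              length(x$classes), paste(x$classes, collapse = ", "),
              length(x$fit$center), ncol(x$fit$W1)))
  invisible(x)
}

#' Training configuration for the tile autoencoder
#'
#' @param epochs,batch,lr Adam schedule.
#' @param pool decoder works at a `pool`-fold reduced raster which is
#'   upsampled back to tile shape (nearest neighbour); tile_size must be a
#'   multiple of `pool`.
#' @param seed training seed.
#' @param n_freq,n_orient encoder descriptor layout.
#' @return A config list.
#' @export
autoencoder_config <- function(epochs = 80L, batch = 64L, lr = 5e-3,
                               pool = 4L, seed = 1L,
                               n_freq = 8L, n_orient = 6L) {
  as.list(environment())
}

pool_tile <- function(m, f) {
  g <- nrow(m) %/% f
  t(rowsum(t(rowsum(m, rep(seq_len(g), each = f))),
           rep(seq_len(g), each = f))) / f^2
}

#' Train the tile autoencoder
#'
#' Unsupervised embedding model for the codebook routes: the encoder maps a
#' tile through the spectral filter bank into a tanh bottleneck of dimension
#' `embed_dim` (the embedding), and a linear decoder reconstructs the tile at
#' a pooled resolution that is upsampled back to tile shape. The training
#' objective is mean squared reconstruction error.
#'
#' @param x unlabeled tiles (`tile_set` or list of grayscale matrices).
#' @param embed_dim embedding dimension E; must be smaller than the tile
#'   pixel count.
#' @param config an [autoencoder_config()].
#' @return A `tile_autoencoder` object.
#' @export
train_autoencoder <- function(x, embed_dim = 32L,
                              config = autoencoder_config()) {
  tiles <- if (inherits(x, "tile_set")) x$tiles else x
  stopifnot(length(tiles) >= 2)
  ts <- nrow(tiles[[1]])
  if (embed_dim >= ts * ts)
    stop("`embed_dim` must be smaller than the tile pixel count")
  if (ts %% config$pool != 0) stop("tile size must be a multiple of `pool`")
  desc <- tile_descriptors(tiles, config$n_freq, config$n_orient)
  g <- ts %/% config$pool
  Yt <- t(vapply(tiles, function(m) as.vector(pool_tile(m, config$pool)),
                 numeric(g * g)))
  fit <- mlp_ae_train(desc, Yt, embed_dim, epochs = config$epochs,
                      batch = config$batch, lr = config$lr,
                      seed = config$seed)
  structure(list(fit = fit, embed_dim = as.integer(embed_dim),
                 tile_size = ts, config = config),
            class = "tile_autoencoder")
}

#' Embed tiles into the autoencoder's latent space
#'
#' @param model a `tile_autoencoder`.
#' @param x tiles (`tile_set`, list, single tile matrix, or descriptor
#'   matrix).
#' @return Matrix `n_tiles x embed_dim`.
#' @export
embed_tiles <- function(model, x) {
  stopifnot(inherits(model, "tile_autoencoder"))
  rd <- resolve_descriptors(x, model$config$n_freq, model$config$n_orient,
                            model$tile_size)
  if (ncol(rd$desc) != length(model$fit$center))
    stop("descriptor length does not match the trained model")
  mlp_ae_embed(model$fit, rd$desc)
}

#' Reconstruct tiles from the autoencoder
#'
#' @param model a `tile_autoencoder`.
#' @param x tiles as in [embed_tiles()].
#' @return List of reconstructed tile matrices (tile shape).
#' @export
reconstruct_tiles <- function(model, x) {
  Z <- embed_tiles(model, x)
  Y <- mlp_ae_decode(model$fit, Z)
  g <- model$tile_size %/% model$config$pool
  up <- matrix(1, model$config$pool, model$config$pool)
  lapply(seq_len(nrow(Y)), function(i)
    kronecker(matrix(Y[i, ], g, g), up))
}

#' @export
print.tile_autoencoder <- function(x, ...) {
  cat(sprintf("Tile autoencoder: %d-px tiles -> E = %d (pool %d decoder)\n",
              x$tile_size, x$embed_dim, x$config$pool))
  invisible(x)
}
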