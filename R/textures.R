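#' Render one synthetic tile texture
#'
#' Draws a single grayscale tile for a texture class of a cohort, or a
#' near-white background tile. Class textures are oriented sinusoid gratings;
#' per-tile randomness covers grating phase, amplitude, a small mean-intensity
#' jitter, orientation/log-frequency jitter scaled by `texture_noise`, and
#' additive pixel noise. Intensities are clipped to \[0, 1\]. The same
#' `(class_id, seed)` pair always renders a bit-identical tile.
#'
#' @param class_id a class name from `params$class_names`, or `"background"`.
#' @param params a [cohort_params()] object.
#' @param seed integer seed for this tile.
#' @return A `tile_size x tile_size` numeric matrix in \[0, 1\].
#' @export
render_tile_texture <- function(class_id, params, seed) {
  stopifnot(inherits(params, "cohort_params"))
  ts <- params$tile_size
  if (identical(class_id, "background")) {
    return(withr::with_seed(seed, {
      pix <- 0.965 + stats::rnorm(ts * ts, 0, 0.012)
      matrix(pmin(1, pmax(0.92, pix)), ts, ts)
    }))
  }
  row <- match(class_id, params$textures$class)
  if (is.na(row)) stop(sprintf("unknown class_id '%s'", class_id))
  tx <- params$textures[row, ]
  noise <- params$texture_noise
  withr::with_seed(seed, {
    theta <- tx$orient + stats::rnorm(1, 0, 0.6 * noise)
    freq <- tx$freq * exp(stats::rnorm(1, 0, 0.8 * noise))
    phase <- stats::runif(1, 0, 2 * pi)
    amp <- tx$amplitude * stats::runif(1, 0.8, 1.2)
    base <- tx$base + stats::rnorm(1, 0, 0.02)
    u <- (seq_len(ts) - 1) / ts
    wave <- outer(u * sin(theta), u * cos(theta), `+`)
    pix <- base + amp * sin(2 * pi * freq * wave + phase) +
      stats::rnorm(ts * ts, 0, noise)
    matrix(clip01(pix), ts, ts)
  })
}

#' Dominant radial spatial frequency of a tile
#'
#' Locates the radius (in cycles per tile) with maximal total spectral power,
#' DC excluded. For a sinusoid grating this recovers its frequency; used to
#' verify that class textures occupy distinct spectral bands.
#'
#' @param tile square numeric matrix.
#' @return Peak radial frequency in cycles per tile edge.
#' @export
spectrum_peak_frequency <- function(tile) {
  stopifnot(is.matrix(tile), nrow(tile) == ncol(tile))
  ts <- nrow(tile)
  p <- Mod(stats::fft(tile))^2
  idx <- seq_len(ts) - 1
  f <- ifelse(idx > ts / 2, idx - ts, idx)
  r <- sqrt(outer(f^2, f^2, `+`))
  rad <- round(as.vector(r))
  keep <- rad >= 1 & rad <= ts / 2
  prof <- rowsum(as.vector(p)[keep], rad[keep])
  as.numeric(rownames(prof))[which.max(prof)]
}
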