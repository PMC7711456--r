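#' Soft histogram encoding of one slide
#'
#' The central aggregation shared by all representation routes: the slide
#' histogram entry for concept k is the average of the tiles' concept-k
#' probabilities, `h_k = (1/|X_i|) sum_x p(c_k | f(x))`, where `|X_i|` counts
#' the tiles that survived the tissue filter.
#'
#' @param tile_probs matrix of per-tile probability vectors over the
#'   vocabulary (one row per retained tile of the slide).
#' @return Named numeric histogram of length K (sums to 1 when the rows do).
#' @export
encode_soft <- function(tile_probs) {
  tile_probs <- as.matrix(tile_probs)
  if (nrow(tile_probs) < 1)
    stop("slide has no retained tiles to encode")
  colMeans(tile_probs)
}

#' Hard histogram encoding of one slide
#'
#' Counting form of the aggregation: `h_k = #{tiles assigned to k} / |X_i|`.
#' Identical to [encode_soft()] applied to one-hot assignment vectors.
#'
#' @param assignments integer codeblock indices (1-based), one per retained
#'   tile.
#' @param K vocabulary size.
#' @return Numeric histogram of length K.
#' @export
encode_hard <- function(assignments, K) {
  if (length(assignments) < 1)
    stop("slide has no retained tiles to encode")
  if (any(assignments < 1 | assignments > K))
    stop("assignments must lie in 1..K")
  tabulate(assignments, K) / length(assignments)
}

#' Encode every slide of a cohort from per-tile probabilities
#'
#' @param tile_probs matrix of per-tile probability vectors (all slides
#'   stacked).
#' @param slide_ids slide id per tile row.
#' @return Matrix `n_slides x K` (rows named by slide id, ordered by first
#'   appearance), each row the slide's soft histogram.
#' @export
slide_histograms <- function(tile_probs, slide_ids) {
  tile_probs <- as.matrix(tile_probs)
  stopifnot(nrow(tile_probs) == length(slide_ids))
  f <- factor(slide_ids, levels = unique(slide_ids))
  sums <- rowsum(tile_probs, f)
  sums / as.vector(table(f))
}

#' Encode every slide of a cohort from hard assignments
#'
#' @param assignments integer codeblock indices per tile.
#' @param slide_ids slide id per tile.
#' @param K vocabulary size.
#' @return Matrix `n_slides x K` of hard histograms.
#' @export
slide_histograms_hard <- function(assignments, slide_ids, K) {
  onehot <- diag(K)[assignments, , drop = FALSE]
  slide_histograms(onehot, slide_ids)
}
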