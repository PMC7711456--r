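#' Fit a k-means centroid codebook
#'
#' Learns the hard-assignment visual vocabulary by clustering tile embeddings
#' with k-means (Hartigan-Wong, seeded, multiple starts). Centroids are
#' sorted lexicographically so component order is reproducible.
#'
#' @param embeddings numeric matrix, one embedding per row.
#' @param K number of codeblocks (K <= n rows).
#' @param seed integer seed.
#' @param nstart,iter.max k-means controls.
#' @return A `centroid_codebook`: list with `centers` (K x E), `K`, `seed`.
#' @export
fit_kmeans_codebook <- function(embeddings, K, seed = 1L, nstart = 5L,
                                iter.max = 100L) {
  embeddings <- as.matrix(embeddings)
  if (nrow(embeddings) < K)
    stop("need at least K embeddings to fit a codebook")
  km <- withr::with_seed(seed,
    stats::kmeans(embeddings, centers = K, nstart = nstart,
                  iter.max = iter.max))
  centers <- km$centers
  ord <- do.call(order, as.data.frame(centers))
  structure(list(centers = unname(centers[ord, , drop = FALSE]),
                 K = as.integer(K), seed = as.integer(seed),
                 tot_withinss = km$tot.withinss),
            class = "centroid_codebook")
}

#' Hard-assign embeddings to the nearest codeblock
#'
#' Euclidean nearest centroid; ties resolve to the lowest index.
#'
#' @param codebook a `centroid_codebook`.
#' @param v embedding vector or matrix of embeddings (rows).
#' @return Integer codeblock indices (1-based).
#' @export
hard_assign <- function(codebook, v) {
  stopifnot(inherits(codebook, "centroid_codebook"))
  V <- if (is.matrix(v)) v else matrix(v, nrow = 1)
  if (ncol(V) != ncol(codebook$centers))
    stop("embedding length does not match the codebook")
  C <- codebook$centers
  d2 <- outer(rowSums(V^2), rep(1, nrow(C))) - 2 * V %*% t(C) +
    outer(rep(1, nrow(V)), rowSums(C^2))
  idx <- max.col(-d2, ties.method = "first")
  if (!is.matrix(v)) idx[1] else idx
}

#' Fit a Gaussian-mixture codebook
#'
#' Learns the soft-assignment vocabulary: a K-component Gaussian mixture with
#' diagonal covariances fitted by EM, initialized from a seeded k-means run
#' with the same seed (weights = cluster proportions, means = centroids,
#' variances = within-cluster per-dimension variance). Variances are floored
#' at `var_floor` for small-sample stability; the log-likelihood is
#' non-decreasing over iterations and recorded.
#'
#' @param embeddings numeric matrix, one embedding per row.
#' @param K number of mixture components (K <= n rows).
#' @param seed integer seed.
#' @param max_iter,tol EM controls (relative log-likelihood change).
#' @param var_floor lower bound on diagonal covariance entries.
#' @return A `gaussian_codebook`: list with `weights` (sum 1), `means`
#'   (K x E), `vars` (K x E, diagonal covariances), `loglik` trace.
#' @export
fit_gmm_codebook <- function(embeddings, K, seed = 1L, max_iter = 200L,
                             tol = 1e-8, var_floor = 1e-6) {
  X <- as.matrix(embeddings)
  n <- nrow(X); E <- ncol(X)
  if (n < K) stop("need at least K embeddings to fit a codebook")

  km <- fit_kmeans_codebook(X, K, seed = seed)
  assign0 <- hard_assign(km, X)
  means <- km$centers
  weights <- as.numeric(tabulate(assign0, K)) / n
  weights <- pmax(weights, 1e-10); weights <- weights / sum(weights)
  vars <- matrix(0, K, E)
  for (k in seq_len(K)) {
    rows <- X[assign0 == k, , drop = FALSE]
    vars[k, ] <- if (nrow(rows) > 1)
      apply(rows, 2, function(col) mean((col - mean(col))^2))
    else rep(0, E)
  }
  vars <- pmax(vars, var_floor)

  loglik <- numeric(0)
  prev <- -Inf
  for (it in seq_len(max_iter)) {
    lp <- gmm_log_joint(X, weights, means, vars)   # n x K: log pi_k + log N
    lse <- logsumexp_rows(lp)
    ll <- sum(lse)
    loglik <- c(loglik, ll)
    resp <- exp(lp - lse)
    nk <- colSums(resp)
    weights <- pmax(nk / n, 1e-10); weights <- weights / sum(weights)
    safe_nk <- pmax(nk, 1e-10)
    means <- crossprod(resp, X) / safe_nk
    vars <- pmax(crossprod(resp, X^2) / safe_nk - means^2, var_floor)
    if (is.finite(prev) && (ll - prev) < tol * (abs(prev) + 1)) break
    prev <- ll
  }

  structure(list(weights = weights, means = unname(means),
                 vars = unname(vars), K = as.integer(K), E = E,
                 loglik = loglik, seed = as.integer(seed),
                 var_floor = var_floor),
            class = "gaussian_codebook")
}

# log(pi_k) + log N(x | mu_k, diag(sigma2_k)) for all points x components
gmm_log_joint <- function(X, weights, means, vars) {
  n <- nrow(X); K <- nrow(means)
  lp <- matrix(0, n, K)
  for (k in seq_len(K)) {
    d <- sweep(X, 2, means[k, ])
    lp[, k] <- log(weights[k]) -
      0.5 * sum(log(2 * pi * vars[k, ])) -
      0.5 * rowSums(sweep(d^2, 2, vars[k, ], "/"))
  }
  lp
}

#' Posterior codeblock probabilities under a Gaussian codebook
#'
#' For embedding `v`, component `m` receives
#' `pi_m N(v | mu_m, Sigma_m) / sum_k pi_k N(v | mu_k, Sigma_k)`; computed in
#' log space for numerical stability. Rows sum to 1.
#'
#' @param codebook a `gaussian_codebook`.
#' @param v embedding vector or matrix of embeddings (rows).
#' @return Probability vector over K, or an `n x K` matrix.
#' @export
gmm_posterior <- function(codebook, v) {
  stopifnot(inherits(codebook, "gaussian_codebook"))
  V <- if (is.matrix(v)) v else matrix(v, nrow = 1)
  if (!all(is.finite(V))) stop("embeddings must be finite")
  if (ncol(V) != codebook$E)
    stop("embedding length does not match the codebook")
  lp <- gmm_log_joint(V, codebook$weights, codebook$means, codebook$vars)
  P <- exp(lp - logsumexp_rows(lp))
  if (!is.matrix(v)) P[1, ] else P
}

#' @export
print.gaussian_codebook <- function(x, ...) {
  cat(sprintf("Gaussian codebook: K = %d components over E = %d dims (final loglik %.2f)\n",
              x$K, x$E, x$loglik[length(x$loglik)]))
  invisible(x)
}

#' Sweep codebook sizes against a downstream evaluation
#'
#' For every K in `K_list`, fits a codebook on the embeddings and calls
#' `eval_fn(codebook, K)`, which must return a named numeric vector holding
#' at least `weighted_auc`, `ci_lo`, `ci_hi` (e.g. the weighted AUC of a
#' cross-validated fusion classifier over the re-encoded slides). A K larger
#' than the number of embeddings is reported as a failed row, not an error.
#'
#' @param embeddings numeric matrix of tile embeddings.
#' @param K_list codebook sizes; the default grid spans 3 to 300.
#' @param eval_fn function(codebook, K) -> named numeric.
#' @param kind `"gmm"` or `"km"`.
#' @param seed fitting seed.
#' @return data.frame sorted by K with the evaluation columns and an `error`
#'   column (NA on success).
#' @export
sweep_codebook_sizes <- function(embeddings, K_list = c(3, 5, 10, 20, 50, 100, 150, 200, 300),
                                 eval_fn, kind = c("gmm", "km"), seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(length(K_list) >= 1)
  K_list <- sort(unique(as.integer(K_list)))
  rows <- lapply(K_list, function(K) {
    res <- tryCatch({
      cb <- if (kind == "gmm") fit_gmm_codebook(embeddings, K, seed = seed)
            else fit_kmeans_codebook(embeddings, K, seed = seed)
      as.list(eval_fn(cb, K))
    }, error = function(e) list(error = conditionMessage(e)))
    err <- res$error %||% NA_character_
    data.frame(K = K,
               weighted_auc = res$weighted_auc %||% NA_real_,
               ci_lo = res$ci_lo %||% NA_real_,
               ci_hi = res$ci_hi %||% NA_real_,
               error = err, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Serialize a codebook to a portable JSON container
#'
#' Writes the codebook kind, dimensions, seed and parameter arrays to a
#' single JSON file that round-trips exactly at full double precision.
#'
#' @param codebook a `centroid_codebook` or `gaussian_codebook`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_codebook <- function(codebook, path) {
  obj <- if (inherits(codebook, "centroid_codebook")) {
    list(kind = "centroid", K = codebook$K, E = ncol(codebook$centers),
         seed = codebook$seed, centers = codebook$centers)
  } else if (inherits(codebook, "gaussian_codebook")) {
    list(kind = "gaussian", K = codebook$K, E = codebook$E,
         seed = codebook$seed, var_floor = codebook$var_floor,
         weights = codebook$weights, means = codebook$means,
         vars = codebook$vars)
  } else stop("not a codebook")
  # 17 significant digits: exact double-precision round-trip
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' Read a codebook written by [write_codebook()]
#'
#' @param path JSON file path.
#' @return The codebook object.
#' @export
read_codebook <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(obj$kind, "centroid")) {
    structure(list(centers = matrix(obj$centers, obj$K, obj$E),
                   K = as.integer(obj$K), seed = as.integer(obj$seed)),
              class = "centroid_codebook")
  } else if (identical(obj$kind, "gaussian")) {
    structure(list(weights = obj$weights,
                   means = matrix(obj$means, obj$K, obj$E),
                   vars = matrix(obj$vars, obj$K, obj$E),
                   K = as.integer(obj$K), E = as.integer(obj$E),
                   loglik = numeric(0), seed = as.integer(obj$seed),
                   var_floor = obj$var_floor),
              class = "gaussian_codebook")
  } else stop("unrecognized codebook container")
}
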