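# Shared fixtures, memoised so expensive pipeline stages (cohort rendering,
# autoencoder, GMM codebook) are built once per test run and reused across
# files. All seeds are fixed study conditions, not per-test knobs.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# the full-size study cohort (30 patients) used by the acceptance suite
study_params <- function() cohort_params(seed = 101L)

study_cohort <- function() memo("study_cohort", generate_cohort(study_params()))

study_tiles <- function() memo("study_tiles", cohort_tiles(study_cohort()))

study_desc <- function() memo("study_desc", tile_descriptors(study_tiles()$tiles))

study_autoencoder <- function() memo("study_ae",
  train_autoencoder(study_tiles()$tiles, 32, autoencoder_config(seed = 202L)))

study_embeddings <- function() memo("study_emb",
  embed_tiles(study_autoencoder(), study_desc()))

study_gmm <- function() memo("study_gmm",
  fit_gmm_codebook(study_embeddings(), 150, seed = 303L))

study_posteriors <- function() memo("study_post",
  gmm_posterior(study_gmm(), study_embeddings()))

study_histograms <- function() memo("study_hist",
  slide_histograms(study_posteriors(), study_tiles()$index$slide_id))

study_meta <- function() {
  idx <- study_tiles()$index
  idx[match(unique(idx$slide_id), idx$slide_id),
      c("slide_id", "patient_id", "label")]
}

# a small cohort for cheap unit tests
small_cohort <- function() memo("small_cohort",
  generate_cohort(cohort_params(n_patients = 6, seed = 55L)))

small_tiles <- function() memo("small_tiles", cohort_tiles(small_cohort()))

# well-separated Gaussian blob fixture for codebook tests: 3 components in
# E dimensions with unit spacing `sep` between neighbouring means
blob_data <- function(n = 600, E = 8, sep = 6, seed = 77,
                      props = c(0.5, 0.3, 0.2)) {
  withr::with_seed(seed, {
    sizes <- round(props * n)
    sizes[1] <- n - sum(sizes[-1])
    means <- matrix(0, 3, E)
    means[2, 1] <- sep
    means[3, 2] <- sep
    X <- do.call(rbind, lapply(1:3, function(k)
      matrix(stats::rnorm(sizes[k] * E, 0, 0.5), sizes[k], E) +
        matrix(means[k, ], sizes[k], E, byrow = TRUE)))
    list(X = X, means = means, sizes = sizes, sep = sep,
         labels = rep(1:3, sizes))
  })
}

# random Gaussian codebook for posterior-oracle checks
random_codebook <- function(K, E, seed) {
  withr::with_seed(seed, {
    structure(list(
      weights = {
        w <- stats::runif(K, 0.2, 1); w / sum(w)
      },
      means = matrix(stats::rnorm(K * E), K, E),
      vars = matrix(stats::runif(K * E, 0.05, 2), K, E),
      K = as.integer(K), E = as.integer(E),
      loglik = numeric(0), seed = seed, var_floor = 1e-6
    ), class = "gaussian_codebook")
  })
}

# naive density-ratio oracle for the mixture posterior (no log-space tricks)
naive_posterior <- function(cb, v) {
  dens <- vapply(seq_len(cb$K), function(k)
    cb$weights[k] * prod(stats::dnorm(v, cb$means[k, ], sqrt(cb$vars[k, ]))),
    numeric(1))
  dens / sum(dens)
}
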