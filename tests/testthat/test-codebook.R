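test_that("k-means codebook handles closed-form and recovery cases", {
  bd <- blob_data()
  cb1 <- fit_kmeans_codebook(bd$X, 1, seed = 3)
  expect_equal(as.vector(cb1$centers), colMeans(bd$X), tolerance = 1e-10)

  cb3 <- fit_kmeans_codebook(bd$X, 3, seed = 3)
  # each centroid lands within 0.1 * blob spacing of a distinct blob mean
  d <- as.matrix(stats::dist(rbind(cb3$centers, bd$means)))[1:3, 4:6]
  hit <- apply(d, 1, which.min)
  expect_equal(sort(unname(hit)), 1:3)
  expect_true(all(apply(d, 1, min) < 0.1 * bd$sep))

  # duplicating every point leaves the optimum unchanged
  cbd <- fit_kmeans_codebook(rbind(bd$X, bd$X), 3, seed = 3)
  expect_equal(cbd$centers, cb3$centers, tolerance = 1e-6)

  expect_error(fit_kmeans_codebook(bd$X[1:2, ], 3), "at least K")
})

test_that("hard assignment is exact, tie-breaks low, and matches brute force", {
  cb <- structure(list(centers = matrix(c(0, 0, 1, 0, 0, 1), 3, 2,
                                        byrow = TRUE),
                       K = 3L, seed = 1L),
                  class = "centroid_codebook")
  expect_equal(hard_assign(cb, c(1, 0)), 2)
  expect_equal(hard_assign(cb, c(0.5, 0.5)), 1)  # equidistant from all three

  withr::with_seed(8, V <- matrix(stats::rnorm(400), 200, 2))
  fast <- hard_assign(cb, V)
  brute <- apply(V, 1, function(v)
    which.min(colSums((t(cb$centers) - v)^2)))
  expect_equal(fast, brute)
})

test_that("GMM codebook: closed form at K = 1, blob recovery, monotone log-likelihood", {
  bd <- blob_data()
  g1 <- fit_gmm_codebook(bd$X, 1, seed = 5)
  expect_equal(g1$weights, 1)
  expect_equal(as.vector(g1$means), colMeans(bd$X), tolerance = 1e-8)
  expect_equal(as.vector(g1$vars),
               apply(bd$X, 2, function(v) mean((v - mean(v))^2)),
               tolerance = 1e-8)

  g3 <- fit_gmm_codebook(bd$X, 3, seed = 5)
  expect_equal(sum(g3$weights), 1, tolerance = 1e-9)
  d <- as.matrix(stats::dist(rbind(g3$means, bd$means)))[1:3, 4:6]
  ord <- apply(d, 1, which.min)
  expect_equal(sort(unname(ord)), 1:3)
  expect_true(all(apply(d, 1, min) < 0.1 * bd$sep))
  expect_true(all(abs(g3$weights - (bd$sizes / sum(bd$sizes))[ord]) < 0.05))
  expect_true(all(diff(g3$loglik) > -1e-6))

  # property: monotone likelihood on unstructured data too
  withr::with_seed(19, Xr <- matrix(stats::rnorm(600), 120, 5))
  gr <- fit_gmm_codebook(Xr, 7, seed = 2)
  expect_true(all(diff(gr$loglik) > -1e-6))
  expect_true(all(gr$vars >= 1e-6))
})

test_that("GMM recovery agrees with an independent mixture implementation", {
  withr::local_package("mclust")   # Mclust needs its namespace attached
  bd <- blob_data()
  ours <- fit_gmm_codebook(bd$X, 3, seed = 5)
  ref <- mclust::Mclust(bd$X, G = 3, modelNames = "VVI", verbose = FALSE)
  ref_means <- t(ref$parameters$mean)
  d <- as.matrix(stats::dist(rbind(ours$means, ref_means)))[1:3, 4:6]
  expect_true(all(apply(d, 1, min) < 0.05))
})

test_that("mixture posterior matches the naive density-ratio oracle", {
  withr::with_seed(41, seeds <- sample.int(1e6, 200))
  worst <- 0
  for (s in seeds[1:200]) {
    cb <- random_codebook(K = 5, E = 4, seed = s)
    v <- withr::with_seed(s + 1, stats::rnorm(4))
    p <- gmm_posterior(cb, v)
    q <- naive_posterior(cb, v)
    worst <- max(worst, max(abs(p - q)))
    expect_equal(sum(p), 1, tolerance = 1e-9)
  }
  expect_lt(worst, 1e-9)
})

test_that("posterior symmetry and sharp-covariance limits hold", {
  cb <- structure(list(
    weights = rep(1 / 3, 3),
    means = matrix(c(1, 0, 0, 0, 1, 0, 0, 0, 1), 3, 3, byrow = TRUE),
    vars = matrix(0.5, 3, 3), K = 3L, E = 3L,
    loglik = numeric(0), seed = 1L, var_floor = 1e-6),
    class = "gaussian_codebook")
  # the centroid of the simplex is equidistant from all means
  p <- gmm_posterior(cb, rep(1 / 3, 3))
  expect_equal(p, rep(1 / 3, 3), tolerance = 1e-12)

  cb$vars <- matrix(1e-6, 3, 3)
  p2 <- gmm_posterior(cb, cb$means[2, ])
  expect_gt(p2[2], 1 - 1e-9)
  expect_error(gmm_posterior(cb, c(Inf, 0, 0)), "finite")
  expect_error(gmm_posterior(cb, c(0, 0)), "length")
})

test_that("codebook size sweep reports per-K evaluations and survives oversized K", {
  bd <- blob_data(n = 60)
  fake_eval <- function(cb, K)
    c(weighted_auc = 1 - 1 / K, ci_lo = 0.5, ci_hi = 1)
  tab <- sweep_codebook_sizes(bd$X, c(100, 2, 5), fake_eval, kind = "km",
                              seed = 9)
  expect_equal(tab$K, c(2, 5, 100))
  expect_equal(tab$weighted_auc[1:2], c(0.5, 0.8))
  expect_true(is.na(tab$weighted_auc[3]))   # K > n reported, not fatal
  expect_false(is.na(tab$error[3]))

  single <- sweep_codebook_sizes(bd$X, 4, fake_eval, kind = "gmm", seed = 9)
  expect_equal(nrow(single), 1)
})

test_that("codebooks round-trip through the JSON container at full precision", {
  bd <- blob_data(n = 80, E = 3)
  km <- fit_kmeans_codebook(bd$X, 4, seed = 3)
  g <- fit_gmm_codebook(bd$X, 4, seed = 3)
  d <- withr::local_tempdir()
  p1 <- write_codebook(km, file.path(d, "km.json"))
  p2 <- write_codebook(g, file.path(d, "gmm.json"))
  km2 <- read_codebook(p1)
  g2 <- read_codebook(p2)
  expect_identical(km2$centers, km$centers)
  expect_identical(g2$means, g$means)
  expect_identical(g2$vars, g$vars)
  expect_identical(g2$weights, g$weights)
  withr::with_seed(5, v <- stats::rnorm(3))
  expect_identical(gmm_posterior(g2, v), gmm_posterior(g, v))
  expect_identical(hard_assign(km2, v), hard_assign(km, v))
})
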