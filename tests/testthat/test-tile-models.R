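# held-out split over the small cohort's tissue tiles, truth-labeled
tile_split <- function() {
  memo("tile_split", {
    ct <- small_tiles()
    desc <- tile_descriptors(ct$tiles)
    keep <- which(ct$index$truth != "background")
    withr::with_seed(11, tr <- sample(keep, floor(0.7 * length(keep))))
    te <- setdiff(keep, tr)
    list(desc = desc, truth = ct$index$truth, tr = tr, te = te)
  })
}

test_that("tile classifier reaches high held-out accuracy on truth-labeled textures", {
  sp <- tile_split()
  clf <- train_tile_classifier(sp$desc[sp$tr, ], sp$truth[sp$tr],
                               classifier_config(seed = 21))
  P <- predict_concept_probabilities(clf, sp$desc[sp$te, ])
  acc <- mean(colnames(P)[max.col(P)] == sp$truth[sp$te])
  expect_gte(acc, 0.95)
  # probability contract
  expect_true(all(P >= 0))
  expect_equal(rowSums(P), rep(1, nrow(P)), tolerance = 1e-6)
})

test_that("label permutation collapses held-out accuracy to chance", {
  # class-balanced split so chance level is exactly 1/K
  sp <- tile_split()
  cls <- sort(unique(sp$truth[sp$tr]))
  n_tr <- min(table(sp$truth[sp$tr])[cls])
  n_te <- min(table(sp$truth[sp$te])[cls])
  withr::with_seed(31, {
    tr <- unlist(lapply(cls, function(k)
      sample(sp$tr[sp$truth[sp$tr] == k], n_tr)))
    te <- unlist(lapply(cls, function(k)
      sample(sp$te[sp$truth[sp$te] == k], n_te)))
    perm <- sample(sp$truth[tr])
  })
  clf <- train_tile_classifier(sp$desc[tr, ], perm,
                               classifier_config(seed = 21))
  P <- predict_concept_probabilities(clf, sp$desc[te, ])
  acc <- mean(colnames(P)[max.col(P)] == sp$truth[te])
  expect_lt(abs(acc - 1 / 3), 0.1)
})

test_that("classifier training is deterministic, evaluation-mode stable, and validates input", {
  sp <- tile_split()
  sub <- sp$tr[1:300]
  cfg <- classifier_config(seed = 5, epochs = 15)
  c1 <- train_tile_classifier(sp$desc[sub, ], sp$truth[sub], cfg)
  c2 <- train_tile_classifier(sp$desc[sub, ], sp$truth[sub], cfg)
  expect_identical(c1$fit, c2$fit)
  expect_equal(cfg$dropout, 0.5)

  one <- small_tiles()$tiles[[1]]
  p1 <- predict_concept_probabilities(c1, one)
  p2 <- predict_concept_probabilities(c1, one)
  expect_identical(p1, p2)
  expect_equal(ncol(p1), 3)

  expect_error(train_tile_classifier(sp$desc[sub, ],
                                     rep("a", length(sub))),
               "two classes")
  # a pixel-trained model knows its tile shape and rejects mismatches
  ct <- small_tiles()
  keep <- which(ct$index$truth != "background")[1:200]
  cpx <- train_tile_classifier(ct$tiles[keep], ct$index$truth[keep],
                               classifier_config(seed = 5, epochs = 5))
  expect_error(predict_concept_probabilities(cpx, matrix(0.5, 16, 16)),
               "shape")
})

test_that("trained lesion-texture tiles are recognized as the diseased class", {
  sp <- tile_split()
  clf <- train_tile_classifier(sp$desc[sp$tr, ], sp$truth[sp$tr],
                               classifier_config(seed = 21))
  p <- cohort_params(seed = 91)
  lesions <- lapply(1:100, function(i)
    render_tile_texture("dysplastic", p, 7000 + i))
  P <- predict_concept_probabilities(clf, lesions)
  expect_gte(mean(colnames(P)[max.col(P)] == "dysplastic"), 0.9)
})

test_that("autoencoder beats the constant mean-image predictor and separates classes", {
  ct <- small_tiles()
  ae <- train_autoencoder(ct$tiles, 32, autoencoder_config(seed = 7))
  n <- min(400, length(ct$tiles))
  rec <- reconstruct_tiles(ae, ct$tiles[seq_len(n)])
  mean_img <- Reduce(`+`, ct$tiles[seq_len(n)]) / n
  err_rec <- mean(vapply(seq_len(n), function(i)
    mean((rec[[i]] - ct$tiles[[i]])^2), numeric(1)))
  err_const <- mean(vapply(seq_len(n), function(i)
    mean((mean_img - ct$tiles[[i]])^2), numeric(1)))
  expect_lt(err_rec, err_const)

  emb <- embed_tiles(ae, ct$tiles)
  expect_equal(ncol(emb), 32)
  expect_true(all(is.finite(emb)))

  tc <- ct$index$truth
  cls <- setdiff(unique(tc), "background")
  cents <- sapply(cls, function(k) colMeans(emb[tc == k, , drop = FALSE]))
  within <- mean(vapply(cls, function(k) {
    d <- sweep(emb[tc == k, , drop = FALSE], 2, cents[, k])
    mean(sqrt(rowSums(d^2)))
  }, numeric(1)))
  between <- mean(stats::dist(t(cents)))
  expect_gt(between, within)
})

test_that("autoencoder embedding is deterministic and distinguishes extreme tiles", {
  ct <- small_tiles()
  cfg <- autoencoder_config(seed = 7, epochs = 20)
  a1 <- train_autoencoder(ct$tiles[1:200], 16, cfg)
  a2 <- train_autoencoder(ct$tiles[1:200], 16, cfg)
  expect_identical(a1$fit, a2$fit)

  ts <- nrow(ct$tiles[[1]])
  z0 <- embed_tiles(a1, matrix(0, ts, ts))
  z1 <- embed_tiles(a1, matrix(1, ts, ts))
  expect_identical(embed_tiles(a1, matrix(0, ts, ts)), z0)
  expect_gt(sum((z0 - z1)^2), 0)
  expect_equal(length(z0), 16)

  expect_error(train_autoencoder(ct$tiles[1:50], ts * ts),
               "smaller than the tile pixel count")
})
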