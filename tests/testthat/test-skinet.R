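trained_tiny_grid <- function(ds, seed = 4, ...) {
  cfg <- tiny_som_config(seed = seed, ...)
  accumulate_hits(som_train(init_grid(cfg, ds), ds, cfg), ds)
}

test_that("hit accumulation conserves counts and matches brute-force BMUs", {
  ds <- tiny_dataset()
  g <- trained_tiny_grid(ds)
  expect_equal(sum(g$class_hits), n_spectra(ds))

  one <- subset_dataset(ds, 5)
  g1 <- accumulate_hits(g, one)
  expect_equal(sum(g1$class_hits), 1)
  b <- find_bmu(g, one$intensities[1, ])
  expect_equal(unname(g1$class_hits[b, as.character(one$meta$group[1])]), 1)

  # brute-force reconstruction of the full hit table
  hits <- matrix(0L, nrow(g$weights), length(ds$classes),
                 dimnames = list(NULL, ds$classes))
  for (i in seq_len(n_spectra(ds))) {
    b <- brute_bmu(g, ds$intensities[i, ])
    k <- as.character(ds$meta$group[i])
    hits[b, k] <- hits[b, k] + 1L
  }
  expect_equal(unname(g$class_hits), unname(hits))
})

test_that("SOMDI vanishes for indistinguishable classes", {
  ds <- tiny_dataset()
  g <- trained_tiny_grid(ds)
  # identical hit distributions across two pseudo-classes
  g0 <- g
  h <- rowSums(g$class_hits)
  g0$class_hits <- cbind(A = h, B = h)
  g0$classes <- c("A", "B")
  d0 <- somdi(g0)
  expect_true(all(abs(d0$discriminants) < 1e-9))

  # permutation null: one class split at random into two pseudo-classes
  sham <- subset_dataset(ds, which(ds$meta$group == "sham"))
  set.seed(41)
  band_idx <- vapply(c(850, 1098, 1337, 1003, 1266, 1660),
                     function(b) which.min(abs(ds$axis - b)), integer(1))
  null_disc <- replicate(20, {
    pseudo <- sham
    lab <- sample(rep(c("p1", "p2"), length.out = n_spectra(sham)))
    pseudo$meta$group <- factor(lab, levels = c("p1", "p2"))
    pseudo$classes <- c("p1", "p2")
    gp <- accumulate_hits(g, pseudo)
    somdi(gp)$discriminants[band_idx, "p1"]
  })
  m <- rowMeans(null_disc)
  se <- apply(null_disc, 1, sd) / sqrt(ncol(null_disc))
  expect_true(all(abs(m) <= 3 * se + 1e-12))

  g_empty <- g
  g_empty$class_hits[, "sTBI"] <- 0L
  expect_error(somdi(g_empty), "sTBI")
})

test_that("classification reads class hits at the BMU with documented tie rules", {
  ds <- tiny_dataset()
  g <- trained_tiny_grid(ds)

  gd <- g
  gd$class_hits[] <- 0L
  b <- find_bmu(g, g$weights[9, ])
  gd$class_hits[b, ] <- c(10L, 0L, 0L)
  expect_equal(as.character(som_classify(gd, g$weights[9, ])), ds$classes[1])
  gd$class_hits[b, ] <- c(5L, 5L, 0L)
  expect_equal(as.character(som_classify(gd, g$weights[9, ])), ds$classes[1])

  # brute-force oracle: scan + argmax + nearest-hit-neuron fallback
  set.seed(19)
  X <- matrix(runif(200 * length(ds$axis)), 200)
  pred <- som_classify(g, X)
  hit_any <- rowSums(g$class_hits) > 0
  for (i in 1:200) {
    b <- brute_bmu(g, X[i, ])
    if (!hit_any[b]) {
      d2 <- (g$hex$x - g$hex$x[b])^2 + (g$hex$y - g$hex$y[b])^2
      d2[!hit_any] <- Inf
      b <- which.min(d2)
    }
    expect_equal(as.character(pred[i]),
                 ds$classes[which.max(g$class_hits[b, ])])
  }

  # scale invariance of predictions
  expect_equal(som_classify(g, 7 * X[1, ]), som_classify(g, X[1, ]))

  g_none <- g
  g_none$class_hits[] <- 0L
  expect_error(som_classify(g_none, X[1, ]), "no neuron")
})

test_that("cross-validation bookkeeping is stratified and exhaustive", {
  axis <- 1:30
  set.seed(6)
  X <- rbind(matrix(runif(120, 0.9, 1.1) * rep(c(1, 0, 0), each = 10), 4, 30, byrow = TRUE),
             matrix(runif(120, 0.9, 1.1) * rep(c(0, 1, 0), each = 10), 4, 30, byrow = TRUE))
  ds <- raman_dataset(axis, X, data.frame(group = rep(c("A", "B"), each = 4)))
  cfg <- tiny_som_config(rows = 2, cols = 2, n_epochs = 2, seed = 1)
  cv <- cross_validate(ds, cfg, k = 2)
  expect_length(cv$accuracy, 2)
  expect_false(anyNA(cv$predictions)) # each spectrum predicted exactly once
  expect_error(cross_validate(ds, cfg, k = 5), "fewer")
})

test_that("cross-validation is near-perfect on trivially separable data", {
  cfg <- tiny_config(grid_side = 4, mice_per_group = 2, noise_sigma = 0,
                     baseline_scale = 0, cosmic_ray_rate = 0)
  # effects scaled x10: disjoint spectral signatures per group
  cfg$effects$mTBI$band_multipliers[] <- c(4, 4, 4, 0.1, 0.1, 0.1)
  cfg$effects$sTBI$band_multipliers[] <- c(0.1, 0.1, 0.1, 4, 4, 4)
  cfg$effects <- lapply(cfg$effects, function(e) { e$heterogeneity <- 0.01; e })
  ds <- preprocess_maps(generate_maps(cfg), preprocess_config(),
                        classes = names(cfg$effects))
  cv <- cross_validate(ds, tiny_som_config(rows = 6, cols = 6, seed = 2), k = 3)
  expect_gte(cv$mean, 0.99)
  # fold sizes differ by at most one within each group
  folds <- skinet:::stratified_folds(ds$meta$group, 3, 2)
  for (gp in levels(ds$meta$group)) {
    sizes <- table(folds[ds$meta$group == gp])
    expect_lte(max(sizes) - min(sizes), 1)
  }
})

test_that("repeated-initialization evaluation yields row-stochastic confusions", {
  ds <- tiny_dataset(grid_side = 5)
  sp <- split_dataset(ds, preprocess_config(split_fraction = 0.2))
  cfg <- tiny_som_config(n_epochs = 2, seed = 7)
  cm <- som_evaluate(sp$train, sp$test, cfg, repeats = 2)
  expect_equal(unname(rowSums(cm$mean)), rep(100, 3), tolerance = 0.1)
  expect_true(all(cm$mean >= 0))

  cm1 <- som_evaluate(sp$train, sp$test, cfg, repeats = 1)
  cm2 <- som_evaluate(sp$train, sp$test, cfg, repeats = 1)
  expect_identical(cm1$mean, cm2$mean)

  no_stbi <- subset_dataset(sp$test, which(sp$test$meta$group != "sTBI"))
  expect_error(som_evaluate(sp$train, no_stbi, cfg), "absent")
})

test_that("training accuracy is no worse than held-out accuracy on average", {
  acc_train <- numeric(3); acc_test <- numeric(3)
  ds <- tiny_dataset(grid_side = 5)
  sp <- split_dataset(ds, preprocess_config())
  for (s in 1:3) {
    cfg <- tiny_som_config(rows = 6, cols = 6, n_epochs = 3, seed = 30 + s)
    g <- accumulate_hits(som_train(init_grid(cfg, sp$train), sp$train, cfg),
                         sp$train)
    acc_train[s] <- mean(som_classify(g, sp$train$intensities) ==
                           sp$train$meta$group)
    acc_test[s] <- mean(som_classify(g, sp$test$intensities) ==
                          sp$test$meta$group)
  }
  expect_gte(mean(acc_train), mean(acc_test) - 0.02)
})
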