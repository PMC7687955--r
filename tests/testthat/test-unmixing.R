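test_that("the design matrix resamples every component onto the fitting axis", {
  lib <- synthetic_component_library()
  D <- build_design(lib)
  expect_equal(dim(D), c(515, 4))
  expect_equal(attr(D, "axis"), seq(1200, 1714, by = 1))
  # values at shared axis points equal the originals
  shared <- match(seq(1200, 1714, by = 1), lib$axis)
  expect_equal(unname(D[, "cardiolipin"]),
               unname(lib$components[shared, "cardiolipin"]))

  on_axis <- component_library(unmixing_axis(),
                               cbind(a = rep(1, 515), b = seq_len(515)))
  D2 <- build_design(on_axis)
  expect_equal(unname(D2[, "b"]), as.numeric(seq_len(515)))

  narrow <- component_library(seq(1300, 1714, by = 1),
                              cbind(short = rep(1, 415)))
  expect_error(build_design(narrow), "cover")
})

test_that("NNLS recovers exact members and constructed mixtures", {
  lib <- synthetic_component_library()
  D <- build_design(lib)
  fit <- nnls_fit(D[, 2], D)
  expect_equal(unname(fit$coefficients), c(0, 1, 0, 0), tolerance = 1e-8)

  y <- 0.3 * D[, 1] + 0.7 * D[, 2]
  fit2 <- nnls_fit(y, D)
  expect_equal(unname(fit2$coefficients[1:2]), c(0.3, 0.7), tolerance = 1e-6)
  expect_equal(unname(fit2$coefficients[3:4]), c(0, 0), tolerance = 1e-6)
  # independent oracle: projected gradient run to convergence
  expect_equal(unname(fit2$coefficients), pg_nnls(D, y), tolerance = 1e-5)

  neg <- -D[, 3]
  fit3 <- nnls_fit(neg, D)
  expect_equal(unname(fit3$coefficients), rep(0, 4))
  expect_equal(fit3$residual, sqrt(sum(neg^2)))

  expect_error(nnls_fit(c(NA, D[-1, 1]), D), "non-finite")
})

test_that("NNLS satisfies the KKT conditions and is scale-equivariant", {
  set.seed(14)
  for (i in 1:25) {
    D <- matrix(runif(60 * 4), 60)
    y <- rnorm(60)
    cf <- nnls_fit(y, `attr<-`(D, "axis", 1:60))$coefficients
    grad <- crossprod(D, D %*% cf - y)
    expect_true(all(abs(grad[cf > 0]) < 1e-8))
    expect_true(all(grad[cf == 0] >= -1e-8))
  }
  lib <- synthetic_component_library()
  D <- build_design(lib)
  y <- 0.4 * D[, 1] + 1.1 * D[, 4]
  a <- nnls_fit(y, D)$coefficients
  b <- nnls_fit(5 * y, D)$coefficients
  expect_equal(b, 5 * a, tolerance = 1e-8)
})

test_that("per-sample unmixing tabulates one row per brain sample", {
  lib <- synthetic_component_library()
  D <- build_design(lib)
  set.seed(15)
  mix <- matrix(runif(18 * 4, 0, 2), 18)
  avg <- raman_dataset(unmixing_axis(), mix %*% t(D),
                       data.frame(group = rep(c("sham", "mTBI", "sTBI"), each = 6),
                                  mouse = paste0("m", 1:18)))
  res <- fit_dataset(avg, lib)
  expect_equal(nrow(res), 18)
  expect_true(all(as.matrix(res[, lib$names]) >= 0))
  expect_equal(as.matrix(res[, lib$names]), mix, tolerance = 1e-6,
               ignore_attr = TRUE)
  # identical spectra yield identical coefficients
  same <- raman_dataset(unmixing_axis(), rbind(mix[1, ] %*% t(D), mix[1, ] %*% t(D)),
                        data.frame(group = c("a", "b"), mouse = c("m1", "m2")))
  r2 <- fit_dataset(same, lib)
  expect_equal(unlist(r2[1, lib$names]), unlist(r2[2, lib$names]))
})

test_that("noisy non-negative mixtures are recovered within 5% relative RMSE", {
  lib <- synthetic_component_library()
  D <- build_design(lib)[, 1:3]
  attr(D, "axis") <- unmixing_axis()
  set.seed(16)
  rel_err <- replicate(100, {
    truth <- runif(3, 0.5, 2)
    y <- D %*% truth
    y <- y + rnorm(length(y), sd = 0.01 * mean(y))
    got <- nnls_fit(as.numeric(y), D)$coefficients
    sqrt(mean((got - truth)^2)) / sqrt(mean(truth^2))
  })
  expect_lt(mean(rel_err), 0.05)
})

test_that("group comparison reproduces the textbook one-way ANOVA", {
  res <- data.frame(group = rep(c("sham", "mTBI", "sTBI"), each = 6))
  set.seed(17)
  res$cardiolipin <- rnorm(18, mean = rep(c(1.0, 0.8, 0.7), each = 6), sd = 0.1)
  cmp <- compare_groups(res, "cardiolipin")
  # hand-computed between/within mean-square ratio on the realized sample
  x <- res$cardiolipin; g <- factor(res$group)
  mg <- tapply(x, g, mean)
  ssb <- sum(6 * (mg - mean(x))^2)
  ssw <- sum((x - mg[g])^2)
  f_hand <- (ssb / 2) / (ssw / 15)
  expect_equal(cmp$f, f_hand, tolerance = 1e-10)
  expect_equal(cmp$p, stats::pf(f_hand, 2, 15, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(cmp$pairwise$group, c("mTBI", "sTBI"))
  expect_true(all(cmp$pairwise$p_holm >= cmp$pairwise$p_raw))

  # p-value invariant to common rescaling of all coefficients
  res2 <- res
  res2$cardiolipin <- res$cardiolipin * 100
  expect_equal(compare_groups(res2, "cardiolipin")$p, cmp$p, tolerance = 1e-9)
})

test_that("degenerate and extreme group structures are handled explicitly", {
  same <- data.frame(group = rep(c("a", "b", "c"), each = 3),
                     comp = rep(2, 9))
  expect_warning(cmp <- compare_groups(same, "comp"), "no between-group")
  expect_equal(cmp$f, 0)
  expect_equal(cmp$p, 1)

  shifted <- data.frame(group = rep(c("a", "b", "c"), each = 3),
                        comp = rep(c(0, 0, 10), each = 3) + rnorm(9, sd = 1e-6))
  expect_lt(compare_groups(shifted, "comp")$p, 1e-6)

  expect_error(compare_groups(same, "nope"), "no such component")
  expect_error(compare_groups(same[1:3, ], "comp"), "2 groups")
})
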