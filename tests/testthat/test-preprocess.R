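test_that("cosmic-ray removal repairs injected spikes and only those", {
  cfg <- tiny_config(grid_side = 6, cosmic_ray_rate = 4, seed = 13)
  m <- generate_map("sham", config = cfg, seed = 13)
  injected <- m$provenance$spikes
  expect_gt(nrow(injected), 0)
  out <- remove_cosmic_rays(m)
  reps <- out$provenance$repairs
  # every injected (position, channel) is repaired
  inj_key <- unique(paste(injected$index, injected$channel))
  rep_key <- paste(reps$index, reps$channel)
  expect_true(all(inj_key %in% rep_key))
  # post-repair residual at spiked channels is at noise level
  for (k in seq_len(nrow(injected))) {
    i <- injected$index[k]; ch <- injected$channel[k]
    others <- setdiff(seq_len(nrow(m$intensities)), i)
    ref <- median(m$intensities[others, ch])
    expect_lt(abs(out$intensities[i, ch] - ref), 3 * (cfg$noise_sigma + cfg$baseline_scale))
  }
})

test_that("spike-free maps need no repair at the default threshold", {
  m <- generate_map("sham", config = tiny_config(grid_side = 6,
                                                 cosmic_ray_rate = 0),
                    seed = 17)
  out <- remove_cosmic_rays(m)
  expect_equal(nrow(out$provenance$repairs), 0)
  expect_equal(out$intensities, m$intensities)
  expect_error(remove_cosmic_rays(
    generate_map("sham", config = tiny_config(grid_side = 1,
                                              cosmic_ray_rate = 0), seed = 1)),
    "at least 2")
})

test_that("repairs equal a brute-force scan applying the same rule", {
  cfg <- tiny_config(grid_side = 5, cosmic_ray_rate = 6, seed = 23)
  m <- generate_map("mTBI", config = cfg, seed = 23)
  k_th <- 8
  out <- remove_cosmic_rays(m, preprocess_config(cosmic_k = k_th))
  # independent scan: for each spectrum, median of 4-connected neighbours
  # per channel, MAD threshold on the residuals
  step <- m$step
  found <- list()
  for (i in seq_len(nrow(m$intensities))) {
    px <- m$positions$x[i]; py <- m$positions$y[i]
    nb <- which((abs(m$positions$x - px - step) < 1e-9 & abs(m$positions$y - py) < 1e-9) |
                (abs(m$positions$x - px + step) < 1e-9 & abs(m$positions$y - py) < 1e-9) |
                (abs(m$positions$x - px) < 1e-9 & abs(m$positions$y - py - step) < 1e-9) |
                (abs(m$positions$x - px) < 1e-9 & abs(m$positions$y - py + step) < 1e-9))
    ref <- apply(m$intensities[nb, , drop = FALSE], 2, median)
    resid <- m$intensities[i, ] - ref
    hits <- which(resid > k_th * mad(resid))
    if (length(hits)) found[[length(found) + 1]] <- data.frame(index = i, channel = hits)
  }
  found <- do.call(rbind, found)
  got <- out$provenance$repairs[, c("index", "channel")]
  expect_equal(got[order(got$index, got$channel), ],
               found[order(found$index, found$channel), ],
               ignore_attr = TRUE)
})

test_that("baseline subtraction recovers peaks over a known cubic background", {
  axis <- seq(605, 1715, by = 1)
  flat <- subtract_baseline(raman_spectrum(axis, rep(0, length(axis))))
  expect_true(all(abs(flat$intensity) < 1e-9))

  clean <- make_component_spectrum(default_bands(), axis)$intensity
  u <- (axis - 605) / 1110
  cubic <- 2 + 1.5 * u - 2 * u^2 + 1.2 * u^3
  corrected <- subtract_baseline(raman_spectrum(axis, clean + cubic))
  for (b in c(850, 1003, 1266, 1337, 1447, 1660)) {
    i <- which(axis == b)
    expect_lt(abs(corrected$intensity[i] - clean[i]) / clean[i], 0.05)
  }

  # a pure smooth cubic is absorbed almost entirely into the baseline
  resid <- subtract_baseline(raman_spectrum(axis, cubic))$intensity
  expect_lt(sqrt(mean(resid^2)), 0.01 * sqrt(mean(cubic^2)))

  expect_error(subtract_baseline(raman_spectrum(axis[1:20], rnorm(20))),
               "too short")
})

test_that("baseline subtraction commutes with positive intensity scaling", {
  axis <- seq(605, 1715, by = 1)
  set.seed(7)
  y <- make_component_spectrum(default_bands(), axis)$intensity +
    1 + (axis - 605) / 1110 + rnorm(length(axis), sd = 0.02)
  a <- subtract_baseline(raman_spectrum(axis, y))$intensity
  b <- subtract_baseline(raman_spectrum(axis, 3.7 * y))$intensity
  expect_equal(b, 3.7 * a, tolerance = 1e-6)
})

test_that("map averaging is the pointwise mean, invariant to order", {
  axis <- c(605, 606)
  m <- raman_map(axis, rbind(c(0, 2), c(2, 0)),
                 data.frame(x = c(0, 1.5), y = c(0, 0)))
  expect_equal(average_map(m)$intensity, c(1, 1))

  same <- raman_map(axis, rbind(c(1, 2), c(1, 2), c(1, 2)),
                    data.frame(x = c(0, 1.5, 3), y = 0))
  expect_equal(average_map(same)$intensity, c(1, 2))

  cfg <- tiny_config(grid_side = 3)
  mm <- generate_map("sham", config = cfg, seed = 2)
  perm <- sample(nrow(mm$intensities))
  mp <- raman_map(mm$axis, mm$intensities[perm, ], mm$positions[perm, ],
                  step = mm$step)
  expect_equal(average_map(mp)$intensity, average_map(mm)$intensity)
})

test_that("normalisation yields unit Euclidean norm", {
  s <- normalize_spectrum(raman_spectrum(c(605, 606), c(3, 4)))
  expect_equal(s$intensity, c(0.6, 0.8))
  expect_equal(normalize_spectrum(s)$intensity, s$intensity)
  set.seed(3)
  for (i in 1:100) {
    v <- normalize_spectrum(raman_spectrum(1:10, runif(10) + 0.01))
    expect_equal(sqrt(sum(v$intensity^2)), 1, tolerance = 1e-12)
  }
  expect_error(normalize_spectrum(raman_spectrum(1:3, c(0, 0, 0))), "all-zero")
})

test_that("the stratified split is exact per group, disjoint and seeded", {
  ds <- tiny_dataset(grid_side = 5) # 3 groups x 2 mice x 25
  cfg <- preprocess_config(split_fraction = 0.2, split_seed = 3)
  sp <- split_dataset(ds, cfg)
  for (g in ds$classes) {
    n_g <- sum(ds$meta$group == g)
    expect_equal(sum(sp$test$meta$group == g), round(0.2 * n_g))
    expect_equal(sum(sp$train$meta$group == g), n_g - round(0.2 * n_g))
  }
  expect_equal(sort(c(sp$test_idx, setdiff(seq_len(n_spectra(ds)), sp$test_idx))),
               seq_len(n_spectra(ds)))

  sp2 <- split_dataset(ds, cfg)
  expect_identical(sp$test_idx, sp2$test_idx)
  sp3 <- split_dataset(ds, preprocess_config(split_seed = 4))
  expect_false(identical(sp$test_idx, sp3$test_idx))

  small <- subset_dataset(ds, which(!duplicated(ds$meta$group)))
  expect_error(split_dataset(small, cfg), "too small")
})
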