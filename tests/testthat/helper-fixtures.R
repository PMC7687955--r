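# Shared fixtures: small configurations that keep the study's structure
# (3 groups, band effects, per-mouse heterogeneity) at reduced size.

tiny_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(mice_per_group = 2, eyes_per_mouse = 1, grid_side = 4, seed = seed),
    list(...))
  do.call(sim_config, args)
}

# Noise- and baseline-free config: spectra are exact clean band sums.
clean_config <- function(seed = 1, ...) {
  tiny_config(seed = seed, baseline_scale = 0, noise_sigma = 0,
              cosmic_ray_rate = 0, ...)
}

tiny_som_config <- function(seed = 1, ...) {
  args <- utils::modifyList(list(rows = 4, cols = 4, seed = seed), list(...))
  do.call(som_config, args)
}

# A small labeled dataset of unit-normalised spectra for SOM tests.
tiny_dataset <- function(seed = 1, ...) {
  cfg <- tiny_config(seed = seed, ...)
  preprocess_maps(generate_maps(cfg), preprocess_config(),
                  classes = names(cfg$effects))
}

# Independent brute-force BMU: plain double loop over neurons.
brute_bmu <- function(grid, x) {
  best <- -Inf
  arg <- NA_integer_
  for (k in seq_len(nrow(grid$weights))) {
    w <- grid$weights[k, ]
    s <- sum(w * x) / (sqrt(sum(w^2)) * sqrt(sum(x^2)))
    if (s > best) {
      best <- s
      arg <- k
    }
  }
  arg
}

# Projected-gradient NNLS run to convergence: the independent oracle for
# the active-set solver.
pg_nnls <- function(D, y, iters = 50000, tol = 1e-12) {
  c_hat <- rep(0, ncol(D))
  L <- max(eigen(crossprod(D), only.values = TRUE)$values)
  for (i in seq_len(iters)) {
    grad <- crossprod(D, D %*% c_hat - y)
    c_new <- pmax(c_hat - grad / L, 0)
    if (max(abs(c_new - c_hat)) < tol) {
      c_hat <- c_new
      break
    }
    c_hat <- c_new
  }
  as.numeric(c_hat)
}
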