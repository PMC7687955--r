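#' Self-organizing map configuration
#'
#' Defaults follow the study's tuned model: a 20 x 20 hexagonal grid,
#' 5 epochs of the training data (57,600 presentations for an
#' 11,520-spectrum training set), initial learning rate 0.2, and an
#' initial neighbourhood radius of 2/3 of the grid edge length, with
#' cosine similarity for best-matching-unit search.
#'
#' @param rows,cols grid dimensions (>= 2 each).
#' @param n_epochs passes over the training set; total presentations =
#'   `n_epochs * n` unless `steps` is given.
#' @param steps explicit total presentation count (overrides `n_epochs`).
#' @param initial_learning_rate starting learning rate in (0, 1].
#' @param final_learning_rate learning rate at the last step (default 0.01).
#' @param initial_neighborhood starting neighbourhood radius sigma, in
#'   hex-layout distance units; default `(2/3) * max(rows, cols)`.
#' @param final_neighborhood sigma at the last step (default 1).
#' @param lr_decay `"linear"` or `"exponential"` schedule.
#' @param nbh_decay `"linear"`, `"exponential"`, or `"constant"` (the
#'   latter keeps sigma at its initial value throughout).
#' @param seed integer seed for initialization and presentation order.
#' @return A `som_config` list.
#' @export
som_config <- function(rows = 20, cols = 20, n_epochs = 5, steps = NULL,
                       initial_learning_rate = 0.2,
                       final_learning_rate = 0.01,
                       initial_neighborhood = (2 / 3) * max(rows, cols),
                       final_neighborhood = 1.0,
                       lr_decay = c("linear", "exponential"),
                       nbh_decay = c("linear", "exponential", "constant"),
                       seed = 1) {
  lr_decay <- match.arg(lr_decay)
  nbh_decay <- match.arg(nbh_decay)
  stopifnot(rows >= 2, cols >= 2, n_epochs >= 1,
            initial_learning_rate > 0, initial_learning_rate <= 1,
            final_learning_rate > 0, initial_neighborhood > 0,
            final_neighborhood > 0)
  structure(list(rows = rows, cols = cols, n_epochs = n_epochs, steps = steps,
                 initial_learning_rate = initial_learning_rate,
                 final_learning_rate = final_learning_rate,
                 initial_neighborhood = initial_neighborhood,
                 final_neighborhood = final_neighborhood,
                 lr_decay = lr_decay, nbh_decay = nbh_decay, seed = seed),
            class = "som_config")
}

# Hexagonal layout: odd rows shifted by half a cell, row spacing sqrt(3)/2.
hex_layout <- function(rows, cols) {
  r <- rep(seq_len(rows) - 1, each = cols)
  c <- rep(seq_len(cols) - 1, times = rows)
  data.frame(x = c + 0.5 * (r %% 2), y = r * sqrt(3) / 2)
}

#' Initialize a SOM grid from training data
#'
#' Each neuron's weight vector is a randomly sampled training spectrum
#' plus small Gaussian jitter (sd = 1e-3 x the data's intensity scale),
#' then unit-normalised.
#'
#' @param config a [som_config].
#' @param data a non-empty [raman_dataset].
#' @return Object of class `som_grid`: weights (neurons x channels), hex
#'   layout coordinates, axis, and (until [accumulate_hits]) empty class
#'   hit counts.
#' @export
init_grid <- function(config, data) {
  stopifnot(inherits(config, "som_config"), inherits(data, "raman_dataset"))
  n <- n_spectra(data)
  if (n < 1) stop("cannot initialize a SOM from an empty dataset")
  k <- config$rows * config$cols
  d <- length(data$axis)
  W <- with_seed(config$seed, {
    idx <- sample.int(n, k, replace = TRUE)
    jitter_sd <- 1e-3 * sd(data$intensities)
    data$intensities[idx, , drop = FALSE] +
      matrix(rnorm(k * d, sd = jitter_sd), k, d)
  })
  nrm <- sqrt(rowSums(W^2))
  nrm[nrm == 0] <- 1
  W <- W / nrm
  structure(list(weights = W, hex = hex_layout(config$rows, config$cols),
                 rows = config$rows, cols = config$cols, axis = data$axis,
                 config = config, class_hits = NULL, classes = NULL),
            class = "som_grid")
}

#' @export
print.som_grid <- function(x, ...) {
  cat(sprintf("<som_grid> %d x %d hexagonal, %d-channel weights%s\n",
              x$rows, x$cols, ncol(x$weights),
              if (is.null(x$class_hits)) "" else ", class hits attached"))
  invisible(x)
}

#' Cosine similarity between two vectors
#'
#' @param a,b numeric vectors of equal length, neither all-zero.
#' @return `dot(a, b) / (|a| |b|)`, in `[-1, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity is undefined for a zero vector")
  sum(a * b) / (na * nb)
}

# Vectorised BMU search for a matrix of inputs (rows); ties -> lowest index.
bmu_indices <- function(grid, X) {
  if (ncol(X) != ncol(grid$weights)) {
    stop("input dimension does not match the SOM weights")
  }
  wn <- sqrt(rowSums(grid$weights^2))
  S <- X %*% t(grid$weights)
  S <- sweep(S, 2, wn, "/") # input norm > 0 does not change the argmax
  max.col(S, ties.method = "first")
}

#' Find the best matching unit for a spectrum
#'
#' @param grid a `som_grid`.
#' @param spectrum a [raman_spectrum] or numeric vector matching the
#'   weight dimension.
#' @return Neuron index (row of `grid$weights`); ties broken by lowest
#'   index.
#' @export
find_bmu <- function(grid, spectrum) {
  x <- if (inherits(spectrum, "raman_spectrum")) spectrum$intensity else
    as.numeric(spectrum)
  if (sqrt(sum(x^2)) == 0) stop("cannot match an all-zero spectrum")
  bmu_indices(grid, matrix(x, nrow = 1))
}

#' Total training presentations for a configuration
#'
#' With the study defaults (5 epochs) and an 11,520-spectrum training
#' split this is 57,600 presentations.
#'
#' @param config a [som_config].
#' @param n training-set size.
#' @return `config$steps` if set, else `config$n_epochs * n`.
#' @export
training_steps <- function(config, n) {
  if (is.null(config$steps)) config$n_epochs * n else config$steps
}

decay_schedule <- function(kind, from, to, steps) {
  if (steps == 1) return(from)
  t <- (seq_len(steps) - 1) / (steps - 1)
  switch(kind,
         linear = from + (to - from) * t,
         exponential = from * (to / from)^t,
         constant = rep(from, steps))
}

#' Train a self-organizing map
#'
#' Iterative Kohonen training: at each step a spectrum is drawn by
#' cycling a per-epoch seeded shuffle of the training set, its BMU found
#' by cosine similarity, and every neuron updated by
#' `w <- w + alpha(t) h(i, bmu, t) (x - w)` with a Gaussian neighbourhood
#' `h = exp(-d^2 / (2 sigma(t)^2))` over hex-layout Euclidean distance.
#' Learning rate and neighbourhood follow the configured decay schedules.
#'
#' @param grid an initialized `som_grid`.
#' @param data the training [raman_dataset].
#' @param config a [som_config]; defaults to the grid's own.
#' @return The trained `som_grid`; the per-epoch running quantization
#'   error (mean `1 - similarity` of each presented spectrum to its BMU
#'   at presentation time) is attached as `qe_trace`.
#' @export
som_train <- function(grid, data, config = grid$config) {
  stopifnot(inherits(grid, "som_grid"), inherits(data, "raman_dataset"))
  n <- n_spectra(data)
  steps <- training_steps(config, n)
  if (steps < 1) stop("training needs at least one step")
  epochs <- ceiling(steps / n)
  order <- with_seed(config$seed + 1L,
                     unlist(lapply(seq_len(epochs), function(e) sample.int(n))))
  order <- order[seq_len(steps)]
  alpha <- decay_schedule(config$lr_decay, config$initial_learning_rate,
                          config$final_learning_rate, steps)
  sigma <- decay_schedule(config$nbh_decay, config$initial_neighborhood,
                          config$final_neighborhood, steps)
  D2 <- as.matrix(dist(grid$hex))^2
  res <- som_train_cpp(grid$weights, data$intensities, order - 1L, D2,
                       alpha, sigma, n)
  out <- grid
  out$weights <- res$weights
  out$qe_trace <- as.numeric(res$qe_trace)
  out
}

#' Quantization error of a SOM on a dataset
#'
#' @param grid a `som_grid`.
#' @param data a non-empty [raman_dataset].
#' @return Mean over spectra of `1 - cosine_similarity(x, w_bmu)`.
#' @export
quantization_error <- function(grid, data) {
  stopifnot(inherits(data, "raman_dataset"))
  n <- n_spectra(data)
  if (n < 1) stop("quantization error needs at least one spectrum")
  X <- data$intensities
  b <- bmu_indices(grid, X)
  W <- grid$weights[b, , drop = FALSE]
  sims <- rowSums(X * W) /
    (sqrt(rowSums(X^2)) * sqrt(rowSums(W^2)))
  mean(1 - sims)
}
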