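#' Accumulate per-neuron class hit counts
#'
#' For every training spectrum, the BMU is found and a hit recorded for
#' the spectrum's class at that neuron. The hit counts carry the
#' supervision: labels never influence the weight updates themselves.
#'
#' @param grid a trained `som_grid`.
#' @param data a labeled [raman_dataset]; its declared class set becomes
#'   the grid's class set.
#' @return The grid with `class_hits` (neurons x classes count matrix)
#'   and `classes` filled in.
#' @export
accumulate_hits <- function(grid, data) {
  stopifnot(inherits(grid, "som_grid"), inherits(data, "raman_dataset"))
  labels <- data$meta$group
  if (anyNA(labels)) stop("labels outside the declared class set")
  b <- bmu_indices(grid, data$intensities)
  k <- nrow(grid$weights)
  classes <- data$classes
  hits <- matrix(0L, k, length(classes), dimnames = list(NULL, classes))
  for (j in seq_along(classes)) {
    tab <- tabulate(b[labels == classes[j]], nbins = k)
    hits[, j] <- tab
  }
  grid$class_hits <- hits
  grid$classes <- classes
  grid
}

#' SOMDI discriminant spectra
#'
#' For each class k, neuron i's activation share is
#' `m[i, k] = hits[i, k] / sum_i hits[i, k]`. The discriminant spectrum of
#' class k is the hit-share-contrast-weighted sum of the neuron weight
#' vectors, `sum_i (m[i, k] - mean over other classes of m[i, .]) w_i`:
#' positive entries mark wavenumbers elevated in class k relative to the
#' remaining classes, negative entries wavenumbers suppressed.
#'
#' @param grid a `som_grid` with class hits ([accumulate_hits]).
#' @return Object of class `somdi_result`: list with `axis`,
#'   `discriminants` (channels x classes matrix) and `classes`.
#' @export
somdi <- function(grid) {
  if (is.null(grid$class_hits)) stop("class hits not populated; run accumulate_hits first")
  hits <- grid$class_hits
  totals <- colSums(hits)
  empty <- names(totals)[totals == 0]
  if (length(empty)) {
    stop("class with zero hits: ", paste(empty, collapse = ", "))
  }
  M <- sweep(hits, 2, totals, "/")
  nc <- ncol(M)
  disc <- sapply(seq_len(nc), function(k) {
    other <- rowMeans(M[, -k, drop = FALSE])
    as.numeric(t(grid$weights) %*% (M[, k] - other))
  })
  colnames(disc) <- colnames(hits)
  structure(list(axis = grid$axis, discriminants = disc,
                 classes = colnames(hits)),
            class = "somdi_result")
}

#' @export
print.somdi_result <- function(x, ...) {
  cat(sprintf("<somdi_result> %d channels x %d classes (%s)\n",
              nrow(x$discriminants), length(x$classes),
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

# For each BMU index, the neuron whose hits decide the class: the BMU
# itself, or (if it was never hit) the nearest hit neuron in hex layout.
effective_hit_neuron <- function(grid, b) {
  hit_any <- rowSums(grid$class_hits) > 0
  if (!any(hit_any)) stop("no neuron has any class hits")
  need <- !hit_any[b]
  if (any(need)) {
    hx <- grid$hex
    hit_idx <- which(hit_any)
    for (i in which(need)) {
      d2 <- (hx$x[hit_idx] - hx$x[b[i]])^2 + (hx$y[hit_idx] - hx$y[b[i]])^2
      b[i] <- hit_idx[which.min(d2)]
    }
  }
  b
}

#' Classify spectra with a supervised SOM
#'
#' A spectrum activates its BMU; the predicted class is the class with
#' most training hits at that neuron. If the BMU was never hit during
#' training, the nearest (hex-layout) neuron with hits is used. Ties are
#' broken by class order; since BMU search is cosine-based, predictions
#' are invariant to positive scaling of the input.
#'
#' @param grid a `som_grid` with class hits.
#' @param x a [raman_spectrum], numeric vector, or matrix of row spectra.
#' @return Factor of predicted class labels (levels = the grid's classes).
#' @export
som_classify <- function(grid, x) {
  if (is.null(grid$class_hits)) stop("class hits not populated; run accumulate_hits first")
  X <- if (inherits(x, "raman_spectrum")) matrix(x$intensity, nrow = 1)
  else if (is.matrix(x)) x
  else matrix(as.numeric(x), nrow = 1)
  b <- bmu_indices(grid, X)
  b <- effective_hit_neuron(grid, b)
  pred <- max.col(grid$class_hits[b, , drop = FALSE], ties.method = "first")
  factor(grid$classes[pred], levels = grid$classes)
}

# Stratified fold assignment: within each group, a seeded shuffle dealt
# round-robin, so fold sizes differ by at most one per group.
stratified_folds <- function(groups, k, seed) {
  folds <- integer(length(groups))
  for (g in levels(groups)) {
    gi <- which(groups == g)
    if (length(gi) < k) stop("group '", g, "' has fewer spectra than folds")
    shuffled <- with_seed(seed + match(g, levels(groups)), sample(gi))
    folds[shuffled] <- rep_len(seq_len(k), length(gi))
  }
  folds
}

#' Stratified k-fold cross-validation of the supervised SOM
#'
#' @param dataset a labeled [raman_dataset]; every group needs at least
#'   `k` spectra.
#' @param config a [som_config].
#' @param k number of folds (default 10).
#' @return List: `accuracy` (per fold), `mean`, `sd`, and `predictions`
#'   (factor, one prediction per spectrum from its held-out fold).
#' @export
cross_validate <- function(dataset, config, k = 10) {
  stopifnot(inherits(dataset, "raman_dataset"))
  groups <- dataset$meta$group
  folds <- stratified_folds(groups, k, config$seed)
  preds <- factor(rep(NA_character_, n_spectra(dataset)),
                  levels = dataset$classes)
  acc <- numeric(k)
  for (f in seq_len(k)) {
    hold <- which(folds == f)
    train <- subset_dataset(dataset, which(folds != f))
    cfg <- config
    cfg$seed <- config$seed + f
    grid <- som_train(init_grid(cfg, train), train, cfg)
    grid <- accumulate_hits(grid, train)
    p <- som_classify(grid, dataset$intensities[hold, , drop = FALSE])
    preds[hold] <- p
    acc[f] <- mean(p == groups[hold])
  }
  list(accuracy = acc, mean = mean(acc), sd = sd(acc), predictions = preds)
}

#' Evaluate a supervised SOM over repeated initializations
#'
#' Trains `repeats` SOMs from distinct initializations (seeds
#' `config$seed + 1 ... + repeats`), classifies the held-out test set
#' with each, and averages the row-normalised percentage confusion
#' matrices. Rows are actual classes and sum to 100.
#'
#' @param train_data,test_data disjoint labeled [raman_dataset]s sharing
#'   one class set; every class must appear in the test set.
#' @param config a [som_config].
#' @param repeats number of independent initializations (default 10).
#' @return Object of class `som_confusion`: `mean` (percent matrix,
#'   actual x predicted), `sd_diag` (per-class sd of the diagonal across
#'   repeats), `per_repeat` (list of percent matrices), `classes`.
#' @export
som_evaluate <- function(train_data, test_data, config, repeats = 10) {
  stopifnot(inherits(train_data, "raman_dataset"),
            inherits(test_data, "raman_dataset"))
  classes <- train_data$classes
  if (!identical(classes, test_data$classes)) {
    stop("train and test data must declare the same class set")
  }
  missing <- setdiff(classes, unique(as.character(test_data$meta$group)))
  if (length(missing)) {
    stop("class absent from test data: ", paste(missing, collapse = ", "))
  }
  actual <- test_data$meta$group
  mats <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    cfg <- config
    cfg$seed <- config$seed + r
    grid <- som_train(init_grid(cfg, train_data), train_data, cfg)
    grid <- accumulate_hits(grid, train_data)
    pred <- som_classify(grid, test_data$intensities)
    counts <- table(actual = actual, predicted = pred)
    mats[[r]] <- 100 * sweep(unclass(counts), 1, rowSums(counts), "/")
  }
  mean_mat <- Reduce(`+`, mats) / repeats
  diag_reps <- vapply(mats, diag, numeric(length(classes)))
  sd_diag <- if (repeats > 1) apply(diag_reps, 1, sd) else
    rep(0, length(classes))
  names(sd_diag) <- classes
  structure(list(mean = mean_mat, sd_diag = sd_diag, per_repeat = mats,
                 classes = classes, repeats = repeats),
            class = "som_confusion")
}

#' @export
print.som_confusion <- function(x, digits = 1, ...) {
  cat(sprintf("<som_confusion> mean over %d initializations (row %%)\n",
              x$repeats))
  print(round(x$mean, digits))
  cat("diagonal sd:", paste(sprintf("%s %.1f", x$classes, x$sd_diag),
                            collapse = ", "), "\n")
  invisible(x)
}
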