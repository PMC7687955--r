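#' Preprocessing configuration
#'
#' @param cosmic_k spike threshold in robust-deviation (MAD) units
#'   (default 8).
#' @param baseline_nodes number of spline nodes for baseline estimation
#'   (default 11, >= 3).
#' @param baseline_max_iter iteration cap for the lower-envelope re-fit.
#' @param normalize whether spectra are scaled to unit Euclidean norm
#'   before classification.
#' @param split_fraction test fraction of the stratified split (default 0.2).
#' @param split_seed seed for the stratified split.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(cosmic_k = 8, baseline_nodes = 11,
                              baseline_max_iter = 50, normalize = TRUE,
                              split_fraction = 0.2, split_seed = 1) {
  stopifnot(cosmic_k > 0, baseline_nodes >= 3, baseline_max_iter >= 1,
            split_fraction > 0, split_fraction < 1)
  structure(list(cosmic_k = cosmic_k, baseline_nodes = baseline_nodes,
                 baseline_max_iter = baseline_max_iter, normalize = normalize,
                 split_fraction = split_fraction, split_seed = split_seed),
            class = "preprocess_config")
}

# 4-connected spatial neighbours on the map grid, by position matching.
grid_neighbours <- function(positions, step) {
  n <- nrow(positions)
  key <- paste(round(positions$x / step), round(positions$y / step))
  lookup <- match(key, key) # identity; used via named environment below
  idx <- seq_len(n)
  names(idx) <- key
  offs <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  lapply(seq_len(n), function(i) {
    gx <- round(positions$x[i] / step)
    gy <- round(positions$y[i] / step)
    nb <- vapply(offs, function(o) {
      j <- idx[paste(gx + o[1], gy + o[2])]
      if (is.na(j)) NA_integer_ else j
    }, integer(1))
    nb[!is.na(nb)]
  })
}

# Columnwise median of up to 4 rows without apply(): closed forms per count.
rows_median <- function(X) {
  k <- nrow(X)
  if (k == 1) return(X[1, ])
  if (k == 2) return((X[1, ] + X[2, ]) / 2)
  if (k == 3) {
    return(X[1, ] + X[2, ] + X[3, ] -
             pmax(X[1, ], X[2, ], X[3, ]) - pmin(X[1, ], X[2, ], X[3, ]))
  }
  s <- X[1, ] + X[2, ] + X[3, ] + X[4, ]
  (s - pmax(X[1, ], X[2, ], X[3, ], X[4, ]) -
     pmin(X[1, ], X[2, ], X[3, ], X[4, ])) / 2
}

#' Remove cosmic-ray spikes using spatial nearest neighbours
#'
#' For every spectrum, each channel is compared to the median of the
#' 4-connected grid neighbours at that channel; channels whose positive
#' residual exceeds `cosmic_k` robust standard deviations (MAD of the
#' spectrum's residuals) are replaced by the neighbour median. Cosmic rays
#' are single-acquisition events, so spatial neighbours are clean
#' references.
#'
#' @param map a [raman_map] with at least 2 spectra.
#' @param config a [preprocess_config].
#' @return The repaired map; repairs are recorded in
#'   `provenance$repairs` (data frame: index, x, y, channel, wavenumber,
#'   original, replacement).
#' @export
remove_cosmic_rays <- function(map, config = preprocess_config()) {
  stopifnot(inherits(map, "raman_map"))
  n <- nrow(map$intensities)
  if (n < 2) stop("cosmic-ray removal needs at least 2 spectra (no neighbours)")
  nbrs <- grid_neighbours(map$positions, map$step)
  X <- map$intensities
  repaired <- X
  reps <- list()
  for (i in seq_len(n)) {
    nb <- nbrs[[i]]
    if (!length(nb)) next
    ref <- rows_median(X[nb, , drop = FALSE])
    resid <- X[i, ] - ref
    scale <- mad(resid)
    if (scale <= 0) scale <- max(abs(resid)) * 1e-12 + 1e-300
    hit <- which(resid > config$cosmic_k * scale)
    if (length(hit)) {
      reps[[length(reps) + 1]] <- data.frame(
        index = i, x = map$positions$x[i], y = map$positions$y[i],
        channel = hit, wavenumber = map$axis[hit],
        original = X[i, hit], replacement = ref[hit])
      repaired[i, hit] <- ref[hit]
    }
  }
  repairs <- if (length(reps)) do.call(rbind, reps) else
    data.frame(index = integer(0), x = numeric(0), y = numeric(0),
               channel = integer(0), wavenumber = numeric(0),
               original = numeric(0), replacement = numeric(0))
  out <- map
  out$intensities <- repaired
  out$provenance$repairs <- repairs
  out
}

baseline_envelope <- function(wavenumber, intensity, nodes, max_iter) {
  n <- length(wavenumber)
  # nodes equal-width windows spanning the axis
  edges <- seq(min(wavenumber), max(wavenumber), length.out = nodes + 1)
  win <- findInterval(wavenumber, edges, rightmost.closed = TRUE)
  win[win > nodes] <- nodes
  y_work <- intensity
  prev <- rep(Inf, nodes)
  spl_y <- numeric(n)
  for (it in seq_len(max_iter)) {
    node_x <- numeric(nodes)
    node_v <- numeric(nodes)
    for (j in seq_len(nodes)) {
      sel <- which(win == j)
      k <- sel[which.min(y_work[sel])]
      node_x[j] <- wavenumber[k]
      node_v[j] <- y_work[k]
    }
    spl_y <- splinefun(node_x, node_v, method = "natural")(wavenumber)
    if (max(abs(node_v - prev)) < 1e-6) break
    prev <- node_v
    y_work <- pmax(y_work, spl_y) # lift points below the envelope
  }
  spl_y
}

#' Subtract a fluorescence baseline by iterative lower-envelope spline
#'
#' Emulates node-based "intelligent" spline baseline correction: node
#' windows are spread evenly across the axis, node values start at window
#' minima, a natural cubic spline is fitted through the nodes, points
#' below the current spline are lifted onto it (so noise dips stop
#' dragging the envelope down while peaks stay excluded via the window
#' minima), and the fit is repeated until node values stabilise
#' (< 1e-6 change) or `baseline_max_iter` is reached. The final spline is
#' subtracted from the original spectrum; the result is not clipped and
#' may be slightly negative.
#'
#' @param spectrum a [raman_spectrum] with more than
#'   `2 * baseline_nodes` points.
#' @param config a [preprocess_config].
#' @return Baseline-subtracted [raman_spectrum]; the fitted baseline is
#'   attached as attribute `"baseline"`.
#' @export
subtract_baseline <- function(spectrum, config = preprocess_config()) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  if (length(spectrum$wavenumber) <= 2 * config$baseline_nodes) {
    stop("spectrum too short for ", config$baseline_nodes, " baseline nodes")
  }
  base <- baseline_envelope(spectrum$wavenumber, spectrum$intensity,
                            config$baseline_nodes, config$baseline_max_iter)
  out <- raman_spectrum(spectrum$wavenumber, spectrum$intensity - base)
  attr(out, "baseline") <- base
  out
}

# Matrix fast path used by map/dataset pipelines.
subtract_baseline_matrix <- function(axis, X, config) {
  t(vapply(seq_len(nrow(X)), function(i) {
    X[i, ] - baseline_envelope(axis, X[i, ], config$baseline_nodes,
                               config$baseline_max_iter)
  }, numeric(ncol(X))))
}

#' Subtract baselines from every spectrum of a map
#'
#' @param map a [raman_map].
#' @param config a [preprocess_config].
#' @return The map with per-spectrum baselines removed.
#' @export
subtract_baseline_map <- function(map, config = preprocess_config()) {
  out <- map
  out$intensities <- subtract_baseline_matrix(map$axis, map$intensities, config)
  out
}

#' Average a spectral map into a single spectrum
#'
#' @param map a non-empty [raman_map].
#' @return The pointwise mean [raman_spectrum].
#' @export
average_map <- function(map) {
  stopifnot(inherits(map, "raman_map"))
  if (nrow(map$intensities) < 1) stop("cannot average an empty map")
  raman_spectrum(map$axis, colMeans(map$intensities))
}

#' Scale a spectrum to unit Euclidean norm
#'
#' @param spectrum a [raman_spectrum]; must not be all-zero.
#' @return The normalised [raman_spectrum].
#' @export
normalize_spectrum <- function(spectrum) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  nrm <- sqrt(sum(spectrum$intensity^2))
  if (nrm == 0) stop("cannot normalize an all-zero spectrum")
  raman_spectrum(spectrum$wavenumber, spectrum$intensity / nrm)
}

#' Stratified train/test split
#'
#' Exactly `round(split_fraction * n_g)` spectra per group are reserved
#' for testing; the split is disjoint, exhaustive, and deterministic under
#' `split_seed`.
#'
#' @param dataset a [raman_dataset].
#' @param config a [preprocess_config].
#' @return List with elements `train` and `test` ([raman_dataset]s) and
#'   `test_idx` (the reserved row indices).
#' @export
split_dataset <- function(dataset, config = preprocess_config()) {
  stopifnot(inherits(dataset, "raman_dataset"))
  groups <- dataset$meta$group
  test_idx <- integer(0)
  for (g in levels(groups)) {
    gi <- which(groups == g)
    n_test <- round(config$split_fraction * length(gi))
    if (length(gi) < 1 / config$split_fraction) {
      stop("group '", g, "' too small to split at fraction ",
           config$split_fraction)
    }
    picked <- with_seed(config$split_seed + match(g, levels(groups)),
                        sample(gi, n_test))
    test_idx <- c(test_idx, picked)
  }
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_len(n_spectra(dataset)), test_idx)
  list(train = subset_dataset(dataset, train_idx),
       test = subset_dataset(dataset, test_idx),
       test_idx = test_idx)
}

#' Full per-map preprocessing pipeline
#'
#' Applies cosmic-ray removal and per-spectrum baseline subtraction to
#' each map, then flattens into a labeled dataset (optionally
#' unit-normalised per spectrum).
#'
#' @param maps list of [raman_map] with group/mouse/eye provenance.
#' @param config a [preprocess_config].
#' @param classes declared class set for the resulting dataset.
#' @return A [raman_dataset]; total repair count in attribute `"n_repairs"`.
#' @export
preprocess_maps <- function(maps, config = preprocess_config(), classes = NULL) {
  n_rep <- 0
  cleaned <- lapply(maps, function(m) {
    m <- remove_cosmic_rays(m, config)
    n_rep <<- n_rep + nrow(m$provenance$repairs)
    subtract_baseline_map(m, config)
  })
  ds <- flatten_maps(cleaned, classes = classes)
  if (config$normalize) {
    nrm <- sqrt(rowSums(ds$intensities^2))
    if (any(nrm == 0)) stop("all-zero spectrum after preprocessing")
    ds$intensities <- ds$intensities / nrm
  }
  attr(ds, "n_repairs") <- n_rep
  ds
}
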