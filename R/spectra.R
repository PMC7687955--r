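#' A single Raman spectrum
#'
#' Container for one Raman measurement: a strictly increasing wavenumber
#' axis (cm^-1) and matching intensities in arbitrary units. Axes supplied
#' in descending order (common in instrument exports) are reversed, with
#' intensities reordered consistently.
#'
#' @param wavenumber numeric vector of Raman shifts (cm^-1), strictly
#'   monotone, length >= 2.
#' @param intensity numeric vector of intensities, same length.
#' @return An object of class `raman_spectrum`: a list with elements
#'   `wavenumber` and `intensity`.
#' @examples
#' s <- raman_spectrum(c(605, 606, 607), c(1, 2, 1))
#' @export
raman_spectrum <- function(wavenumber, intensity) {
  wavenumber <- as.numeric(wavenumber)
  intensity <- as.numeric(intensity)
  if (length(wavenumber) != length(intensity)) {
    stop("wavenumber and intensity must have equal length")
  }
  if (length(wavenumber) < 2) {
    stop("a spectrum needs at least 2 points")
  }
  if (anyNA(wavenumber) || anyNA(intensity)) {
    stop("missing values are not allowed in a spectrum")
  }
  d <- diff(wavenumber)
  if (all(d < 0)) { # descending instrument export: normalise order
    wavenumber <- rev(wavenumber)
    intensity <- rev(intensity)
  } else if (any(d <= 0)) {
    stop("wavenumber axis must be strictly monotone")
  }
  structure(list(wavenumber = wavenumber, intensity = intensity),
            class = "raman_spectrum")
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum> %d points, %.1f-%.1f cm-1\n",
              length(x$wavenumber), min(x$wavenumber), max(x$wavenumber)))
  invisible(x)
}

#' @export
length.raman_spectrum <- function(x) length(x$wavenumber)

# Tolerance under which two axes count as the same axis.
AXIS_TOL <- 1e-6

same_axis <- function(a, b) {
  length(a) == length(b) && all(abs(a - b) < AXIS_TOL)
}

#' A spectral map: a spatial grid of spectra
#'
#' @param axis shared wavenumber axis (cm^-1), strictly increasing.
#' @param intensities numeric matrix, one row per spectrum, `length(axis)`
#'   columns.
#' @param positions data frame with numeric columns `x`, `y` (micrometres),
#'   one row per spectrum; positions must be unique.
#' @param step grid step size in micrometres (default 1.5).
#' @param provenance free-form list of metadata (e.g. injected-spike records
#'   from the synthetic generator).
#' @return Object of class `raman_map`.
#' @export
raman_map <- function(axis, intensities, positions, step = 1.5,
                      provenance = list()) {
  axis <- as.numeric(axis)
  intensities <- as.matrix(intensities)
  if (any(diff(axis) <= 0)) stop("map axis must be strictly increasing")
  if (ncol(intensities) != length(axis)) {
    stop("intensity columns must match axis length")
  }
  if (nrow(positions) != nrow(intensities)) {
    stop("one (x, y) position is required per spectrum")
  }
  if (anyDuplicated(positions[, c("x", "y")])) {
    stop("map positions must be unique")
  }
  structure(list(axis = axis, intensities = intensities,
                 positions = as.data.frame(positions), step = step,
                 provenance = provenance),
            class = "raman_map")
}

#' @export
print.raman_map <- function(x, ...) {
  cat(sprintf("<raman_map> %d spectra x %d channels, step %.2f um\n",
              nrow(x$intensities), length(x$axis), x$step))
  invisible(x)
}

#' Extract one spectrum from a map or dataset
#'
#' @param x a `raman_map` or `raman_dataset`.
#' @param i row index.
#' @return A `raman_spectrum`.
#' @export
get_spectrum <- function(x, i) {
  raman_spectrum(x$axis, x$intensities[i, ])
}

#' A labeled collection of spectra with group/mouse/eye metadata
#'
#' Flat dataset used for classifier training and evaluation: all spectra
#' share one axis; per-spectrum metadata carries the injury-state label,
#' the animal identifier, the eye side and (optionally) map coordinates.
#'
#' @param axis shared wavenumber axis (cm^-1).
#' @param intensities matrix, one row per spectrum.
#' @param meta data frame with at least a `group` column; typically also
#'   `mouse` and `eye` (ipsilateral/contralateral).
#' @param classes declared class set; defaults to the groups present.
#' @return Object of class `raman_dataset`.
#' @export
raman_dataset <- function(axis, intensities, meta, classes = NULL) {
  axis <- as.numeric(axis)
  intensities <- as.matrix(intensities)
  meta <- as.data.frame(meta)
  if (any(diff(axis) <= 0)) stop("dataset axis must be strictly increasing")
  if (ncol(intensities) != length(axis)) {
    stop("intensity columns must match axis length")
  }
  if (nrow(meta) != nrow(intensities)) {
    stop("metadata rows must match the number of spectra")
  }
  if (is.null(meta$group)) stop("meta must contain a 'group' column")
  if (is.null(classes)) classes <- unique(as.character(meta$group))
  bad <- setdiff(unique(as.character(meta$group)), classes)
  if (length(bad)) {
    stop("labels outside the declared class set: ", paste(bad, collapse = ", "))
  }
  meta$group <- factor(as.character(meta$group), levels = classes)
  structure(list(axis = axis, intensities = intensities, meta = meta,
                 classes = classes),
            class = "raman_dataset")
}

#' @export
print.raman_dataset <- function(x, ...) {
  tab <- table(x$meta$group)
  cat(sprintf("<raman_dataset> %d spectra x %d channels; groups: %s\n",
              nrow(x$intensities), length(x$axis),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Number of spectra in a dataset
#' @param dataset a `raman_dataset`.
#' @return Integer count.
#' @export
n_spectra <- function(dataset) nrow(dataset$intensities)

#' Subset a labeled dataset by row index
#'
#' @param dataset a `raman_dataset`.
#' @param idx integer index vector.
#' @return A `raman_dataset` with the selected spectra (class set retained).
#' @export
subset_dataset <- function(dataset, idx) {
  raman_dataset(dataset$axis, dataset$intensities[idx, , drop = FALSE],
                dataset$meta[idx, , drop = FALSE], classes = dataset$classes)
}

#' A library of named component spectra on a shared axis
#'
#' @param axis shared wavenumber axis (cm^-1).
#' @param components numeric matrix, one column per component,
#'   `length(axis)` rows, with unique column names.
#' @return Object of class `component_library`.
#' @export
component_library <- function(axis, components) {
  axis <- as.numeric(axis)
  components <- as.matrix(components)
  if (any(diff(axis) <= 0)) stop("library axis must be strictly increasing")
  if (nrow(components) != length(axis)) {
    stop("component rows must match axis length")
  }
  nm <- colnames(components)
  if (is.null(nm) || anyDuplicated(nm)) {
    stop("components must have unique names")
  }
  structure(list(axis = axis, components = components, names = nm),
            class = "component_library")
}

#' @export
print.component_library <- function(x, ...) {
  cat(sprintf("<component_library> %d components on %d-point axis: %s\n",
              ncol(x$components), length(x$axis),
              paste(x$names, collapse = ", ")))
  invisible(x)
}
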