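#' Read a spectrum from two-column delimited text
#'
#' Accepts whitespace- or comma-delimited numeric text with two columns
#' (wavenumber, intensity); lines starting with `#` and blank lines are
#' skipped. Descending axes (typical of instrument exports) are reordered
#' to ascending.
#'
#' @param path file path.
#' @return A [raman_spectrum].
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  parts <- strsplit(trimws(lines[keep]), "[[:space:],]+")
  n_fields <- lengths(parts)
  if (any(n_fields != 2)) {
    bad <- rows[which(n_fields != 2)[1]]
    stop(sprintf("%s: line %d does not have two columns", path, bad))
  }
  vals <- suppressWarnings(vapply(parts, function(p) as.numeric(p),
                                  numeric(2)))
  if (anyNA(vals)) {
    bad <- rows[which(colSums(is.na(vals)) > 0)[1]]
    stop(sprintf("%s: non-numeric value at line %d", path, bad))
  }
  if (ncol(vals) < 2) stop(path, ": a spectrum needs at least 2 points")
  raman_spectrum(vals[1, ], vals[2, ])
}

#' Write a spectrum as two-column text
#'
#' @param spectrum a [raman_spectrum].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  writeLines(sprintf("%.12g %.12g", spectrum$wavenumber, spectrum$intensity),
             path)
  invisible(path)
}

read_manifest <- function(manifest_path) {
  if (!file.exists(manifest_path)) stop("no such manifest: ", manifest_path)
  man <- read.table(manifest_path, header = TRUE, sep = "",
                    comment.char = "#", stringsAsFactors = FALSE)
  if (is.null(man$file)) stop("manifest must have a 'file' column")
  man
}

load_manifest_spectra <- function(man, dir) {
  paths <- file.path(dir, man$file)
  missing <- !file.exists(paths)
  if (any(missing)) {
    stop("manifest references missing file(s): ",
         paste(man$file[missing], collapse = ", "))
  }
  spectra <- lapply(paths, read_spectrum)
  axis <- spectra[[1]]$wavenumber
  for (i in seq_along(spectra)) {
    if (!same_axis(axis, spectra[[i]]$wavenumber)) {
      stop("axis mismatch in file: ", man$file[i])
    }
  }
  list(axis = axis,
       intensities = do.call(rbind, lapply(spectra, `[[`, "intensity")))
}

#' Read a spectral map from a manifest
#'
#' The manifest is a delimited table with a header naming at least
#' `file`, `x_um`, `y_um`; file paths are resolved relative to the
#' manifest's directory. All spectra must share one axis (pointwise
#' agreement within 1e-6 cm^-1).
#'
#' @param manifest_path path to the manifest table.
#' @param step grid step size in micrometres.
#' @return A [raman_map].
#' @export
read_map <- function(manifest_path, step = 1.5) {
  man <- read_manifest(manifest_path)
  if (is.null(man$x_um) || is.null(man$y_um)) {
    stop("map manifest needs 'x_um' and 'y_um' columns")
  }
  loaded <- load_manifest_spectra(man, dirname(manifest_path))
  raman_map(loaded$axis, loaded$intensities,
            data.frame(x = man$x_um, y = man$y_um), step = step)
}

#' Read a labeled dataset from a manifest
#'
#' As [read_map], but the manifest additionally carries `group`, `mouse`
#' and `eye` columns which become per-spectrum metadata.
#'
#' @param manifest_path path to the manifest table.
#' @return A [raman_dataset].
#' @export
read_dataset <- function(manifest_path) {
  man <- read_manifest(manifest_path)
  for (col in c("group", "mouse", "eye")) {
    if (is.null(man[[col]])) stop("dataset manifest needs a '", col, "' column")
  }
  loaded <- load_manifest_spectra(man, dirname(manifest_path))
  meta <- man[, setdiff(names(man), "file"), drop = FALSE]
  names(meta)[names(meta) == "x_um"] <- "x"
  names(meta)[names(meta) == "y_um"] <- "y"
  raman_dataset(loaded$axis, loaded$intensities, meta)
}

#' Write a labeled dataset as per-spectrum files plus a manifest
#'
#' @param dataset a [raman_dataset].
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- n_spectra(dataset)
  files <- sprintf("spectrum_%05d.txt", seq_len(n))
  for (i in seq_len(n)) {
    write_spectrum(get_spectrum(dataset, i), file.path(dir, files[i]))
  }
  man <- data.frame(file = files,
                    group = as.character(dataset$meta$group),
                    mouse = if (is.null(dataset$meta$mouse)) NA else dataset$meta$mouse,
                    eye = if (is.null(dataset$meta$eye)) NA else dataset$meta$eye,
                    x_um = if (is.null(dataset$meta$x)) 0 else dataset$meta$x,
                    y_um = if (is.null(dataset$meta$y)) 0 else dataset$meta$y)
  manifest <- file.path(dir, "manifest.txt")
  write.table(man, manifest, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Read a component library from a delimited table
#'
#' First column is the wavenumber axis; each further column is one named
#' component spectrum.
#'
#' @param path path to a delimited text table with a header row.
#' @param sep field separator (default: any whitespace).
#' @return A [component_library].
#' @export
read_component_library <- function(path, sep = "") {
  tab <- read.table(path, header = TRUE, sep = sep, comment.char = "#",
                    check.names = FALSE)
  if (ncol(tab) < 2) stop("library table needs a wavenumber column plus components")
  ord <- order(tab[[1]])
  component_library(tab[[1]][ord],
                    as.matrix(tab[ord, -1, drop = FALSE]))
}

#' Resample a spectrum onto a target axis by linear interpolation
#'
#' Interpolation is strictly within the source range; extrapolation is
#' refused.
#'
#' @param spectrum a [raman_spectrum].
#' @param target_axis strictly increasing wavenumbers within the source
#'   axis range.
#' @return A [raman_spectrum] on `target_axis`.
#' @export
resample <- function(spectrum, target_axis) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  target_axis <- as.numeric(target_axis)
  src <- spectrum$wavenumber
  if (min(target_axis) < min(src) - AXIS_TOL ||
      max(target_axis) > max(src) + AXIS_TOL) {
    stop("target axis extends beyond the source range; refusing to extrapolate")
  }
  out <- approx(src, spectrum$intensity, xout = target_axis, rule = 2)$y
  raman_spectrum(target_axis, out)
}
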