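#' Default unmixing axis: 1200-1714 cm^-1 at 1 cm^-1 increments
#'
#' @return Numeric axis of 515 points.
#' @export
unmixing_axis <- function() seq(1200, 1714, by = 1)

#' Build an NNLS design matrix from a component library
#'
#' Every component is linearly resampled onto the target axis; a
#' component whose axis does not span the target range is rejected by
#' name.
#'
#' @param library a [component_library].
#' @param target_axis fitting axis (default [unmixing_axis]).
#' @param intercept add a constant offset column (default `FALSE`;
#'   spectra are expected baseline-subtracted upstream).
#' @return Matrix with `length(target_axis)` rows and one named column
#'   per component, with the axis in attribute `"axis"`.
#' @export
build_design <- function(library, target_axis = unmixing_axis(),
                         intercept = FALSE) {
  stopifnot(inherits(library, "component_library"))
  rng <- range(target_axis)
  if (min(library$axis) > rng[1] + AXIS_TOL ||
      max(library$axis) < rng[2] - AXIS_TOL) {
    stop("library does not cover the target range ",
         rng[1], "-", rng[2], " cm-1")
  }
  cols <- lapply(library$names, function(nm) {
    resample(raman_spectrum(library$axis, library$components[, nm]),
             target_axis)$intensity
  })
  design <- do.call(cbind, cols)
  colnames(design) <- library$names
  if (intercept) design <- cbind(design, `(offset)` = 1)
  attr(design, "axis") <- as.numeric(target_axis)
  design
}

#' Non-negative least-squares fit of a spectrum against a design
#'
#' Solves `min ||y - D c||_2` subject to `c >= 0` with the Lawson-Hanson
#' active-set algorithm ([pracma::lsqnonneg], the algorithm behind
#' MATLAB's `lsqnonneg`).
#'
#' @param spectrum a [raman_spectrum] on the design axis, or a numeric
#'   vector of matching length.
#' @param design design matrix from [build_design].
#' @return Object of class `unmix_fit`: `coefficients` (named,
#'   non-negative) and `residual` (Euclidean norm of the misfit).
#' @export
nnls_fit <- function(spectrum, design) {
  y <- if (inherits(spectrum, "raman_spectrum")) {
    if (!same_axis(spectrum$wavenumber, attr(design, "axis"))) {
      stop("spectrum is not on the design axis; resample() it first")
    }
    spectrum$intensity
  } else as.numeric(spectrum)
  if (length(y) != nrow(design)) stop("spectrum length does not match design")
  if (!all(is.finite(y)) || !all(is.finite(design))) {
    stop("non-finite values in NNLS input")
  }
  fit <- pracma::lsqnonneg(design, y)
  coefs <- pmax(fit$x, 0)
  names(coefs) <- colnames(design)
  structure(list(coefficients = coefs,
                 residual = sqrt(max(fit$resid.norm, 0))),
            class = "unmix_fit")
}

#' @export
print.unmix_fit <- function(x, ...) {
  cat("<unmix_fit> residual", format(x$residual, digits = 4), "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Unmix every sample-average spectrum of a dataset
#'
#' Runs [nnls_fit] per sample (one average spectrum per group/mouse
#' combination), resampling each average onto the design axis first.
#'
#' @param averages a [raman_dataset] whose rows are per-sample average
#'   spectra with `group` (and typically `mouse`) metadata.
#' @param library a [component_library].
#' @param target_axis fitting axis (default [unmixing_axis]).
#' @return Data frame: `sample`, `group`, one coefficient column per
#'   component, and `residual`.
#' @export
fit_dataset <- function(averages, library, target_axis = unmixing_axis()) {
  stopifnot(inherits(averages, "raman_dataset"))
  design <- build_design(library, target_axis)
  n <- n_spectra(averages)
  rows <- lapply(seq_len(n), function(i) {
    sp <- resample(get_spectrum(averages, i), target_axis)
    fit <- nnls_fit(sp, design)
    out <- as.data.frame(as.list(fit$coefficients), check.names = FALSE)
    out$residual <- fit$residual
    out
  })
  meta <- averages$meta
  sample_id <- if (!is.null(meta$mouse)) as.character(meta$mouse) else
    paste0("sample_", seq_len(n))
  cbind(data.frame(sample = sample_id,
                   group = as.character(meta$group),
                   stringsAsFactors = FALSE),
        do.call(rbind, rows))
}

#' Compare one component's coefficients across injury groups
#'
#' Classic one-way ANOVA (between/within mean-square ratio, equal
#' variances) across all groups, plus pairwise Welch t-tests of every
#' other group against the reference (sham) group, reported both raw and
#' Holm-adjusted.
#'
#' @param results data frame from [fit_dataset].
#' @param component component (column) name to compare.
#' @param reference reference group; defaults to `"sham"` when present,
#'   else the first group.
#' @return Object of class `group_comparison`: `component`, `means`
#'   (named per-group), `f`, `p`, and `pairwise` (data frame: group,
#'   p_raw, p_holm).
#' @export
compare_groups <- function(results, component, reference = NULL) {
  if (is.null(results[[component]])) stop("no such component: ", component)
  g <- factor(results$group)
  if (nlevels(g) < 2) stop("need at least 2 groups to compare")
  if (any(table(g) < 2)) stop("every group needs at least 2 samples")
  x <- results[[component]]
  if (is.null(reference)) {
    reference <- if ("sham" %in% levels(g)) "sham" else levels(g)[1]
  }
  means <- tapply(x, g, mean)
  # degenerate-variance cases handled explicitly
  ssb <- sum(tapply(x, g, length) * (means - mean(x))^2)
  ssw <- sum((x - means[g])^2)
  if (ssb < .Machine$double.eps * sum(x^2 + 1)) {
    warning("no between-group variation; F reported as 0")
    f <- 0; p <- 1
  } else if (ssw < .Machine$double.eps * sum(x^2 + 1)) {
    warning("zero within-group variance; F reported as Inf")
    f <- Inf; p <- 0
  } else {
    av <- oneway.test(x ~ g, var.equal = TRUE)
    f <- unname(av$statistic); p <- unname(av$p.value)
  }
  others <- setdiff(levels(g), reference)
  p_raw <- vapply(others, function(lv) {
    # Welch is undefined when both samples are essentially constant
    tryCatch(t.test(x[g == lv], x[g == reference])$p.value,
             error = function(e) NA_real_)
  }, numeric(1))
  pairwise <- data.frame(group = others, p_raw = p_raw,
                         p_holm = p.adjust(p_raw, "holm"))
  structure(list(component = component, means = means, f = f, p = p,
                 reference = reference, pairwise = pairwise),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: F = %.3f, p = %.4g\n",
              x$component, x$f, x$p))
  cat("group means:", paste(sprintf("%s %.3g", names(x$means), x$means),
                            collapse = ", "), "\n")
  cat(sprintf("pairwise vs %s (Welch, raw / Holm):\n", x$reference))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}
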