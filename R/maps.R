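#' Band intensity within a wavenumber window
#'
#' The band statistic behind the ratio maps: by default the maximum
#' intensity within `center +/- half_width` (robust to small calibration
#' shifts); trapezoidal band area is available as an alternative.
#'
#' @param spectrum a [raman_spectrum].
#' @param center band centre (cm^-1).
#' @param half_width window half-width (cm^-1, default 8).
#' @param stat `"max"` (default) or `"area"`.
#' @return Band intensity (scalar).
#' @export
band_intensity <- function(spectrum, center, half_width = 8,
                           stat = c("max", "area")) {
  stat <- match.arg(stat)
  ax <- spectrum$wavenumber
  lo <- center - half_width
  hi <- center + half_width
  if (lo < min(ax) - AXIS_TOL || hi > max(ax) + AXIS_TOL) {
    stop("band window ", lo, "-", hi, " cm-1 lies outside the axis")
  }
  sel <- which(ax >= lo - AXIS_TOL & ax <= hi + AXIS_TOL)
  y <- spectrum$intensity[sel]
  if (stat == "max") max(y) else {
    x <- ax[sel]
    sum(diff(x) * (head(y, -1) + y[-1]) / 2)
  }
}

#' Band-ratio image of a spectral map
#'
#' Computes the per-position ratio of two band intensities (default
#' 1447 / 1266 cm^-1, the CH2-bending to CH-bending contrast that rises
#' when the 1266 cm^-1 band is suppressed after injury). Positions whose
#' denominator is at or below `eps` are flagged invalid, not dropped.
#' The map is expected baseline-subtracted.
#'
#' @param map a [raman_map].
#' @param numerator,denominator band centres (cm^-1).
#' @param half_width window half-width (cm^-1, default 8).
#' @param stat band statistic, see [band_intensity].
#' @param eps denominator validity threshold (default 1e-9).
#' @return Object of class `ratio_image`: `values` and `valid` vectors
#'   aligned to `positions`, plus a `matrix` form (y rows x x columns)
#'   when positions form a complete rectangular grid.
#' @export
ratio_map <- function(map, numerator = 1447, denominator = 1266,
                      half_width = 8, stat = c("max", "area"), eps = 1e-9) {
  stopifnot(inherits(map, "raman_map"))
  stat <- match.arg(stat)
  n <- nrow(map$intensities)
  num <- numeric(n)
  den <- numeric(n)
  for (i in seq_len(n)) {
    sp <- get_spectrum(map, i)
    num[i] <- band_intensity(sp, numerator, half_width, stat)
    den[i] <- band_intensity(sp, denominator, half_width, stat)
  }
  valid <- den > eps
  values <- ifelse(valid, num / den, NA_real_)
  xs <- sort(unique(map$positions$x))
  ys <- sort(unique(map$positions$y))
  mat <- NULL
  if (length(xs) * length(ys) == n) {
    mat <- matrix(NA_real_, length(ys), length(xs), dimnames = list(ys, xs))
    mat[cbind(match(map$positions$y, ys), match(map$positions$x, xs))] <- values
  }
  structure(list(values = values, valid = valid,
                 positions = map$positions, matrix = mat,
                 numerator = numerator, denominator = denominator,
                 half_width = half_width),
            class = "ratio_image")
}

#' @export
print.ratio_image <- function(x, ...) {
  cat(sprintf("<ratio_image> %d positions, %g / %g cm-1; mean ratio %.3f (%d invalid)\n",
              length(x$values), x$numerator, x$denominator,
              mean(x$values, na.rm = TRUE), sum(!x$valid)))
  invisible(x)
}

#' Default class palette (sham black, mTBI purple, sTBI orange)
#' @return Named vector of hex colors.
#' @export
default_palette <- function() {
  c(sham = "#000000", mTBI = "#9467BD", sTBI = "#FF7F0E")
}

# Proportion-weighted RGB mix of class colors for one neuron.
mix_colors <- function(props, palette) {
  rgbm <- col2rgb(palette)
  mixed <- rgbm %*% props
  rgb(mixed[1], mixed[2], mixed[3], maxColorValue = 255)
}

#' Render a SOM hit map with class color mixing
#'
#' Each neuron is drawn as a hexagon colored by the hit-proportion-
#' weighted mix of its classes' colors; neurons without hits are neutral
#' grey. Returns the per-neuron colors (for programmatic checks) together
#' with a ggplot of the tiled map.
#'
#' @param grid a `som_grid` with class hits.
#' @param palette named vector of colors, one per class; classes missing
#'   from the palette fall back to [default_palette] order.
#' @param empty_color fill for zero-hit neurons.
#' @return Object of class `som_hitmap`: `colors` (per neuron),
#'   `proportions` (neurons x classes), and `plot` (ggplot).
#' @export
render_hitmap <- function(grid, palette = default_palette(),
                          empty_color = "#BFBFBF") {
  if (is.null(grid$class_hits)) stop("class hits not populated; run accumulate_hits first")
  classes <- grid$classes
  pal <- palette[classes]
  if (anyNA(pal)) {
    fallback <- rep_len(c("#000000", "#9467BD", "#FF7F0E", "#1F77B4",
                          "#2CA02C", "#D62728"), length(classes))
    pal[is.na(pal)] <- fallback[is.na(pal)]
    names(pal) <- classes
  }
  hits <- grid$class_hits
  totals <- rowSums(hits)
  props <- hits
  props[totals > 0, ] <- hits[totals > 0, , drop = FALSE] / totals[totals > 0]
  colors <- vapply(seq_len(nrow(hits)), function(i) {
    if (totals[i] == 0) empty_color else mix_colors(props[i, ], pal)
  }, character(1))

  # pointy-top hexagon outline scaled to the unit hex layout
  r <- 1 / sqrt(3)
  ang <- pi / 6 + seq(0, 5) * pi / 3
  hex_x <- r * cos(ang)
  hex_y <- r * sin(ang)
  k <- nrow(grid$hex)
  poly <- data.frame(
    id = rep(seq_len(k), each = 6),
    x = rep(grid$hex$x, each = 6) + rep(hex_x, k),
    y = rep(grid$hex$y, each = 6) + rep(hex_y, k),
    fill = rep(colors, each = 6))
  plt <- ggplot2::ggplot(poly, ggplot2::aes(x = x, y = y, group = id)) +
    ggplot2::geom_polygon(fill = poly$fill, color = "white", linewidth = 0.2) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
  structure(list(colors = colors, proportions = props, palette = pal,
                 plot = plt),
            class = "som_hitmap")
}

#' @export
print.som_hitmap <- function(x, ...) {
  cat(sprintf("<som_hitmap> %d neurons; palette: %s\n", length(x$colors),
              paste(sprintf("%s=%s", names(x$palette), x$palette),
                    collapse = ", ")))
  invisible(x)
}
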