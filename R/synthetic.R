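#' Specify one Raman band
#'
#' @param center band centre (cm^-1).
#' @param fwhm full width at half maximum (cm^-1), > 0.
#' @param amplitude peak amplitude (arbitrary intensity units), >= 0.
#' @param shape `"gaussian"` or `"lorentzian"`.
#' @return A `band_spec` list.
#' @export
band_spec <- function(center, fwhm, amplitude, shape = c("gaussian", "lorentzian")) {
  shape <- match.arg(shape)
  if (fwhm <= 0) stop("fwhm must be > 0")
  if (amplitude < 0) stop("amplitude must be >= 0")
  structure(list(center = center, fwhm = fwhm, amplitude = amplitude,
                 shape = shape), class = "band_spec")
}

band_profile <- function(band, axis) {
  if (band$shape == "gaussian") {
    band$amplitude * exp(-4 * log(2) * (axis - band$center)^2 / band$fwhm^2)
  } else {
    hw2 <- (band$fwhm / 2)^2
    band$amplitude * hw2 / ((axis - band$center)^2 + hw2)
  }
}

#' Group-dependent band effect
#'
#' Multiplicative intensity changes applied to selected bands for one
#' injury state, plus the animal-to-animal heterogeneity of those changes
#' (coefficient of variation of per-mouse lognormal multipliers).
#'
#' @param group group label (e.g. `"sham"`, `"mTBI"`, `"sTBI"`).
#' @param band_multipliers named numeric vector; names are band centres
#'   (cm^-1), values are positive multiplicative factors. The control
#'   (sham) group uses an empty vector: all bands at factor 1.
#' @param heterogeneity coefficient of variation (>= 0) of the per-mouse
#'   random multipliers.
#' @return A `group_effect` list.
#' @export
group_effect <- function(group, band_multipliers = numeric(0),
                         heterogeneity = 0.05) {
  if (length(band_multipliers) && any(band_multipliers <= 0)) {
    stop("band multipliers must be > 0")
  }
  if (heterogeneity < 0) stop("heterogeneity must be >= 0")
  structure(list(group = group, band_multipliers = band_multipliers,
                 heterogeneity = heterogeneity), class = "group_effect")
}

#' Default band table for neural tissue
#'
#' Bands at 850, 1003 (sharp phenylalanine ring-breathing, Lorentzian),
#' 1098, 1266, 1337, 1447 and 1660 cm^-1 with amplitudes chosen to mimic a
#' typical fingerprint-region tissue spectrum (CH2 bending at 1447 cm^-1
#' strongest).
#'
#' @return List of [band_spec] objects.
#' @export
default_bands <- function() {
  list(
    band_spec(850, 18, 0.50),
    band_spec(1003, 10, 0.90, shape = "lorentzian"),
    band_spec(1098, 22, 0.45),
    band_spec(1266, 26, 0.70),
    band_spec(1337, 24, 0.80),
    band_spec(1447, 22, 1.00),
    band_spec(1660, 30, 0.95)
  )
}

#' Default injury-state effects
#'
#' Severe TBI raises the bands at 850, 1098 and 1337 cm^-1 (factor 1.15)
#' and lowers 1003, 1266 and 1660 cm^-1 (factor 0.85); moderate TBI applies
#' the same directions at smaller magnitude (1.07 / 0.93) with double the
#' animal-to-animal heterogeneity (CV 0.10 vs 0.05), making it the hardest
#' group to separate from sham. Sham applies no band change.
#'
#' @return Named list of [group_effect] objects (sham, mTBI, sTBI).
#' @export
default_effects <- function() {
  up <- c(`850` = 1, `1098` = 1, `1337` = 1)
  down <- c(`1003` = 1, `1266` = 1, `1660` = 1)
  list(
    sham = group_effect("sham", numeric(0), heterogeneity = 0.05),
    mTBI = group_effect("mTBI", c(up * 1.07, down * 0.93), heterogeneity = 0.10),
    sTBI = group_effect("sTBI", c(up * 1.15, down * 0.85), heterogeneity = 0.05)
  )
}

#' Simulation configuration
#'
#' Defaults reproduce the retina study design: 3 injury states x 6 mice x
#' 2 eyes, one 20 x 20 map (400 spectra) per eye at 1.5 um steps, on a
#' 605-1715 cm^-1 axis at 1 cm^-1 increments.
#'
#' @param mice_per_group animals per injury state.
#' @param eyes_per_mouse tissue samples (maps) per animal; 2 for retina
#'   (both eyes), 1 for brain (contusion core).
#' @param grid_side map edge length in points (map is `grid_side^2` spectra).
#' @param axis_start,axis_stop,axis_step wavenumber axis (cm^-1).
#' @param step_um spatial step between map points (micrometres).
#' @param bands list of [band_spec].
#' @param effects named list of [group_effect]; the names define the groups.
#' @param baseline_scale amplitude of the smooth autofluorescence baseline
#'   (same units as band amplitudes).
#' @param noise_sigma standard deviation of additive Gaussian noise.
#' @param cosmic_ray_rate expected number of single-channel spikes per map.
#' @param seed integer seed governing all generator randomness.
#' @return A `sim_config` list.
#' @export
sim_config <- function(mice_per_group = 6, eyes_per_mouse = 2,
                       grid_side = 20,
                       axis_start = 605, axis_stop = 1715, axis_step = 1,
                       step_um = 1.5,
                       bands = default_bands(), effects = default_effects(),
                       baseline_scale = 0.5, noise_sigma = 0.05,
                       cosmic_ray_rate = 5, seed = 1) {
  stopifnot(mice_per_group >= 1, eyes_per_mouse >= 1, grid_side >= 1,
            axis_step > 0, axis_stop > axis_start,
            baseline_scale >= 0, noise_sigma >= 0, cosmic_ray_rate >= 0)
  if (is.null(names(effects)) || anyDuplicated(names(effects))) {
    stop("effects must be a uniquely named list of group_effect objects")
  }
  axis <- seq(axis_start, axis_stop, by = axis_step)
  for (b in bands) {
    if (b$center < axis_start || b$center > axis_stop) {
      stop("band center ", b$center, " lies outside the axis range")
    }
  }
  structure(list(mice_per_group = mice_per_group,
                 eyes_per_mouse = eyes_per_mouse, grid_side = grid_side,
                 axis = axis, step_um = step_um,
                 bands = bands, effects = effects,
                 baseline_scale = baseline_scale, noise_sigma = noise_sigma,
                 cosmic_ray_rate = cosmic_ray_rate, seed = seed),
            class = "sim_config")
}

#' Brain-tissue simulation preset
#'
#' One contusion-core map per animal (instead of two eyes) and a stronger
#' fluorescence baseline, reflecting haemoglobin absorption at the injury
#' site. With defaults: 3 x 6 x 1 x 400 = 7200 spectra.
#'
#' @param ... overrides passed to [sim_config].
#' @return A `sim_config`.
#' @export
sim_config_brain <- function(...) {
  args <- list(...)
  defaults <- list(eyes_per_mouse = 1, baseline_scale = 1.0)
  do.call(sim_config, utils::modifyList(defaults, args))
}

#' Sum band profiles into a clean component spectrum
#'
#' @param bands list of [band_spec]; every centre must lie within the axis.
#' @param axis strictly increasing wavenumber axis.
#' @param multipliers optional named vector of per-band-centre factors.
#' @return A [raman_spectrum]; all intensities >= 0.
#' @export
make_component_spectrum <- function(bands, axis, multipliers = numeric(0)) {
  axis <- as.numeric(axis)
  if (any(diff(axis) <= 0)) stop("axis must be strictly increasing")
  y <- numeric(length(axis))
  for (b in bands) {
    if (b$center < min(axis) || b$center > max(axis)) {
      stop("band center ", b$center, " outside axis range")
    }
    m <- multipliers[as.character(b$center)]
    if (is.na(m) || !length(m)) m <- 1
    y <- y + m * band_profile(b, axis)
  }
  raman_spectrum(axis, y)
}

# Per-mouse lognormal band multipliers with mean 1 and CV = heterogeneity,
# one draw per band (drawn once per animal so both eyes share them).
draw_mouse_factors <- function(effect, bands) {
  h <- effect$heterogeneity
  centers <- vapply(bands, `[[`, numeric(1), "center")
  if (h == 0) {
    out <- rep(1, length(bands))
  } else {
    s <- sqrt(log(1 + h^2))
    out <- rlnorm(length(bands), meanlog = -s^2 / 2, sdlog = s)
  }
  names(out) <- as.character(centers)
  out
}

clean_signal <- function(config, group, mouse_factors = NULL) {
  eff <- config$effects[[group]]
  if (is.null(eff)) stop("unknown group: ", group)
  mult <- vapply(config$bands, function(b) {
    cc <- as.character(b$center)
    g <- eff$band_multipliers[cc]
    if (is.na(g) || !length(g)) g <- 1
    m <- if (is.null(mouse_factors)) 1 else mouse_factors[cc]
    if (is.na(m) || !length(m)) m <- 1
    g * m
  }, numeric(1))
  y <- numeric(length(config$axis))
  for (i in seq_along(config$bands)) {
    y <- y + mult[i] * band_profile(config$bands[[i]], config$axis)
  }
  y
}

# Random positive cubic baseline emulating broad autofluorescence.
random_baseline <- function(config) {
  if (config$baseline_scale == 0) return(numeric(length(config$axis)))
  u <- (config$axis - min(config$axis)) / diff(range(config$axis))
  co <- rnorm(4)
  raw <- co[1] + co[2] * u + co[3] * u^2 + co[4] * u^3
  v <- raw - min(raw)
  if (max(v) > 0) v <- v / max(v)
  config$baseline_scale * (0.2 + v)
}

add_baseline_noise <- function(clean, config) {
  y <- clean + random_baseline(config)
  if (config$noise_sigma > 0) {
    y <- y + rnorm(length(y), sd = config$noise_sigma)
  }
  pmax(y, 0)
}

#' Generate one synthetic spectrum
#'
#' Clean band sum (group effect x per-mouse factors), plus a random smooth
#' positive cubic baseline scaled by `baseline_scale`, plus zero-mean
#' Gaussian noise; intensities clipped at zero. Uses the current RNG
#' state: seed externally (or via [generate_dataset]) for reproducibility.
#'
#' @param group group label, must have a [group_effect] in `config`.
#' @param mouse_factors per-mouse multiplier draw (named by band centre),
#'   as produced once per animal; `NULL` for factors of 1.
#' @param config a [sim_config].
#' @return A [raman_spectrum].
#' @export
generate_spectrum <- function(group, mouse_factors = NULL, config = sim_config()) {
  clean <- clean_signal(config, group, mouse_factors)
  raman_spectrum(config$axis, add_baseline_noise(clean, config))
}

#' Generate one synthetic spectral map
#'
#' `grid_side^2` spectra at positions `(i * step_um, j * step_um)`; a
#' Poisson(`cosmic_ray_rate`) number of single-channel cosmic-ray spikes
#' is injected at random (spectrum, channel) locations with amplitude
#' 20 x the map's 95th intensity percentile, and every spike is recorded
#' in the map's provenance for downstream oracles.
#'
#' @inheritParams generate_spectrum
#' @param mouse,eye identifiers stored in provenance.
#' @param seed optional seed; `NULL` continues from the current RNG state.
#' @return A [raman_map] with `provenance$spikes` (data frame: index,
#'   x, y, channel, wavenumber, amplitude).
#' @export
generate_map <- function(group, mouse = 1, eye = "ipsi", config = sim_config(),
                         mouse_factors = NULL, seed = NULL) {
  if (!is.null(seed)) return(with_seed(seed, generate_map(group, mouse, eye,
                                                          config, mouse_factors)))
  if (is.null(config$effects[[group]])) stop("unknown group: ", group)
  n_side <- config$grid_side
  n <- n_side^2
  clean <- clean_signal(config, group, mouse_factors)
  intens <- matrix(0, n, length(config$axis))
  for (i in seq_len(n)) {
    intens[i, ] <- add_baseline_noise(clean, config)
  }
  pos <- expand.grid(ix = seq_len(n_side) - 1, iy = seq_len(n_side) - 1)
  positions <- data.frame(x = pos$ix * config$step_um,
                          y = pos$iy * config$step_um)
  n_spikes <- rpois(1, config$cosmic_ray_rate)
  spikes <- data.frame(index = integer(0), x = numeric(0), y = numeric(0),
                       channel = integer(0), wavenumber = numeric(0),
                       amplitude = numeric(0))
  if (n_spikes > 0) {
    amp <- 20 * quantile(intens, 0.95, names = FALSE)
    idx <- sample.int(n, n_spikes, replace = TRUE)
    chan <- sample.int(length(config$axis), n_spikes, replace = TRUE)
    for (k in seq_len(n_spikes)) {
      intens[idx[k], chan[k]] <- intens[idx[k], chan[k]] + amp
    }
    spikes <- data.frame(index = idx, x = positions$x[idx],
                         y = positions$y[idx], channel = chan,
                         wavenumber = config$axis[chan],
                         amplitude = rep(amp, n_spikes))
  }
  raman_map(config$axis, intens, positions, step = config$step_um,
            provenance = list(group = group, mouse = mouse, eye = eye,
                              spikes = spikes))
}

#' Generate all maps of the study design
#'
#' One map per (group, mouse, eye); per-mouse band factors are drawn once
#' per animal so that both eyes of one mouse share its heterogeneity draw.
#'
#' @param config a [sim_config].
#' @return List of [raman_map] objects with group/mouse/eye provenance.
#' @export
generate_maps <- function(config = sim_config()) {
  with_seed(config$seed, {
    eyes <- if (config$eyes_per_mouse == 2) c("ipsi", "contra") else
      paste0("s", seq_len(config$eyes_per_mouse))
    maps <- list()
    for (g in names(config$effects)) {
      for (m in seq_len(config$mice_per_group)) {
        mf <- draw_mouse_factors(config$effects[[g]], config$bands)
        for (e in eyes) {
          maps[[length(maps) + 1]] <-
            generate_map(g, mouse = paste0(g, "_m", m), eye = e,
                         config = config, mouse_factors = mf)
        }
      }
    }
    maps
  })
}

#' Flatten a list of maps into a labeled dataset
#'
#' @param maps list of [raman_map] with group/mouse/eye provenance.
#' @param classes declared class set (default: groups in order encountered).
#' @return A [raman_dataset] whose metadata includes map coordinates.
#' @export
flatten_maps <- function(maps, classes = NULL) {
  axis <- maps[[1]]$axis
  for (m in maps) {
    if (!same_axis(axis, m$axis)) stop("maps do not share a common axis")
  }
  intens <- do.call(rbind, lapply(maps, `[[`, "intensities"))
  meta <- do.call(rbind, lapply(maps, function(m) {
    data.frame(group = m$provenance$group, mouse = m$provenance$mouse,
               eye = m$provenance$eye, x = m$positions$x, y = m$positions$y)
  }))
  raman_dataset(axis, intens, meta, classes = classes)
}

#' Generate the full synthetic labeled dataset
#'
#' With retina defaults this is 3 groups x 6 mice x 2 eyes x 400 spectra =
#' 14,400 spectra (4800 per group).
#'
#' @param config a [sim_config].
#' @return A [raman_dataset]; the injected-spike records of every map are
#'   attached as attribute `"spikes"`.
#' @export
generate_dataset <- function(config = sim_config()) {
  maps <- generate_maps(config)
  ds <- flatten_maps(maps, classes = names(config$effects))
  spikes <- do.call(rbind, lapply(seq_along(maps), function(i) {
    s <- maps[[i]]$provenance$spikes
    if (nrow(s)) cbind(map = i, s) else NULL
  }))
  attr(ds, "spikes") <- spikes
  ds
}

#' Synthetic brain-lipid component library
#'
#' Stand-in component spectra over 1150-1750 cm^-1 emulating the spectral
#' character of a brain lipid/protein fitting library: a cardiolipin-like
#' component with strong 1266 and 1660 cm^-1 bands (unsaturated acyl
#' chains), plus cholesterol-, sphingomyelin- and cytochrome-c-like
#' profiles. These are synthetic shapes for testing and demonstration,
#' not measured spectra; real libraries load via
#' [read_component_library].
#'
#' @param axis wavenumber axis (default 1150-1750 cm^-1 at 1 cm^-1).
#' @return A [component_library].
#' @export
synthetic_component_library <- function(axis = seq(1150, 1750, by = 1)) {
  comp <- function(bands) make_component_spectrum(bands, axis)$intensity
  components <- cbind(
    cardiolipin = comp(list(band_spec(1266, 24, 0.90),
                            band_spec(1302, 20, 0.40),
                            band_spec(1440, 22, 0.65),
                            band_spec(1660, 26, 1.00))),
    cholesterol = comp(list(band_spec(1300, 28, 0.55),
                            band_spec(1440, 20, 1.00),
                            band_spec(1672, 24, 0.35))),
    sphingomyelin = comp(list(band_spec(1296, 22, 0.60),
                              band_spec(1437, 22, 1.00),
                              band_spec(1654, 30, 0.45))),
    cytochrome_c = comp(list(band_spec(1313, 18, 0.60),
                             band_spec(1371, 16, 0.45),
                             band_spec(1585, 18, 0.80),
                             band_spec(1638, 16, 0.50)))
  )
  component_library(axis, components)
}
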