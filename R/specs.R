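#' Describe a synthetic cell population
#'
#' Parameters of the simulated population of adherent single cells imaged by
#' timelapse QPI. Defaults emulate a 96-well-plate assay imaged every 20
#' minutes for 48 hours, with initial dry masses of a few hundred picograms.
#'
#' @param n_cells Number of cells (>= 1).
#' @param initial_mass_mix List of mixture components for the initial dry
#'   mass. Each component is a list with fields `weight`, `mean_pg`, `sd_pg`,
#'   and optionally `dist` ("lognormal", the default, or "normal"), `sgr`
#'   (the component's drug-free specific growth rate in 1/h; defaults to
#'   `sgr_control`) and `responsive` (logical; `FALSE` marks a contaminating
#'   subpopulation that ignores the drug entirely). Weights must sum to 1.
#' @param sgr_control Drug-free specific growth rate, 1/h.
#' @param sgr_sd Between-cell standard deviation of the specific growth
#'   rate, 1/h (static biological heterogeneity).
#' @param sgr_wander_sd Stationary standard deviation of the within-cell
#'   temporal growth-rate fluctuation, 1/h. Single-cell growth rates are
#'   not constant over two days (cell-cycle and state changes); the
#'   fluctuation follows an Ornstein-Uhlenbeck process with correlation
#'   time `sgr_wander_tau`. Set to 0 for exactly constant per-cell rates.
#' @param sgr_wander_tau Correlation time of the rate fluctuation, hours.
#' @param noise_sd_mass Additive per-frame mass measurement noise, pg.
#' @param frame_interval Imaging cadence in hours (default 1/3 h = 20 min).
#' @param duration Total imaging duration, hours.
#' @param growth_model "exponential" (mass grows as exp(g t)) or "linear"
#'   (mass grows as m0 (1 + g t)); the linear model makes the straight-line
#'   SGR estimator exact and is used for exactness tests.
#' @param motion_step Random-walk step size, um per frame.
#' @param motion_bound Half-width of the reflecting box that bounds each
#'   cell's walk around its starting position, um.
#' @param field_um Side of the square field the cells occupy, um.
#' @param seed Integer seed making the simulation reproducible.
#' @return A `population_spec` object.
#' @export
population_spec <- function(n_cells = 100L,
                            initial_mass_mix = list(list(weight = 1, mean_pg = 300, sd_pg = 100)),
                            sgr_control = 0.02,
                            sgr_sd = 0.005,
                            sgr_wander_sd = 0.005,
                            sgr_wander_tau = 8,
                            noise_sd_mass = 2,
                            frame_interval = 1 / 3,
                            duration = 48,
                            growth_model = c("exponential", "linear"),
                            motion_step = 1,
                            motion_bound = 10,
                            field_um = 300,
                            seed = NULL) {
  growth_model <- match.arg(growth_model)
  n_cells <- as.integer(n_cells)
  if (n_cells < 1L) stop("n_cells must be >= 1")
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  if (duration <= 0) stop("duration must be > 0")
  if (noise_sd_mass < 0 || sgr_sd < 0 || sgr_wander_sd < 0) {
    stop("standard deviations must be >= 0")
  }
  if (sgr_wander_tau <= 0) stop("sgr_wander_tau must be > 0")
  w <- vapply(initial_mass_mix, function(cmp) cmp$weight, numeric(1))
  if (abs(sum(w) - 1) > 1e-8) stop("initial_mass_mix weights must sum to 1")
  for (cmp in initial_mass_mix) {
    if (cmp$mean_pg <= 0 || cmp$sd_pg < 0) stop("invalid mass component")
  }
  structure(list(n_cells = n_cells, initial_mass_mix = initial_mass_mix,
                 sgr_control = sgr_control, sgr_sd = sgr_sd,
                 sgr_wander_sd = sgr_wander_sd,
                 sgr_wander_tau = sgr_wander_tau,
                 noise_sd_mass = noise_sd_mass,
                 frame_interval = frame_interval, duration = duration,
                 growth_model = growth_model, motion_step = motion_step,
                 motion_bound = motion_bound, field_um = field_um,
                 seed = seed),
            class = "population_spec")
}

#' Describe a drug's generative dose effect
#'
#' Generative counterpart of the Hill dose-response model: the mean specific
#' growth rate of responsive cells at concentration C is
#' `Emax + (E0 - Emax) / (1 + (C/EC50)^HS)`, reached with an exponential
#' onset of timescale `response_delay_tau`. A `resistant_fraction` of cells
#' keeps growing at `resistant_sgr` regardless of dose.
#'
#' @param e0 Low-dose (control-side) SGR asymptote, 1/h.
#' @param emax High-dose SGR asymptote, 1/h.
#' @param ec50 Half-effect concentration (any unit, used consistently).
#' @param hs Hill slope (> 0).
#' @param response_delay_tau Exponential onset timescale, hours (0 = drug
#'   acts instantaneously).
#' @param resistant_fraction Proportion of drug-insensitive cells in [0, 1].
#' @param resistant_sgr SGR of resistant cells, 1/h.
#' @return A `drug_effect_spec` object.
#' @export
drug_effect_spec <- function(e0 = 0.02, emax = -0.01, ec50 = 1, hs = 1,
                             response_delay_tau = 0,
                             resistant_fraction = 0, resistant_sgr = 0.02) {
  if (ec50 <= 0) stop("ec50 must be > 0")
  if (hs <= 0) stop("hs must be > 0")
  if (response_delay_tau < 0) stop("response_delay_tau must be >= 0")
  if (resistant_fraction < 0 || resistant_fraction > 1) {
    stop("resistant_fraction must be in [0, 1]")
  }
  structure(list(e0 = e0, emax = emax, ec50 = ec50, hs = hs,
                 response_delay_tau = response_delay_tau,
                 resistant_fraction = resistant_fraction,
                 resistant_sgr = resistant_sgr),
            class = "drug_effect_spec")
}

#' Describe a synthetic imaging scene
#'
#' Geometry and phase-rendering parameters for turning simulated mass tracks
#' into quantitative phase frames. The defaults match a 10x / 0.25 NA DPC
#' system scale (0.6 um pixels, 525 nm illumination).
#'
#' @param image_shape Integer vector (rows, cols) in pixels; a scalar is
#'   recycled to a square frame.
#' @param pixel_size Pixel pitch, um.
#' @param wavelength Illumination wavelength, nm.
#' @param cell_radius_mean,cell_radius_sd Cell radius distribution, um.
#' @param phase_profile "uniform-disk" or "gaussian-blob" per-cell phase
#'   footprint.
#' @param background_phase_sd Additive background phase noise, radians.
#' @return A `scene_spec` object.
#' @export
scene_spec <- function(image_shape = c(256L, 256L), pixel_size = 0.6,
                       wavelength = 525, cell_radius_mean = 8,
                       cell_radius_sd = 1,
                       phase_profile = c("uniform-disk", "gaussian-blob"),
                       background_phase_sd = 0) {
  phase_profile <- match.arg(phase_profile)
  image_shape <- as.integer(rep(image_shape, length.out = 2L))
  if (any(image_shape < 8L)) stop("image_shape too small")
  if (pixel_size <= 0 || wavelength <= 0) stop("pixel_size and wavelength must be > 0")
  if (cell_radius_mean <= 0 || cell_radius_sd < 0) stop("invalid cell radius")
  if (background_phase_sd < 0) stop("background_phase_sd must be >= 0")
  structure(list(image_shape = image_shape, pixel_size = pixel_size,
                 wavelength = wavelength, cell_radius_mean = cell_radius_mean,
                 cell_radius_sd = cell_radius_sd, phase_profile = phase_profile,
                 background_phase_sd = background_phase_sd),
            class = "scene_spec")
}

#' Describe the DPC optical system
#'
#' @param numerical_aperture Objective NA (0 < NA < 1); the LED half-circle
#'   illumination is treated as matched to the objective NA.
#' @param wavelength Illumination wavelength, nm.
#' @param pixel_size Object-space pixel pitch, um.
#' @param regularization_beta Tikhonov regularization parameter (> 0).
#' @return An `optics_spec` object.
#' @export
optics_spec <- function(numerical_aperture = 0.25, wavelength = 525,
                        pixel_size = 0.6, regularization_beta = 1e-3) {
  if (numerical_aperture <= 0 || numerical_aperture >= 1) {
    stop("numerical_aperture must be in (0, 1)")
  }
  if (wavelength <= 0 || pixel_size <= 0) stop("wavelength and pixel_size must be > 0")
  if (regularization_beta <= 0) stop("regularization_beta must be > 0")
  structure(list(numerical_aperture = numerical_aperture,
                 wavelength = wavelength, pixel_size = pixel_size,
                 regularization_beta = regularization_beta),
            class = "optics_spec")
}

#' Constants converting integrated phase to dry mass
#'
#' Dry mass is `(lambda / (2 pi alpha)) * sum(phase) * pixel_area`, using the
#' specific refractive increment alpha relating refractive-index change to
#' biomolecule concentration.
#'
#' @param alpha Specific refractive increment, m^3/kg (default 1.8e-4).
#' @param wavelength Wavelength, nm.
#' @param pixel_area Pixel area, um^2.
#' @return A `mass_constants` object.
#' @export
mass_constants <- function(alpha = 1.8e-4, wavelength = 525,
                           pixel_area = 0.36) {
  if (alpha <= 0 || wavelength <= 0 || pixel_area <= 0) {
    stop("all mass constants must be strictly positive")
  }
  structure(list(alpha = alpha, wavelength = wavelength,
                 pixel_area = pixel_area),
            class = "mass_constants")
}

#' Cost model for frame-to-frame cell linking
#'
#' Link cost between an observation pair is
#' `spatial_weight * |dxy|^2 + mass_weight * dm^2`; candidate links farther
#' than `max_link_distance` or with a relative mass jump above
#' `max_mass_jump` are forbidden (track birth/death instead). `NULL` weights
#' are replaced at link time by the reciprocal of the corresponding
#' population variance, so position and mass contribute comparably.
#'
#' @param spatial_weight Weight on squared displacement, 1/um^2, or NULL.
#' @param mass_weight Weight on squared mass change, 1/pg^2, or NULL.
#' @param max_link_distance Gate on displacement, um.
#' @param max_mass_jump Gate on |dm| / max(m), fraction.
#' @param max_gap_frames Frames a track may skip (0 disables gap closing).
#' @return A `link_cost` object.
#' @export
link_cost <- function(spatial_weight = NULL, mass_weight = NULL,
                      max_link_distance = 20, max_mass_jump = 0.5,
                      max_gap_frames = 0L) {
  if (!is.null(spatial_weight) && spatial_weight < 0) stop("weights must be >= 0")
  if (!is.null(mass_weight) && mass_weight < 0) stop("weights must be >= 0")
  if (!is.null(spatial_weight) && !is.null(mass_weight) &&
      spatial_weight == 0 && mass_weight == 0) {
    stop("spatial_weight and mass_weight cannot both be zero")
  }
  if (max_link_distance <= 0) stop("max_link_distance must be > 0")
  structure(list(spatial_weight = spatial_weight, mass_weight = mass_weight,
                 max_link_distance = max_link_distance,
                 max_mass_jump = max_mass_jump,
                 max_gap_frames = as.integer(max_gap_frames)),
            class = "link_cost")
}

#' Kernel density estimation parameters for SGR distributions
#'
#' @param bandwidth Gaussian kernel bandwidth in 1/h (default 0.0025).
#' @param n_grid Number of grid points.
#' @param pad_bw Grid padding beyond the pooled sample range, in bandwidths.
#' @return A `kde_params` object.
#' @export
kde_params <- function(bandwidth = 0.0025, n_grid = 512L, pad_bw = 4) {
  if (bandwidth <= 0) stop("bandwidth must be > 0")
  structure(list(bandwidth = bandwidth, n_grid = as.integer(n_grid),
                 pad_bw = pad_bw),
            class = "kde_params")
}

#' Initial-mass filter for contaminated samples
#'
#' @param threshold Mass threshold, pg (>= 0; 0 with "keep_above" is the
#'   identity filter).
#' @param side "keep_above" (default; retains the large, growing cells) or
#'   "keep_below".
#' @return A `mass_filter` object.
#' @export
mass_filter <- function(threshold, side = c("keep_above", "keep_below")) {
  side <- match.arg(side)
  if (threshold < 0) stop("threshold must be >= 0")
  structure(list(threshold = threshold, side = side), class = "mass_filter")
}
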