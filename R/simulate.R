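#' Simulate single-cell dry-mass tracks under a drug dose
#'
#' Generates the mass trajectory of every cell in a population dosed at a
#' given concentration. Each cell draws a drug-free growth rate around its
#' component's control SGR; responsive, non-resistant cells shift toward the
#' Hill-model mean at the dose with an exponential onset of timescale
#' `tau = response_delay_tau` (the accumulated exponent uses the integral of
#' the instantaneous rate, so for tau = 0 the target rate applies from
#' t = 0). Per-frame additive Gaussian mass noise emulates QPI measurement
#' noise; cells perform a bounded Gaussian random walk around grid-assigned
#' starting positions.
#'
#' @param pop A [population_spec()].
#' @param drug A [drug_effect_spec()], or NULL for an undosed population.
#' @param dose Drug concentration (>= 0, same units as `drug$ec50`).
#' @param well,drug_name Condition labels attached to every track.
#' @return A `data.frame` of class `cell_tracks` with one row per cell per
#'   frame: `cell_id`, `frame` (1-based), `t_h`, `x_um`, `y_um`, `mass_pg`
#'   (noisy observation), `mass_true_pg`, `sgr_true` (the cell's asymptotic
#'   rate at this dose, 1/h), `subpopulation` ("responsive", "resistant" or
#'   "non_responsive"), `well`, `drug`, `dose`. The frame interval (h) is
#'   attached as attribute `frame_interval`.
#' @export
simulate_tracks <- function(pop, drug = NULL, dose = 0, well = "A1",
                            drug_name = if (is.null(drug)) "vehicle" else "drug") {
  stopifnot(inherits(pop, "population_spec"))
  if (!is.null(drug)) stopifnot(inherits(drug, "drug_effect_spec"))
  if (dose < 0) stop("dose must be >= 0")
  n_frames <- floor(pop$duration / pop$frame_interval) + 1L
  if (n_frames < 2L) stop("duration must cover at least two frames")

  with_seed(pop$seed, {
    n <- pop$n_cells
    # component assignment and initial masses
    w <- vapply(pop$initial_mass_mix, `[[`, numeric(1), "weight")
    comp <- sample.int(length(w), n, replace = TRUE, prob = w)
    m0 <- numeric(n)
    g_ctrl <- numeric(n)
    responsive <- logical(n)
    for (k in seq_along(pop$initial_mass_mix)) {
      cmp <- pop$initial_mass_mix[[k]]
      idx <- which(comp == k)
      if (!length(idx)) next
      dist <- cmp$dist %||% "lognormal"
      if (dist == "lognormal") {
        # parameterized by the component's arithmetic mean and sd
        cv2 <- (cmp$sd_pg / cmp$mean_pg)^2
        sdlog <- sqrt(log1p(cv2))
        meanlog <- log(cmp$mean_pg) - sdlog^2 / 2
        m0[idx] <- stats::rlnorm(length(idx), meanlog, sdlog)
      } else {
        m0[idx] <- pmax(stats::rnorm(length(idx), cmp$mean_pg, cmp$sd_pg),
                        cmp$mean_pg / 10)
      }
      g_ctrl[idx] <- cmp$sgr %||% pop$sgr_control
      responsive[idx] <- cmp$responsive %||% TRUE
    }
    g_ctrl <- g_ctrl + stats::rnorm(n, 0, pop$sgr_sd)

    # resistant cells keep their own rate regardless of dose
    resistant <- logical(n)
    g_target <- g_ctrl
    tau <- 0
    if (!is.null(drug) && dose > 0) {
      resistant <- stats::runif(n) < drug$resistant_fraction
      hill_mean <- hill_model(dose, drug$e0, drug$emax, drug$ec50, drug$hs)
      shift <- hill_mean - drug$e0  # dose-induced change in mean SGR
      g_target <- g_ctrl + ifelse(responsive & !resistant, shift, 0)
      g_target[resistant] <- drug$resistant_sgr +
        stats::rnorm(sum(resistant), 0, pop$sgr_sd)
      tau <- drug$response_delay_tau
    }

    t_h <- (seq_len(n_frames) - 1L) * pop$frame_interval
    # accumulated growth exponent: integral of g0 + (gt - g0)(1 - exp(-t/tau))
    onset_int <- if (tau > 0) t_h - tau * (1 - exp(-t_h / tau)) else t_h
    expo <- outer(g_ctrl, t_h) + outer(g_target - g_ctrl, onset_int)
    if (pop$sgr_wander_sd > 0) {
      # within-cell OU growth-rate fluctuation, integrated per frame
      a <- exp(-pop$frame_interval / pop$sgr_wander_tau)
      w <- matrix(0, n, n_frames)
      w[, 1L] <- stats::rnorm(n, 0, pop$sgr_wander_sd)
      innov_sd <- pop$sgr_wander_sd * sqrt(1 - a^2)
      for (k in 2:n_frames) {
        w[, k] <- a * w[, k - 1L] + stats::rnorm(n, 0, innov_sd)
      }
      wint <- t(apply(w * pop$frame_interval, 1L, cumsum)) -
        w * pop$frame_interval  # integral up to the start of each frame
      expo <- expo + wint
    }
    mass_true <- if (pop$growth_model == "exponential") {
      m0 * exp(expo)
    } else {
      m0 * (1 + expo)
    }
    noise <- if (pop$noise_sd_mass > 0) {
      matrix(stats::rnorm(n * n_frames, 0, pop$noise_sd_mass), n, n_frames)
    } else 0
    mass_obs <- mass_true + noise

    # grid starting positions with jitter, bounded reflecting random walk
    side <- ceiling(sqrt(n))
    pitch <- pop$field_um / side
    gx <- ((seq_len(n) - 1L) %% side + 0.5) * pitch
    gy <- ((seq_len(n) - 1L) %/% side + 0.5) * pitch
    gx <- gx + stats::runif(n, -pitch / 8, pitch / 8)
    gy <- gy + stats::runif(n, -pitch / 8, pitch / 8)
    bounded_walk <- function(start, bound, step) {
      d <- cumsum(c(0, stats::rnorm(n_frames - 1L, 0, step)))
      # reflect into [-bound, bound]
      d <- abs((d + bound) %% (4 * bound) - 2 * bound) - bound
      start + d
    }
    xs <- t(vapply(gx, bounded_walk, numeric(n_frames),
                   bound = pop$motion_bound, step = pop$motion_step))
    ys <- t(vapply(gy, bounded_walk, numeric(n_frames),
                   bound = pop$motion_bound, step = pop$motion_step))

    subpop <- ifelse(resistant, "resistant",
                     ifelse(responsive, "responsive", "non_responsive"))
    out <- data.frame(
      cell_id = rep(seq_len(n), each = n_frames),
      frame = rep(seq_len(n_frames), n),
      t_h = rep(t_h, n),
      x_um = as.vector(t(xs)),
      y_um = as.vector(t(ys)),
      mass_pg = as.vector(t(mass_obs)),
      mass_true_pg = as.vector(t(mass_true)),
      sgr_true = rep(g_target, each = n_frames),
      subpopulation = rep(subpop, each = n_frames),
      well = well, drug = drug_name, dose = dose,
      stringsAsFactors = FALSE
    )
    attr(out, "frame_interval") <- pop$frame_interval
    class(out) <- c("cell_tracks", "data.frame")
    out
  })
}

#' Simulate a multi-well dose-response experiment
#'
#' Convenience wrapper running [simulate_tracks()] once per well of a plate
#' map, deriving per-well seeds from the population seed so wells are
#' independent but the whole experiment is reproducible.
#'
#' @param pop A [population_spec()] (its `seed` seeds the experiment).
#' @param drug A [drug_effect_spec()].
#' @param plate A plate-map `data.frame` with columns `well`, `drug`,
#'   `dose`, and optionally `control_group` (see [make_plate_map()]).
#' @return A single `cell_tracks` data.frame; `cell_id` is made unique
#'   across wells.
#' @export
simulate_experiment <- function(pop, drug, plate) {
  stopifnot(is.data.frame(plate), all(c("well", "drug", "dose") %in% names(plate)))
  base_seed <- pop$seed %||% 0L
  res <- vector("list", nrow(plate))
  for (i in seq_len(nrow(plate))) {
    pop_i <- pop
    pop_i$seed <- (base_seed + 7919L * i) %% .Machine$integer.max
    tr <- simulate_tracks(pop_i, drug, dose = plate$dose[i],
                          well = plate$well[i], drug_name = plate$drug[i])
    tr$cell_id <- paste0(plate$well[i], "_", tr$cell_id)
    res[[i]] <- tr
  }
  out <- do.call(rbind, res)
  attr(out, "frame_interval") <- pop$frame_interval
  class(out) <- c("cell_tracks", "data.frame")
  out
}
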