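#' Build a plate map
#'
#' One row per well: drug name, dose (0 for vehicle), control-group tag
#' (vehicle wells must carry one of two groups, e.g. "ctrlA"/"ctrlB", for
#' the time-of-response threshold), and positions imaged per well.
#'
#' @param well,drug,dose Vectors of equal length.
#' @param control_group Control-group tag per well ("" for treated wells).
#' @param positions Imaged positions per well (default 9).
#' @param vehicle_fraction Vehicle (e.g. DMSO) volume fraction kept
#'   constant across wells; recorded for provenance (default 0.001).
#' @return `data.frame` of class `plate_map`.
#' @export
make_plate_map <- function(well, drug, dose, control_group = "",
                           positions = 9L, vehicle_fraction = 0.001) {
  pm <- data.frame(well = well, drug = drug, dose = dose,
                   control_group = control_group,
                   positions = positions, stringsAsFactors = FALSE)
  if (anyDuplicated(pm$well)) stop("duplicate wells in plate map")
  if (any(pm$dose < 0)) stop("doses must be >= 0")
  attr(pm, "vehicle_fraction") <- vehicle_fraction
  class(pm) <- c("plate_map", "data.frame")
  pm
}

#' Read / write a plate map as YAML
#'
#' @param path File path.
#' @param pm A `plate_map`.
#' @return `read_plate_map` returns a `plate_map`.
#' @export
read_plate_map <- function(path) {
  y <- yaml::read_yaml(path)
  wells <- y$wells
  pm <- make_plate_map(
    well = vapply(wells, `[[`, character(1), "well"),
    drug = vapply(wells, `[[`, character(1), "drug"),
    dose = vapply(wells, function(w) as.numeric(w$dose), numeric(1)),
    control_group = vapply(wells, function(w) w$control_group %||% "", character(1)),
    positions = vapply(wells, function(w) as.integer(w$positions %||% 9L), integer(1)),
    vehicle_fraction = y$vehicle_fraction %||% 0.001)
  pm
}

#' @rdname read_plate_map
#' @export
write_plate_map <- function(pm, path) {
  stopifnot(inherits(pm, "plate_map"))
  y <- list(vehicle_fraction = attr(pm, "vehicle_fraction") %||% 0.001,
            wells = lapply(seq_len(nrow(pm)), function(i) {
              list(well = pm$well[i], drug = pm$drug[i], dose = pm$dose[i],
                   control_group = pm$control_group[i],
                   positions = pm$positions[i])
            }))
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Read / write phase frames as 32-bit float TIFF
#'
#' TIFF samples are stored in [0, 1], so phase in radians is mapped
#' affinely: `stored = (phi + phase_range) / (2 * phase_range)`. Writer and
#' reader must use the same `phase_range`; the default +/- 8 rad covers
#' cellular phase shifts with ~1e-6 rad quantization at 32-bit float.
#' Values outside the range are clipped with a warning.
#'
#' @param frames List of phase matrices (radians) or a single matrix.
#' @param path TIFF path.
#' @param phase_range Half-range of representable phase, radians.
#' @param pixel_size,wavelength Metadata attached on read, um / nm.
#' @return `read_phase_tiff` returns a list of matrices.
#' @export
write_phase_tiff <- function(frames, path, phase_range = 8) {
  if (is.matrix(frames)) frames <- list(frames)
  enc <- lapply(frames, function(m) {
    m <- unclass(m); attributes(m) <- list(dim = dim(m))
    if (any(abs(m) > phase_range)) {
      warning("phase values beyond +/-", phase_range, " rad clipped")
      m <- pmin(pmax(m, -phase_range), phase_range)
    }
    (m + phase_range) / (2 * phase_range)
  })
  tiff::writeTIFF(enc, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_phase_tiff
#' @export
read_phase_tiff <- function(path, phase_range = 8, pixel_size = 0.6,
                            wavelength = 525) {
  imgs <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (is.matrix(imgs)) imgs <- list(imgs)
  lapply(imgs, function(m) {
    m <- m * 2 * phase_range - phase_range
    attr(m, "pixel_size") <- pixel_size
    attr(m, "wavelength") <- wavelength
    m
  })
}

#' Read / write tracks or detections as CSV
#'
#' Tidy CSV with one row per observation; coordinates are um, 0-based
#' pixel-centered.
#'
#' @param tracks `data.frame`.
#' @param path CSV path.
#' @param frame_interval Hours between frames, restored on read.
#' @return `read_tracks_csv` returns a `cell_tracks` data.frame.
#' @export
write_tracks_csv <- function(tracks, path) {
  utils::write.csv(as.data.frame(tracks), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path, frame_interval = 1 / 3) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  attr(out, "frame_interval") <- frame_interval
  class(out) <- c("cell_tracks", "data.frame")
  out
}

#' Pipeline run configuration
#'
#' Fully determines a run given its inputs: stage parameters, seeds and
#' output location. Serialized (JSON) and hashed into every output for
#' provenance.
#'
#' @param optics An [optics_spec()].
#' @param detection List of [segment_cells()] / [detect_cells()] options.
#' @param tracking A [link_cost()].
#' @param sgr List with `median_window`, `min_length`.
#' @param windows List with `width` (h), `centers` (or NULL for the
#'   default 2 h grid).
#' @param kde A [kde_params()].
#' @param mass_threshold Optional mass filter threshold, pg ("auto" to
#'   use [suggest_mass_threshold()], NULL to disable filtering).
#' @param fix_hs Fix the Hill slope (NULL fits it).
#' @param run_mixture Fit the two-Gaussian mixture timecourse per
#'   condition.
#' @param seed Seed recorded and used for any stochastic stage.
#' @param output_dir Directory for result files (NULL: nothing written).
#' @return List of class `run_config`.
#' @export
run_config <- function(optics = optics_spec(), detection = list(),
                       tracking = link_cost(),
                       sgr = list(median_window = 5L, min_length = 20L),
                       windows = list(width = 12, centers = NULL),
                       kde = kde_params(), mass_threshold = NULL,
                       fix_hs = NULL, run_mixture = TRUE, seed = 1L,
                       output_dir = NULL) {
  structure(list(optics = optics, detection = detection, tracking = tracking,
                 sgr = sgr, windows = windows, kde = kde,
                 mass_threshold = mass_threshold, fix_hs = fix_hs,
                 run_mixture = run_mixture, seed = seed,
                 output_dir = output_dir),
            class = "run_config")
}

#' Run the analysis pipeline
#'
#' Executes the stages needed for the given entry level and returns a
#' machine-readable result bundle: per-drug Hill fits with EC50 and depth
#' of response, a time-of-response table (when the plate map defines two
#' control groups), mixture timecourses, normalized mass curves, and a
#' mass-filter report. Every artifact carries the config hash and seed.
#'
#' Entry levels: `intensities` (list of per-position lists, each a list of
#' per-frame four-image sets) are reconstructed to phase; `phase` (list of
#' per-position phase-frame lists, named by well) is detected and tracked;
#' `tracks` (a `cell_tracks` data.frame with `well`, `drug`, `dose`
#' columns) skips the imaging stages.
#'
#' @param config A [run_config()].
#' @param inputs The entry-level data (see Details).
#' @param plate A `plate_map` (required for `intensities`/`phase` entry,
#'   or when tracks lack condition labels).
#' @param entry "tracks", "phase" or "intensities".
#' @return List of class `mqpi_result`: `sgr_table`, `dose_response`
#'   (per drug: `hill_fit`, dose table), `tor` (per drug x dose),
#'   `mixture` (per drug x dose), `mass_curves`, `filter_report`,
#'   `config_hash`, `seed`, `counts`.
#' @export
run_pipeline <- function(config, inputs, plate = NULL,
                         entry = c("tracks", "phase", "intensities")) {
  stopifnot(inherits(config, "run_config"))
  entry <- match.arg(entry)
  counts <- list()

  if (entry == "intensities") {
    if (is.null(plate)) stop("plate map required for intensity-level entry")
    tfs <- NULL
    inputs <- lapply(inputs, function(pos_frames) {
      lapply(pos_frames, function(frames4) {
        phi <- dpc_reconstruct(frames4, config$optics, tfs = tfs)
        attr(phi, "pixel_size") <- config$optics$pixel_size
        attr(phi, "wavelength") <- config$optics$wavelength
        phi
      })
    })
    entry <- "phase"
  }
  if (entry == "phase") {
    if (is.null(plate)) stop("plate map required for phase-level entry")
    wells <- names(inputs)
    if (is.null(wells)) stop("phase input list must be named by well")
    missing_wells <- setdiff(wells, plate$well)
    if (length(missing_wells)) {
      stop("positions imaged for wells missing from the plate map: ",
           paste(missing_wells, collapse = ", "))
    }
    tracks <- do.call(rbind, lapply(wells, function(w) {
      det <- do.call(detect_movie,
                     c(list(inputs[[w]], well = w,
                            pixel_size = config$optics$pixel_size,
                            wavelength = config$optics$wavelength),
                       config$detection))
      tr <- build_tracks(det, config$tracking,
                         frame_interval = config$sgr$frame_interval %||% 1 / 3)
      tr$track_id <- paste0(w, "_", tr$track_id)
      idx <- match(w, plate$well)
      tr$well <- w
      tr$drug <- plate$drug[idx]
      tr$dose <- plate$dose[idx]
      tr
    }))
    class(tracks) <- c("cell_tracks", "data.frame")
    inputs <- tracks
  }
  tracks <- inputs
  stopifnot(is.data.frame(tracks),
            all(c("t_h", "mass_pg") %in% names(tracks)))
  if (!all(c("well", "drug", "dose") %in% names(tracks))) {
    stop("tracks need well/drug/dose condition labels (see plate map)")
  }
  counts$n_observations <- nrow(tracks)

  sgr_tab <- compute_sgr_table(tracks,
                               median_window = config$sgr$median_window %||% 5L,
                               min_length = config$sgr$min_length %||% 20L)
  counts$n_tracks_kept <- nrow(sgr_tab)
  counts$n_tracks_skipped_short <- attr(sgr_tab, "skipped")

  # optional initial-mass filter
  filter_report <- NULL
  if (!is.null(config$mass_threshold)) {
    thr <- config$mass_threshold
    if (identical(thr, "auto")) thr <- suggest_mass_threshold(sgr_tab$initial_mass)
    if (is.finite(thr)) {
      filtered <- apply_mass_filter(sgr_tab, mass_filter(thr))
      filter_report <- cbind(threshold_pg = thr, attr(filtered, "summary"))
      sgr_tab <- filtered
    }
  }

  # dose-response per drug (treated doses plus vehicle wells as dose 0)
  drugs <- setdiff(unique(sgr_tab$drug[sgr_tab$dose > 0]), "vehicle")
  vehicle <- sgr_tab[sgr_tab$dose == 0, , drop = FALSE]
  dose_response <- list()
  for (dg in drugs) {
    sub <- rbind(sgr_tab[sgr_tab$drug == dg & sgr_tab$dose > 0, , drop = FALSE],
                 vehicle)
    tab <- sgr_by_dose(sub)
    fit <- try(fit_hill(tab$dose, tab$mean_sgr, fix_hs = config$fix_hs),
               silent = TRUE)
    if (inherits(fit, "try-error")) fit <- NULL
    dose_response[[dg]] <- list(fit = fit, dose_table = tab)
  }

  # windowed SGR, ToR and mixture (needs two control groups and data
  # spanning at least one window)
  win_all <- try(windowed_sgr(tracks, centers = config$windows$centers,
                              width = config$windows$width %||% 12),
                 silent = TRUE)
  if (inherits(win_all, "try-error")) win_all <- NULL
  tor_tab <- NULL
  mixture <- list()
  ctrl_groups <- if (!is.null(plate)) {
    unique(plate$control_group[nzchar(plate$control_group)])
  } else character(0)
  if (is.null(plate) && "control_group" %in% names(tracks)) {
    ctrl_groups <- unique(tracks$control_group[nzchar(tracks$control_group)])
  }
  if (!is.null(win_all) && length(ctrl_groups) >= 2L && !is.null(plate)) {
    grp_wells <- function(g) plate$well[plate$control_group == g]
    win_a <- win_all[win_all$well %in% grp_wells(ctrl_groups[1]), ]
    win_b <- win_all[win_all$well %in% grp_wells(ctrl_groups[2]), ]
    ctrl_wells <- plate$well[nzchar(plate$control_group)]
    win_ctrl <- win_all[win_all$well %in% ctrl_wells, ]
    thr <- control_threshold(win_a, win_b, config$kde)
    rows <- list()
    for (dg in drugs) {
      for (ds in sort(unique(win_all$dose[win_all$drug == dg & win_all$dose > 0]))) {
        win_t <- win_all[win_all$drug == dg & win_all$dose == ds, ]
        tf <- try(time_of_response(win_t, win_ctrl, thr, config$kde),
                  silent = TRUE)
        if (inherits(tf, "try-error")) next
        rows[[length(rows) + 1L]] <- data.frame(
          drug = dg, dose = ds, threshold = unclass(thr),
          h_inf = tf$h_inf, tau = tf$tau, tor = tf$tor,
          responded = tf$responded)
        if (isTRUE(config$run_mixture)) {
          mx <- try(fit_mixture_sequence(win_t, config$kde), silent = TRUE)
          if (!inherits(mx, "try-error")) {
            mixture[[paste(dg, ds, sep = "@")]] <- mx
          }
        }
      }
    }
    tor_tab <- if (length(rows)) do.call(rbind, rows) else NULL
  }

  mass_curves <- lapply(split(tracks, list(tracks$drug, tracks$dose), drop = TRUE),
                        normalized_mass_curve, group_col = "well")

  cfg_for_hash <- config
  cfg_for_hash$output_dir <- NULL
  res <- structure(list(sgr_table = sgr_tab, dose_response = dose_response,
                        tor = tor_tab, mixture = mixture,
                        mass_curves = mass_curves,
                        filter_report = filter_report,
                        config_hash = config_hash(unclass_deep(cfg_for_hash)),
                        seed = config$seed, counts = counts),
                   class = "mqpi_result")
  if (!is.null(config$output_dir)) write_result(res, config$output_dir)
  res
}

# strip classes so jsonlite serializes deterministic plain lists
unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else unclass(x)
}

#' Write a pipeline result bundle to disk
#'
#' `summary.json` (fits, ToR table, mixture timecourses, counts, config
#' hash, seed) plus tidy CSVs for the SGR table.
#'
#' @param res An `mqpi_result`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_result <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summ <- list(
    config_hash = res$config_hash,
    seed = res$seed,
    counts = res$counts,
    dose_response = lapply(res$dose_response, function(x) {
      if (is.null(x$fit)) return(list(error = "fit failed"))
      list(coefficients = as.list(x$fit$coefficients), dor = x$fit$dor,
           rmse = x$fit$rmse, degenerate = x$fit$degenerate,
           ec50_identifiable = x$fit$ec50_identifiable,
           dose_table = x$dose_table)
    }),
    tor = res$tor,
    mixture = lapply(res$mixture, as.data.frame),
    filter_report = res$filter_report)
  jsonlite::write_json(summ, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  utils::write.csv(as.data.frame(res$sgr_table),
                   file.path(dir, "sgr_table.csv"), row.names = FALSE)
  invisible(dir)
}

#' @export
print.mqpi_result <- function(x, ...) {
  cat("mQPI pipeline result\n")
  cat(sprintf("  %d observations -> %d tracks (%d skipped as short)\n",
              x$counts$n_observations %||% NA, x$counts$n_tracks_kept %||% NA,
              x$counts$n_tracks_skipped_short %||% NA))
  for (dg in names(x$dose_response)) {
    f <- x$dose_response[[dg]]$fit
    if (is.null(f)) { cat(sprintf("  %s: fit failed\n", dg)); next }
    cat(sprintf("  %s: EC50 = %.4g, DoR = %s%s\n", dg,
                f$coefficients["ec50"],
                if (is.na(f$dor)) "undefined" else sprintf("%.3g", f$dor),
                if (f$degenerate) " [degenerate]" else ""))
  }
  if (!is.null(x$tor)) {
    cat(sprintf("  ToR rows: %d (%d responded)\n", nrow(x$tor), sum(x$tor$responded)))
  }
  cat("  config:", x$config_hash, "seed:", x$seed, "\n")
  invisible(x)
}

#' Welch t-test and variance F-test for two samples
#'
#' Thin wrapper over `stats::t.test` (two-tailed, Welch correction) and
#' `stats::var.test` (two-tailed F-test), with significance at p < 0.05.
#'
#' @param group_a,group_b Numeric samples (n >= 2 each).
#' @return List with `t` (statistic, p.value, significant) and `f`
#'   (statistic, p.value, significant).
#' @export
standard_tests <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("both groups need n >= 2")
  }
  tt <- stats::t.test(group_a, group_b, var.equal = FALSE)
  ft <- stats::var.test(group_a, group_b)
  list(t = list(statistic = unname(tt$statistic), p.value = tt$p.value,
                significant = tt$p.value < 0.05),
       f = list(statistic = unname(ft$statistic), p.value = ft$p.value,
                significant = ft$p.value < 0.05))
}
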