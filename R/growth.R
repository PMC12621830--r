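#' Specific growth rate of one mass track
#'
#' Median-filters the mass series (shrinking window at the endpoints, so no
#' values are fabricated), fits a least-squares line mass ~ time, and
#' normalizes the slope by the initial projected mass -- the fitted line's
#' value at the track's start time. Tracks must be longer than `min_length`
#' frames.
#'
#' @param t_h Time, hours.
#' @param mass_pg Mass series, pg.
#' @param median_window Median filter size, frames (odd).
#' @param min_length Minimum track length (frames); tracks of length
#'   `<= min_length` are skipped (NULL returned, with the reason reported
#'   via `message()` unless `quiet = TRUE`).
#' @param quiet Suppress the skip message.
#' @return List with `sgr` (1/h), `initial_mass` (pg), `slope` (pg/h),
#'   `r2`, `n_frames`; or NULL for short tracks.
#' @export
compute_sgr <- function(t_h, mass_pg, median_window = 5L, min_length = 20L,
                        quiet = FALSE) {
  n <- length(t_h)
  stopifnot(n == length(mass_pg))
  if (n <= min_length) {
    if (!quiet) message(sprintf("track skipped: length %d <= %d frames",
                                n, min_length))
    return(NULL)
  }
  m <- median_filter(mass_pg, median_window)
  fit <- line_fit(t_h, m, t0 = t_h[1L])
  m0 <- fit$y0
  if (!is.finite(m0) || m0 <= 0) {
    if (!quiet) message("track skipped: non-positive initial projected mass")
    return(NULL)
  }
  list(sgr = fit$slope / m0, initial_mass = m0, slope = fit$slope,
       r2 = fit$r2, n_frames = n)
}

#' Specific growth rates for all tracks in a table
#'
#' Applies [compute_sgr()] to each track of a `cell_tracks` table and
#' returns one SGR record per retained track, carrying condition labels
#' through. Skipped tracks are counted in attribute `skipped`.
#'
#' @param tracks `data.frame` with `track_id` (or `cell_id`), `t_h`,
#'   `mass_pg`, and optional `well`, `drug`, `dose` labels.
#' @param median_window,min_length See [compute_sgr()].
#' @return `data.frame`: `track_id`, `sgr`, `initial_mass`, `fit_r2`,
#'   `n_frames`, plus any of `well`/`drug`/`dose`/`subpopulation` present.
#' @export
compute_sgr_table <- function(tracks, median_window = 5L, min_length = 20L) {
  id_col <- if ("track_id" %in% names(tracks)) "track_id" else "cell_id"
  stopifnot(id_col %in% names(tracks),
            all(c("t_h", "mass_pg") %in% names(tracks)))
  keep_cols <- intersect(c("well", "drug", "dose", "subpopulation", "sgr_true"),
                         names(tracks))
  pieces <- split(tracks, tracks[[id_col]])
  skipped <- 0L
  rows <- lapply(pieces, function(tr) {
    tr <- tr[order(tr$frame), , drop = FALSE]
    rec <- compute_sgr(tr$t_h, tr$mass_pg, median_window, min_length,
                       quiet = TRUE)
    if (is.null(rec)) {
      skipped <<- skipped + 1L
      return(NULL)
    }
    out <- data.frame(track_id = tr[[id_col]][1L], sgr = rec$sgr,
                      initial_mass = rec$initial_mass, fit_r2 = rec$r2,
                      n_frames = rec$n_frames, stringsAsFactors = FALSE)
    for (cl in keep_cols) out[[cl]] <- tr[[cl]][1L]
    out
  })
  if (skipped > 0L) {
    message(sprintf("%d track(s) skipped (shorter than %d frames or degenerate)",
                    skipped, min_length + 1L))
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Windowed specific growth rates
#'
#' Per-cell SGR restricted to sliding time windows: for each window center,
#' each track's mass samples inside [center - width/2, center + width/2]
#' are median-filtered and line-fitted, with the slope normalized by the
#' fitted mass at the window start (the same convention as whole-track
#' SGR). Cells contributing fewer than `min_coverage` of the window's
#' frames are excluded from that window.
#'
#' @param tracks `cell_tracks`-style `data.frame`.
#' @param centers Window centers, hours; default a 2 h grid covering the
#'   data with full windows.
#' @param width Window width, hours (default 12).
#' @param min_coverage Minimum fraction of the window's frames a cell must
#'   have (default 0.5).
#' @param median_window Median filter size, frames.
#' @return `data.frame`: `window_center`, `track_id`, `sgr`,
#'   `initial_mass`, `n_frames`, plus condition labels present in the
#'   input.
#' @export
windowed_sgr <- function(tracks, centers = NULL, width = 12,
                         min_coverage = 0.5, median_window = 5L) {
  stopifnot(width > 0)
  id_col <- if ("track_id" %in% names(tracks)) "track_id" else "cell_id"
  dt <- attr(tracks, "frame_interval") %||%
    stats::median(diff(sort(unique(tracks$t_h))))
  if (is.null(centers)) {
    lo <- min(tracks$t_h); hi <- max(tracks$t_h)
    if (hi - lo < width) stop("data span shorter than one window")
    centers <- seq(ceiling((lo + width / 2) / 2) * 2,
                   floor((hi - width / 2) / 2) * 2, by = 2)
  }
  frames_per_window <- floor(width / dt) + 1
  keep_cols <- intersect(c("well", "drug", "dose", "subpopulation", "sgr_true"),
                         names(tracks))
  idx_by_track <- split(seq_len(nrow(tracks)), tracks[[id_col]])
  n_slots <- length(idx_by_track) * length(centers)
  res_center <- numeric(n_slots); res_id <- vector(typeof(tracks[[id_col]]), n_slots)
  res_sgr <- numeric(n_slots); res_m0 <- numeric(n_slots)
  res_n <- integer(n_slots); res_first <- integer(n_slots)
  k <- 0L
  for (ti in seq_along(idx_by_track)) {
    ix <- idx_by_track[[ti]]
    tt <- tracks$t_h[ix]; mm <- tracks$mass_pg[ix]
    o <- order(tt); tt <- tt[o]; mm <- mm[o]; ix <- ix[o]
    mf <- median_filter(mm, median_window)  # filter the whole track once
    for (cen in centers) {
      sel <- which(tt >= cen - width / 2 & tt <= cen + width / 2)
      ns <- length(sel)
      if (ns < min_coverage * frames_per_window || ns < 3L) next
      fit <- line_fit(tt[sel], mf[sel], t0 = tt[sel[1L]])
      if (!is.finite(fit$y0) || fit$y0 <= 0) next
      k <- k + 1L
      res_center[k] <- cen; res_id[k] <- tracks[[id_col]][ix[1L]]
      res_sgr[k] <- fit$slope / fit$y0; res_m0[k] <- fit$y0
      res_n[k] <- ns; res_first[k] <- ix[1L]
    }
  }
  if (k == 0L) {
    res <- data.frame(window_center = numeric(0), track_id = res_id[0],
                      sgr = numeric(0), initial_mass = numeric(0),
                      n_frames = integer(0))
    for (cl in keep_cols) res[[cl]] <- tracks[[cl]][0]
    return(res)
  }
  sl <- seq_len(k)
  res <- data.frame(window_center = res_center[sl], track_id = res_id[sl],
                    sgr = res_sgr[sl], initial_mass = res_m0[sl],
                    n_frames = res_n[sl], stringsAsFactors = FALSE)
  for (cl in keep_cols) res[[cl]] <- tracks[[cl]][res_first[sl]]
  o <- order(res$window_center, res$track_id)
  res <- res[o, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Population mass curve normalized to its initial value
#'
#' Total (or mean) mass of the population per timepoint divided by its
#' value at the first timepoint. When a replicate grouping column is
#' present, the curve is computed per replicate and the across-replicate
#' mean and SEM are reported.
#'
#' @param tracks `cell_tracks`-style `data.frame`.
#' @param group_col Optional replicate column name (e.g. "well").
#' @param statistic "total" (default) or "mean" mass per timepoint.
#' @return `data.frame`: `t_h`, `norm_mass`, `sem` (NA without
#'   replicates).
#' @export
normalized_mass_curve <- function(tracks, group_col = NULL,
                                  statistic = c("total", "mean")) {
  statistic <- match.arg(statistic)
  agg <- function(df) {
    s <- split(df$mass_pg, df$t_h)
    v <- vapply(s, if (statistic == "total") sum else mean, numeric(1))
    t_h <- as.numeric(names(v))
    o <- order(t_h)
    v <- v[o]; t_h <- t_h[o]
    if (v[1L] <= 0) stop("initial population mass must be > 0")
    data.frame(t_h = t_h, norm_mass = v / v[1L])
  }
  if (is.null(group_col) || !group_col %in% names(tracks) ||
      length(unique(tracks[[group_col]])) < 2L) {
    out <- agg(tracks)
    out$sem <- NA_real_
    return(out)
  }
  reps <- lapply(split(tracks, tracks[[group_col]]), agg)
  t_h <- reps[[1L]]$t_h
  mat <- vapply(reps, function(r) r$norm_mass[match(t_h, r$t_h)],
                numeric(length(t_h)))
  data.frame(t_h = t_h, norm_mass = rowMeans(mat, na.rm = TRUE),
             sem = apply(mat, 1L, stats::sd, na.rm = TRUE) / sqrt(ncol(mat)))
}

#' Filter SGR records by initial mass
#'
#' Retains records above (or below) a mass threshold, e.g. to exclude small
#' non-growing contaminating cells from a direct-from-thaw sample whose
#' initial-mass distribution is bimodal.
#'
#' @param records SGR table from [compute_sgr_table()] (needs
#'   `initial_mass` and `sgr`).
#' @param filter A [mass_filter()].
#' @return The retained subset; a `summary` attribute reports counts and
#'   mean SGR of both subsets. Warns when nothing is retained.
#' @export
apply_mass_filter <- function(records, filter) {
  stopifnot(inherits(filter, "mass_filter"), "initial_mass" %in% names(records))
  keep <- if (filter$side == "keep_above") {
    records$initial_mass > filter$threshold
  } else {
    records$initial_mass < filter$threshold
  }
  kept <- records[keep, , drop = FALSE]
  removed <- records[!keep, , drop = FALSE]
  if (nrow(kept) == 0L) warning("mass filter removed every record")
  attr(kept, "summary") <- data.frame(
    subset = c("kept", "removed"),
    n = c(nrow(kept), nrow(removed)),
    mean_sgr = c(mean(kept$sgr), mean(removed$sgr)),
    mean_initial_mass = c(mean(kept$initial_mass), mean(removed$initial_mass)))
  kept
}

#' Suggest a mass threshold at the antimode of a bimodal distribution
#'
#' Fits one- and two-component Gaussian mixtures to log initial mass
#' (`mclust`). If the two-component model is not favored (BIC) or the
#' components are not separated by at least `min_separation` pooled
#' standard deviations, no threshold is proposed (`NA`). Otherwise the
#' antimode -- the density minimum of the fitted mixture between the two
#' component means -- is returned on the mass scale.
#'
#' @param initial_mass Initial masses, pg.
#' @param min_separation Required separation of the two component means in
#'   units of the mean component standard deviation.
#' @return Threshold in pg, or `NA` with a message when the distribution
#'   is not convincingly bimodal.
#' @export
suggest_mass_threshold <- function(initial_mass, min_separation = 2) {
  x <- log(initial_mass[initial_mass > 0])
  if (length(x) < 20L) {
    message("too few cells to assess bimodality")
    return(NA_real_)
  }
  fit <- mclust::Mclust(x, G = 1:2, modelNames = "V", verbose = FALSE)
  if (is.null(fit) || fit$G < 2L) {
    message("initial-mass distribution looks unimodal; no threshold proposed")
    return(NA_real_)
  }
  mu <- fit$parameters$mean
  sg <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sg) == 1L) sg <- rep(sg, 2L)
  if (abs(diff(mu)) < min_separation * mean(sg)) {
    message("mixture components overlap; no threshold proposed")
    return(NA_real_)
  }
  pro <- fit$parameters$pro
  dens <- function(z) pro[1] * stats::dnorm(z, mu[1], sg[1]) +
    pro[2] * stats::dnorm(z, mu[2], sg[2])
  opt <- stats::optimize(dens, interval = sort(mu))
  exp(opt$minimum)
}
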