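# Shared synthetic fixtures built in code at test time.

# Small noiseless exponential population, optionally dosed.
quiet_pop <- function(n = 5, sgr = 0.02, seed = 1, model = "exponential",
                      duration = 48, noise = 0, sgr_sd = 0) {
  population_spec(n_cells = n, sgr_control = sgr, sgr_sd = sgr_sd,
                  sgr_wander_sd = 0, noise_sd_mass = noise,
                  growth_model = model, duration = duration, seed = seed)
}

# Per-cell log-slope over the full track, computed directly from the
# generated masses -- the independent oracle for generator growth rates.
log_slope_by_cell <- function(tracks) {
  vapply(split(tracks, tracks$cell_id), function(tr) {
    tr <- tr[order(tr$frame), ]
    stats::coef(stats::lm(log(tr$mass_true_pg) ~ tr$t_h))[[2]]
  }, numeric(1))
}

# Windowed SGR table for a simulated population (drug optional).
sim_windows <- function(seed, n = 120, drug = NULL, dose = 0, sgr = 0.02,
                        well = "W") {
  pop <- population_spec(n_cells = n, sgr_control = sgr, sgr_sd = 0.004,
                         noise_sd_mass = 2, seed = seed)
  windowed_sgr(simulate_tracks(pop, drug, dose, well = well))
}

# Which ground-truth identities were recovered as unbroken tracks?
# A full-length track counts as recovering cell g when it stays within
# `tol_um` of g's trajectory at every frame (merged or swapped tracks
# fail this); returns one row per recovered identity with the worst
# relative mass error along the track.
recovered_tracks <- function(trk, truth, qc, n_frames, tol_um = 5) {
  full_ids <- qc$track_id[qc$length == n_frames]
  gt1 <- truth[truth$frame == 1, ]
  rows <- lapply(full_ids, function(tid) {
    tt <- trk[trk$track_id == tid, ]
    tt <- tt[order(tt$frame), ]
    gid <- gt1$cell_id[which.min((gt1$x_um - tt$x_um[1])^2 +
                                   (gt1$y_um - tt$y_um[1])^2)]
    gg <- truth[truth$cell_id == gid, ]
    gg <- gg[order(gg$frame), ]
    if (nrow(gg) != nrow(tt)) return(NULL)
    d <- sqrt((tt$x_um - gg$x_um)^2 + (tt$y_um - gg$y_um)^2)
    if (max(d) > tol_um) return(NULL)
    data.frame(track_id = tid, cell_id = gid,
               mass_err = max(abs(tt$mass_pg - gg$mass_pg) / gg$mass_pg))
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  out[!duplicated(out$cell_id), , drop = FALSE]
}
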