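# Resolve NULL (data-adaptive) link weights: reciprocal of the pooled
# population variance of each term, so position and mass are comparable.
resolve_weights <- function(cost, obs_a, obs_b) {
  ws <- cost$spatial_weight
  wm <- cost$mass_weight
  if (is.null(ws)) {
    v <- stats::var(c(obs_a$x_um, obs_b$x_um)) + stats::var(c(obs_a$y_um, obs_b$y_um))
    ws <- if (is.finite(v) && v > 0) 1 / v else 1
  }
  if (is.null(wm)) {
    v <- stats::var(c(obs_a$mass_pg, obs_b$mass_pg))
    wm <- if (is.finite(v) && v > 0) 1 / v else 0
  }
  c(spatial = ws, mass = wm)
}

#' Optimally link cell observations between two frames
#'
#' Solves the one-to-one assignment minimizing the total link cost
#' `spatial_weight * |dxy|^2 + mass_weight * dm^2` (Hungarian algorithm via
#' `clue::solve_LSAP` on a square matrix padded with non-link slots). Pairs
#' farther apart than `max_link_distance` or with a relative mass jump above
#' `max_mass_jump` are never linked; unmatched observations are track deaths
#' (in `obs_a`) or births (in `obs_b`).
#'
#' @param obs_a,obs_b `data.frame`s with columns `x_um`, `y_um`, `mass_pg`.
#' @param cost A [link_cost()].
#' @return Integer vector of length `nrow(obs_a)`: for each row of `obs_a`,
#'   the matched row index in `obs_b`, or `NA` if unmatched.
#' @export
link_frames <- function(obs_a, obs_b, cost = link_cost()) {
  stopifnot(inherits(cost, "link_cost"))
  na <- nrow(obs_a); nb <- nrow(obs_b)
  if (na == 0L) return(integer(0))
  if (nb == 0L) return(rep(NA_integer_, na))
  w <- resolve_weights(cost, obs_a, obs_b)
  d2 <- outer(obs_a$x_um, obs_b$x_um, `-`)^2 + outer(obs_a$y_um, obs_b$y_um, `-`)^2
  dm <- outer(obs_a$mass_pg, obs_b$mass_pg, `-`)
  mmax <- outer(obs_a$mass_pg, obs_b$mass_pg, pmax)
  cmat <- w["spatial"] * d2 + w["mass"] * dm^2
  forbidden <- sqrt(d2) > cost$max_link_distance |
    abs(dm) / pmax(mmax, .Machine$double.eps) > cost$max_mass_jump
  big <- max(cmat[!forbidden], 0) * (na + nb) + 1
  cmat[forbidden] <- big
  # pad to square: dummy columns (unmatched a) and rows (unmatched b) cost `big`
  n <- max(na, nb)
  full <- matrix(big, na + nb, na + nb)
  full[seq_len(na), seq_len(nb)] <- cmat
  full[cbind(seq_len(na), nb + seq_len(na))] <- big       # a_i unmatched slot
  full[cbind(na + seq_len(nb), seq_len(nb))] <- big       # b_j unmatched slot
  full[na + seq_len(nb), nb + seq_len(na)] <- 0           # dummy-dummy free
  sol <- clue::solve_LSAP(full)
  match_idx <- as.integer(sol[seq_len(na)])
  match_idx[match_idx > nb] <- NA_integer_
  ok <- which(!is.na(match_idx))
  gated <- ok[forbidden[cbind(ok, match_idx[ok])]]
  match_idx[gated] <- NA_integer_
  match_idx
}

#' Assemble frame-to-frame links into cell tracks
#'
#' Links consecutive frames with [link_frames()] and chains the assignments
#' into tracks. Optional gap closing keeps a terminated track eligible for
#' linking across up to `cost$max_gap_frames` missing frames.
#'
#' @param obs `data.frame` of observations across frames (columns `frame`,
#'   `x_um`, `y_um`, `mass_pg`; extra columns are carried through). Frames
#'   must be unique per observation row.
#' @param cost A [link_cost()].
#' @param frame_interval Hours between frames (used for the `t_h` column).
#' @return `data.frame` of class `cell_tracks`: input rows plus `track_id`
#'   and `t_h`, ordered by track then frame. Per-track QC (length, gaps) is
#'   attached as attribute `qc`.
#' @export
build_tracks <- function(obs, cost = link_cost(), frame_interval = 1 / 3) {
  stopifnot(is.data.frame(obs),
            all(c("frame", "x_um", "y_um", "mass_pg") %in% names(obs)))
  frames <- sort(unique(obs$frame))
  if (!is.null(obs$label) &&
      anyDuplicated(obs[, c("frame", "label", if ("position" %in% names(obs)) "position")])) {
    stop("duplicate (frame, label) observations")
  }
  obs$.row <- seq_len(nrow(obs))
  track_of <- rep(NA_integer_, nrow(obs))
  next_track <- 1L
  active_rows <- integer(0)  # row index of each active track's last obs
  for (f in frames) {
    cur <- obs[obs$frame == f, , drop = FALSE]
    # a track may skip at most max_gap_frames calendar frames
    if (length(active_rows)) {
      age <- f - obs$frame[active_rows] - 1L
      active_rows <- active_rows[age <= cost$max_gap_frames]
    }
    if (length(active_rows)) {
      prev <- obs[active_rows, , drop = FALSE]
      m <- link_frames(prev, cur, cost)
    } else {
      m <- integer(0)
    }
    new_active <- integer(0)
    matched_cur <- logical(nrow(cur))
    for (i in seq_along(m)) {
      if (!is.na(m[i])) {
        row_cur <- cur$.row[m[i]]
        track_of[row_cur] <- track_of[active_rows[i]]
        matched_cur[m[i]] <- TRUE
        new_active <- c(new_active, row_cur)
      }
    }
    # unmatched active tracks stay eligible until the gap allowance runs out
    if (length(active_rows)) {
      new_active <- c(new_active, active_rows[is.na(m)])
    }
    # unmatched current observations start new tracks
    for (j in which(!matched_cur)) {
      row_cur <- cur$.row[j]
      track_of[row_cur] <- next_track
      next_track <- next_track + 1L
      new_active <- c(new_active, row_cur)
    }
    active_rows <- new_active
  }
  obs$track_id <- track_of
  obs$t_h <- (obs$frame - min(obs$frame)) * frame_interval
  obs <- obs[order(obs$track_id, obs$frame), ]
  obs$.row <- NULL
  rownames(obs) <- NULL
  lens <- table(obs$track_id)
  gaps <- vapply(split(obs$frame, obs$track_id),
                 function(fr) sum(diff(fr) - 1L), numeric(1))
  attr(obs, "qc") <- data.frame(track_id = as.integer(names(lens)),
                                length = as.integer(lens),
                                gaps = as.integer(gaps))
  attr(obs, "frame_interval") <- frame_interval
  class(obs) <- c("cell_tracks", "data.frame")
  obs
}
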