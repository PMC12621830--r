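# Conversion between integrated phase (radians summed over pixels) and dry
# mass in picograms: mass_kg = lambda * sum(phi) * pixel_area / (2 pi alpha).
phase_sum_for_mass <- function(mass_pg, wavelength_nm, alpha, pixel_area_um2) {
  mass_kg <- mass_pg * 1e-15
  lambda_m <- wavelength_nm * 1e-9
  area_m2 <- pixel_area_um2 * 1e-12
  mass_kg * 2 * pi * alpha / (lambda_m * area_m2)
}

#' Render simulated tracks into quantitative phase frames
#'
#' Draws each cell as a phase footprint (uniform disk or truncated Gaussian
#' blob) centered on its simulated position, scaled so the integrated phase
#' of the footprint corresponds exactly to the cell's scheduled (noisy
#' observed) mass through the dry-mass relation. Ground-truth label images
#' and a per-cell schedule table are returned alongside; overlapping cells
#' are rendered additively and flagged.
#'
#' @param tracks A `cell_tracks` data.frame from [simulate_tracks()].
#' @param scene A [scene_spec()].
#' @param alpha Specific refractive increment, m^3/kg.
#' @param seed Optional seed for cell radii and background noise.
#' @return A list with `phase` (list of matrices, radians, one per frame,
#'   each carrying `pixel_size` and `wavelength` attributes), `labels`
#'   (list of integer ground-truth label matrices), and `truth` (data.frame
#'   `cell_id`, `frame`, `x_um`, `y_um`, `mass_pg`, `subpopulation`,
#'   `overlapping`).
#' @export
render_phase_movie <- function(tracks, scene, alpha = 1.8e-4, seed = NULL) {
  stopifnot(is.data.frame(tracks), inherits(scene, "scene_spec"))
  nr <- scene$image_shape[1]; nc <- scene$image_shape[2]
  px <- scene$pixel_size
  ids <- unique(tracks$cell_id)
  frames <- sort(unique(tracks$frame))

  with_seed(seed, {
    radius <- pmax(stats::rnorm(length(ids), scene$cell_radius_mean,
                                scene$cell_radius_sd),
                   scene$cell_radius_mean / 3)
    names(radius) <- as.character(ids)

    max_r <- max(radius)
    if (2 * max_r >= min(nr, nc) * px) stop("cell radii do not fit in the frame")

    phase <- vector("list", length(frames))
    labels <- vector("list", length(frames))
    truth <- vector("list", length(frames))
    # pixel-center coordinates in um (0-based pixel i has center (i + 0.5) px)
    for (fi in seq_along(frames)) {
      f <- frames[fi]
      sub <- tracks[tracks$frame == f, , drop = FALSE]
      img <- matrix(0, nr, nc)
      lab <- matrix(0L, nr, nc)
      overlapping <- logical(nrow(sub))
      for (ci in seq_len(nrow(sub))) {
        r_um <- radius[as.character(sub$cell_id[ci])]
        # clamp center so the footprint stays inside the frame
        cx <- min(max(sub$x_um[ci], r_um), nc * px - r_um)
        cy <- min(max(sub$y_um[ci], r_um), nr * px - r_um)
        j0 <- max(1L, floor((cx - r_um) / px)); j1 <- min(nc, ceiling((cx + r_um) / px) + 1L)
        i0 <- max(1L, floor((cy - r_um) / px)); i1 <- min(nr, ceiling((cy + r_um) / px) + 1L)
        jj <- j0:j1; ii <- i0:i1
        xc <- (jj - 0.5) * px; yc <- (ii - 0.5) * px
        d2 <- outer((yc - cy)^2, (xc - cx)^2, `+`)
        if (scene$phase_profile == "uniform-disk") {
          w <- (d2 <= r_um^2) * 1
        } else {
          s <- r_um / 2
          w <- exp(-d2 / (2 * s^2))
          w[d2 > r_um^2] <- 0
        }
        sw <- sum(w)
        if (sw == 0) next
        target <- phase_sum_for_mass(sub$mass_pg[ci], scene$wavelength,
                                     alpha, px^2)
        patch <- w * (target / sw)
        hit <- which(patch > 0, arr.ind = TRUE)
        gi <- ii[hit[, 1]]; gj <- jj[hit[, 2]]
        idx <- cbind(gi, gj)
        prev <- lab[idx]
        if (any(prev != 0L)) {
          overlapping[ci] <- TRUE
          overlapping[unique(prev[prev != 0L])] <- TRUE
        }
        img[idx] <- img[idx] + patch[hit]
        lab[idx] <- ci
      }
      if (scene$background_phase_sd > 0) {
        img <- img + matrix(stats::rnorm(nr * nc, 0, scene$background_phase_sd), nr, nc)
      }
      attr(img, "pixel_size") <- px
      attr(img, "wavelength") <- scene$wavelength
      phase[[fi]] <- img
      labels[[fi]] <- lab
      truth[[fi]] <- data.frame(cell_id = sub$cell_id, frame = f,
                                x_um = sub$x_um, y_um = sub$y_um,
                                mass_pg = sub$mass_pg,
                                subpopulation = sub$subpopulation,
                                overlapping = overlapping,
                                stringsAsFactors = FALSE)
    }
    list(phase = phase, labels = labels, truth = do.call(rbind, truth))
  })
}

#' Forward DPC model: phase frames to half-circle intensity images
#'
#' Generates the four half-circle-illumination intensity images that the
#' weak-object linear model predicts for each phase frame, using exactly the
#' transfer functions employed by [reconstruct_phase()], so the
#' forward/inverse pair round-trips. Intensities are
#' `I = background * (1 +/- c)` where `c` is the predicted DPC contrast of
#' the pair. Optional shot noise is Poisson at `photons` expected counts per
#' pixel. Phase values above ~1 rad violate the weak-object assumption and
#' trigger a warning.
#'
#' @param phase_frames List of phase matrices (radians).
#' @param optics An [optics_spec()].
#' @param background Mean background intensity (arbitrary units).
#' @param photons Expected photon count per pixel for shot noise; `Inf`
#'   (default) disables noise.
#' @param seed Optional seed for shot noise.
#' @return A list with one element per frame, each a list of matrices
#'   `top`, `bottom`, `left`, `right`.
#' @export
render_dpc_intensities <- function(phase_frames, optics, background = 1,
                                   photons = Inf, seed = NULL) {
  stopifnot(inherits(optics, "optics_spec"))
  if (is.matrix(phase_frames)) phase_frames <- list(phase_frames)
  dims <- dim(phase_frames[[1]])
  tf <- dpc_transfer_functions(dims, optics)
  if (max(vapply(phase_frames, function(p) max(abs(p)), numeric(1))) > 1) {
    warning("phase exceeds 1 rad; weak-object linear model may be inaccurate")
  }
  with_seed(seed, {
    lapply(phase_frames, function(phi) {
      stopifnot(all(dim(phi) == dims), all(is.finite(phi)))
      P <- stats::fft(phi)
      c_tb <- Re(stats::fft(tf$tb * P, inverse = TRUE)) / prod(dims)
      c_lr <- Re(stats::fft(tf$lr * P, inverse = TRUE)) / prod(dims)
      out <- list(top = background * (1 + c_tb),
                  bottom = background * (1 - c_tb),
                  left = background * (1 + c_lr),
                  right = background * (1 - c_lr))
      if (is.finite(photons)) {
        out <- lapply(out, function(I) {
          I_pos <- pmax(I, 0)
          matrix(stats::rpois(length(I), I_pos * photons) / photons,
                 nrow(I), ncol(I))
        })
      }
      out
    })
  })
}

#' Random band-limited phase test object
#'
#' Generates a smooth random phase map whose spectrum is confined to an
#' annulus of the frequency plane, expressed as fractions of the coherent
#' cutoff NA/lambda. Useful as a ground-truth object for forward/inverse
#' round-trip checks: DPC transfers no DC and attenuates the lowest
#' frequencies, so a quantitatively recoverable object must live in the
#' mid-band.
#'
#' @param dims Image dimensions (rows, cols); a scalar gives a square.
#' @param optics An [optics_spec()].
#' @param band Annulus (low, high) as fractions of the cutoff frequency.
#' @param amplitude Peak absolute phase, radians.
#' @param seed Optional seed.
#' @return Phase matrix (radians), zero-mean.
#' @export
bandlimited_phase <- function(dims, optics, band = c(0.1, 0.6),
                              amplitude = 0.3, seed = NULL) {
  stopifnot(inherits(optics, "optics_spec"), band[1] < band[2], band[1] > 0)
  dims <- rep(as.integer(dims), length.out = 2L)
  cutoff <- optics$numerical_aperture / (optics$wavelength * 1e-3)
  fy <- freq_axis(dims[1], optics$pixel_size)
  fx <- freq_axis(dims[2], optics$pixel_size)
  R <- sqrt(outer(fy^2, fx^2, `+`))
  with_seed(seed, {
    S <- matrix(complex(real = stats::rnorm(prod(dims)),
                        imaginary = stats::rnorm(prod(dims))),
                dims[1], dims[2])
    S[R < band[1] * cutoff | R > band[2] * cutoff] <- 0
    phi <- Re(stats::fft(S, inverse = TRUE)) / prod(dims)
    phi <- phi * amplitude / max(abs(phi))
    phi - mean(phi)
  })
}
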