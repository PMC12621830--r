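# fftfreq-style frequency axis in cycles/um for an n-pixel axis.
freq_axis <- function(n, pixel_size) {
  k <- c(0:(ceiling(n / 2) - 1L), -(floor(n / 2):1))
  k / (n * pixel_size)
}

#' Weak-object phase transfer functions for half-circle DPC
#'
#' Computes, on the discrete frequency grid of an image, the linear transfer
#' function mapping a weak object's phase spectrum to the DPC contrast
#' spectrum of each half-circle illumination pair (top/bottom and
#' left/right). The pupil is a circular aperture of cutoff NA/lambda and the
#' source a matched-NA half disk; the transfer function is the normalized
#' antisymmetric part of the source-pupil cross-correlation, evaluated
#' numerically by FFT. Both the forward model
#' ([render_dpc_intensities()]) and the inverse ([reconstruct_phase()]) use
#' these functions.
#'
#' @param dims Image dimensions (rows, cols).
#' @param optics An [optics_spec()].
#' @return List with complex matrices `tb` and `lr` (purely imaginary,
#'   antisymmetric), in FFT index order.
#' @export
dpc_transfer_functions <- function(dims, optics) {
  stopifnot(inherits(optics, "optics_spec"), length(dims) == 2L)
  lambda_um <- optics$wavelength * 1e-3
  cutoff <- optics$numerical_aperture / lambda_um
  fy <- freq_axis(dims[1], optics$pixel_size)  # rows
  fx <- freq_axis(dims[2], optics$pixel_size)  # cols
  FY <- matrix(fy, dims[1], dims[2])
  FX <- matrix(fx, dims[1], dims[2], byrow = TRUE)
  rho <- sqrt(FX^2 + FY^2)
  pupil <- (rho <= cutoff) * 1
  if (sum(pupil) < 5) stop("degenerate optics: pupil covers almost no frequency samples")

  half_tf <- function(src) {
    # A(u) = sum_v S(v) P(v) P(v+u), via the cross-correlation theorem
    SP <- stats::fft(src * pupil)
    Pf <- stats::fft(pupil)
    A <- Re(stats::fft(Conj(SP) * Pf, inverse = TRUE)) / length(pupil)
    B <- sum(src * pupil^2)               # background brightness of this half
    # A(-u): index reversal on the periodic grid
    Aneg <- A[c(1L, rev(seq_len(dims[1])[-1L])), c(1L, rev(seq_len(dims[2])[-1L]))]
    # contrast TF of the pair (I_a - I_b)/(I_a + I_b): i (A(u) - A(-u)) / B
    (1i) * (A - Aneg) / B
  }
  list(tb = half_tf((FY > 0) * 1), lr = half_tf((FX > 0) * 1))
}

#' DPC contrast of an illumination pair
#'
#' @param i_a,i_b Intensity images of complementary half-circle
#'   illuminations (same dimensions).
#' @return `(i_a - i_b) / (i_a + i_b)`; pixels where the sum is not
#'   strictly positive are set to 0, flagged in the `masked` attribute, and
#'   reported with a warning.
#' @export
dpc_contrast <- function(i_a, i_b) {
  stopifnot(is.matrix(i_a), all(dim(i_a) == dim(i_b)))
  s <- i_a + i_b
  bad <- !(s > 0) | !is.finite(s)
  out <- matrix(0, nrow(i_a), ncol(i_a))
  out[!bad] <- (i_a[!bad] - i_b[!bad]) / s[!bad]
  if (any(bad)) {
    warning(sprintf("%d pixel(s) with non-positive total intensity masked", sum(bad)))
  }
  attr(out, "masked") <- bad
  out
}

#' Tikhonov-regularized phase reconstruction from DPC contrasts
#'
#' Joint least-squares inversion of two (or more) orthogonal DPC contrast
#' images: `phi_hat = IFFT[ sum_j conj(H_j) C_j / (sum_j |H_j|^2 + beta) ]`
#' with the regularization parameter beta (default 1e-3) stabilizing
#' frequencies where the transfer functions vanish. The DC component, which
#' DPC does not transfer, is set to zero.
#'
#' @param contrasts List of contrast matrices (e.g. `list(tb = ..., lr = ...)`),
#'   in the same order as `tfs`.
#' @param optics An [optics_spec()]; `optics$regularization_beta` is used
#'   unless `beta` is given.
#' @param tfs Transfer functions from [dpc_transfer_functions()]; computed
#'   from `optics` when NULL.
#' @param beta Optional override of the regularization parameter.
#' @return Phase matrix (radians) with `pixel_size` and `wavelength`
#'   attributes.
#' @export
reconstruct_phase <- function(contrasts, optics, tfs = NULL, beta = NULL) {
  stopifnot(inherits(optics, "optics_spec"))
  if (is.matrix(contrasts)) contrasts <- list(contrasts)
  if (length(contrasts) < 1L) stop("at least one contrast image required")
  dims <- dim(contrasts[[1]])
  if (is.null(tfs)) tfs <- dpc_transfer_functions(dims, optics)
  tfs <- tfs[seq_along(contrasts)]
  beta <- beta %||% optics$regularization_beta
  if (beta <= 0) stop("beta must be > 0")
  denom_sum <- Reduce(`+`, lapply(tfs, function(H) Mod(H)^2))
  if (max(denom_sum) == 0) stop("all transfer functions are zero: degenerate optics")
  num <- Reduce(`+`, Map(function(C, H) {
    stopifnot(all(dim(C) == dims))
    Conj(H) * stats::fft(C)
  }, contrasts, tfs))
  spec <- num / (denom_sum + beta)
  spec[1, 1] <- 0 + 0i
  phi <- Re(stats::fft(spec, inverse = TRUE)) / prod(dims)
  attr(phi, "pixel_size") <- optics$pixel_size
  attr(phi, "wavelength") <- optics$wavelength
  phi
}

#' Reconstruct phase directly from four half-circle intensities
#'
#' Convenience wrapper: forms the top/bottom and left/right DPC contrasts
#' and applies [reconstruct_phase()].
#'
#' @param intensities List with matrices `top`, `bottom`, `left`, `right`.
#' @inheritParams reconstruct_phase
#' @return Phase matrix (radians).
#' @export
dpc_reconstruct <- function(intensities, optics, tfs = NULL, beta = NULL) {
  stopifnot(all(c("top", "bottom", "left", "right") %in% names(intensities)))
  contrasts <- list(tb = dpc_contrast(intensities$top, intensities$bottom),
                    lr = dpc_contrast(intensities$left, intensities$right))
  reconstruct_phase(contrasts, optics, tfs = tfs, beta = beta)
}
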