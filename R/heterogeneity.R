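# Shared evaluation grid for a set of SGR samples: pooled range padded by
# `pad_bw` bandwidths.
kde_grid <- function(samples, kde) {
  rng <- range(unlist(samples), finite = TRUE)
  pad <- kde$pad_bw * kde$bandwidth
  seq(rng[1] - pad, rng[2] + pad, length.out = kde$n_grid)
}

#' Kernel density estimate of an SGR sample
#'
#' Gaussian-kernel density on a fixed grid, normalized to unit integral
#' (trapezoidal rule). The default bandwidth of 0.0025 1/h matches the
#' scale of single-cell SGR distributions.
#'
#' @param x SGR samples, 1/h (>= 2 values).
#' @param kde A [kde_params()].
#' @param grid Optional explicit grid (overrides the automatic one); use a
#'   shared grid when densities will be compared.
#' @return `data.frame` with `x` (grid) and `y` (density); bandwidth kept
#'   as attribute `bandwidth`.
#' @export
kde_density <- function(x, kde = kde_params(), grid = NULL) {
  stopifnot(inherits(kde, "kde_params"))
  x <- x[is.finite(x)]
  if (length(x) < 2L) stop("need >= 2 samples for a density estimate")
  if (stats::sd(x) == 0) {
    warning("degenerate sample (all values equal); density is delta-like")
  }
  if (is.null(grid)) grid <- kde_grid(list(x), kde)
  d <- stats::density(x, bw = kde$bandwidth, kernel = "gaussian",
                      from = grid[1], to = grid[length(grid)],
                      n = length(grid))
  y <- d$y
  dx <- diff(grid)
  area <- sum((y[-1] + y[-length(y)]) / 2 * dx)
  if (area > 0) y <- y / area
  out <- data.frame(x = grid, y = y)
  attr(out, "bandwidth") <- kde$bandwidth
  out
}

#' Hellinger distance between two densities on a common grid
#'
#' `H = sqrt(1 - integral sqrt(p q) dx)`, in [0, 1]: 0 for identical
#' densities, 1 for disjoint supports. Inputs off unit integral by more
#' than 1e-6 are renormalized with a warning.
#'
#' @param p,q Densities: `data.frame`s with `x`, `y` (as from
#'   [kde_density()]) on the same grid, or plain vectors with `grid`
#'   supplied.
#' @param grid Grid values when `p`, `q` are plain vectors.
#' @return Hellinger distance in [0, 1].
#' @export
hellinger_distance <- function(p, q, grid = NULL) {
  if (is.data.frame(p)) { grid <- p$x; p <- p$y }
  if (is.data.frame(q)) {
    if (!isTRUE(all.equal(grid, q$x))) stop("densities must share a grid")
    q <- q$y
  }
  stopifnot(length(p) == length(q), length(p) == length(grid))
  trapz <- function(y) sum((y[-1] + y[-length(y)]) / 2 * diff(grid))
  for (nm in c("p", "q")) {
    y <- get(nm)
    a <- trapz(y)
    if (abs(a - 1) > 1e-6) {
      warning(sprintf("density '%s' integrates to %.4g; renormalizing", nm, a))
      assign(nm, y / a)
    }
  }
  bc <- trapz(sqrt(pmax(p, 0) * pmax(q, 0)))
  sqrt(min(max(1 - bc, 0), 1))
}

# Per-window-center Hellinger distances between two windowed SGR tables.
windowed_hellinger <- function(win_a, win_b, kde) {
  centers <- sort(intersect(unique(win_a$window_center),
                            unique(win_b$window_center)))
  if (!length(centers)) stop("window grids do not overlap")
  h <- vapply(centers, function(cen) {
    a <- win_a$sgr[win_a$window_center == cen]
    b <- win_b$sgr[win_b$window_center == cen]
    if (length(a) < 2L || length(b) < 2L) return(NA_real_)
    grid <- kde_grid(list(a, b), kde)
    hellinger_distance(kde_density(a, kde, grid), kde_density(b, kde, grid))
  }, numeric(1))
  data.frame(window_center = centers, hellinger = h)
}

#' Response threshold from two on-plate control groups
#'
#' The maximum windowed Hellinger distance between the SGR distributions
#' of the two vehicle control groups: the largest divergence attributable
#' to sampling and plate effects alone. Treated wells must exceed this to
#' count as responding.
#'
#' @param control_a,control_b Windowed SGR tables (from [windowed_sgr()])
#'   for the two control groups.
#' @param kde A [kde_params()].
#' @return Threshold (scalar); per-window distances in attribute `series`.
#' @export
control_threshold <- function(control_a, control_b, kde = kde_params()) {
  if (is.null(control_a) || is.null(control_b) ||
      nrow(control_a) == 0L || nrow(control_b) == 0L) {
    stop("two non-empty control groups are required")
  }
  ser <- windowed_hellinger(control_a, control_b, kde)
  thr <- max(ser$hellinger, na.rm = TRUE)
  attr(thr, "series") <- ser
  thr
}

#' Time of response from windowed Hellinger distances
#'
#' Computes the Hellinger distance between treated and control SGR
#' distributions at each window center, fits the saturating exponential
#' `H(t) = H_inf (1 - exp(-t / tau))` (zero at t = 0, plateau H_inf <= 1),
#' and reports the time at which the fitted curve crosses the
#' control-derived threshold:
#' `ToR = -tau log(1 - threshold / H_inf)`. When the plateau never exceeds
#' the threshold the population is non-responsive and ToR is undefined
#' (NA).
#'
#' @param treated,control Windowed SGR tables ([windowed_sgr()]).
#' @param threshold Response threshold, typically [control_threshold()].
#' @param kde A [kde_params()].
#' @return Object of class `tor_fit`: `series` (window centers and
#'   distances), `h_inf`, `tau`, `threshold`, `tor` (h, or NA),
#'   `responded`, `converged`.
#' @export
time_of_response <- function(treated, control, threshold,
                             kde = kde_params()) {
  ser <- windowed_hellinger(treated, control, kde)
  ok <- is.finite(ser$hellinger)
  if (sum(ok) < 3L) stop("need >= 3 windows with defined Hellinger distance")
  t <- ser$window_center[ok]; h <- ser$hellinger[ok]
  # profiled least squares: for fixed tau the optimal plateau is linear,
  # hinf(tau) = sum(h g)/sum(g^2) with g = 1 - exp(-t/tau), clipped to
  # (0, 1]; the 1-D profile over log tau is searched on a coarse grid and
  # polished with optimize(). This stays well-behaved in the
  # instantaneous-response limit tau -> 0 where a joint Gauss-Newton
  # gradient is singular.
  hinf_of <- function(tau) {
    g <- 1 - exp(-t / tau)
    min(max(sum(h * g) / sum(g^2), 1e-6), 1)
  }
  sse <- function(ltau) {
    tau <- exp(ltau)
    g <- 1 - exp(-t / tau)
    sum((h - hinf_of(tau) * g)^2)
  }
  lgrid <- seq(log(0.1), log(1e4), length.out = 80L)
  vals <- vapply(lgrid, sse, numeric(1))
  i <- which.min(vals)
  br <- c(lgrid[max(1L, i - 1L)], lgrid[min(length(lgrid), i + 1L)])
  opt <- stats::optimize(sse, br)
  tau <- exp(opt$minimum)
  h_inf <- hinf_of(tau)
  converged <- TRUE
  tor <- if (threshold < h_inf) -tau * log(1 - threshold / h_inf) else NA_real_
  structure(list(series = ser, h_inf = h_inf, tau = tau,
                 threshold = unclass(threshold), tor = tor,
                 responded = is.finite(tor), converged = converged),
            class = "tor_fit")
}

#' @export
print.tor_fit <- function(x, ...) {
  cat("Time-of-response (Hellinger) fit\n")
  cat(sprintf("  windows: %d, H_inf = %.3g, tau = %.3g h, threshold = %.3g\n",
              nrow(x$series), x$h_inf, x$tau, x$threshold))
  cat(if (x$responded) sprintf("  ToR = %.2f h\n", x$tor)
      else "  ToR undefined (fitted curve never crosses the threshold)\n")
  invisible(x)
}

#' @export
plot.tor_fit <- function(x, ...) {
  graphics::plot(x$series$window_center, x$series$hellinger,
                 xlab = "time (h)", ylab = "Hellinger distance",
                 ylim = c(0, 1), ...)
  if (x$converged) {
    tt <- seq(0, max(x$series$window_center), length.out = 200)
    graphics::lines(tt, x$h_inf * (1 - exp(-tt / x$tau)))
  }
  graphics::abline(h = x$threshold, lty = 2)
  if (x$responded) graphics::abline(v = x$tor, lty = 3)
  invisible(x)
}

# Two-Gaussian mixture curve in the amplitude parameterization
# y = A [ f exp(-((x - mu_s)/sigma_s)^2) + (1 - f) exp(-((x - mu_n)/sigma_n)^2) ].
# Note exp(-((x-mu)/sigma)^2) has standard deviation sigma/sqrt(2).
two_gauss <- function(x, a, f, mu_s, sigma_s, mu_n, sigma_n) {
  a * (f * exp(-((x - mu_s) / sigma_s)^2) +
       (1 - f) * exp(-((x - mu_n) / sigma_n)^2))
}

# Fit the two-Gaussian curve to a KDE trace by least squares.
fit_two_gaussians <- function(dens, init) {
  env <- list2env(list(x = dens$x, y = dens$y))
  fit <- try(minpack.lm::nlsLM(
    y ~ a * (f * exp(-((x - mu_s) / sigma_s)^2) +
             (1 - f) * exp(-((x - mu_n) / sigma_n)^2)),
    start = init,
    lower = c(a = 0, f = 0, mu_s = -Inf, sigma_s = 1e-6,
              mu_n = -Inf, sigma_n = 1e-6),
    upper = c(a = Inf, f = 1, mu_s = Inf, sigma_s = Inf,
              mu_n = Inf, sigma_n = Inf),
    data = env,
    control = minpack.lm::nls.lm.control(maxiter = 400)), silent = TRUE)
  if (inherits(fit, "try-error")) return(NULL)
  cf <- as.list(stats::coef(fit))
  # responsive component is the lower-SGR one; relabel if needed
  if (cf$mu_s > cf$mu_n) {
    cf <- list(a = cf$a, f = 1 - cf$f, mu_s = cf$mu_n, sigma_s = cf$sigma_n,
               mu_n = cf$mu_s, sigma_n = cf$sigma_s)
  }
  yhat <- two_gauss(dens$x, cf$a, cf$f, cf$mu_s, cf$sigma_s, cf$mu_n, cf$sigma_n)
  sst <- sum((dens$y - mean(dens$y))^2)
  cf$r2 <- if (sst > 0) 1 - sum((dens$y - yhat)^2) / sst else NA_real_
  cf
}

#' Sequentially initialized two-Gaussian mixture over time
#'
#' For each window center, smooths the SGR sample with KDE and fits a sum
#' of two Gaussians
#' `y = A [ f exp(-((x - mu_s)/sigma_s)^2) + (1-f) exp(-((x - mu_n)/sigma_n)^2) ]`
#' with `f` the sensitive (responsive, lower-SGR) fraction. The first
#' window is initialized from the KDE amplitude and the overall median and
#' standard deviation (`mu_s0 = m - s/2`, `mu_n0 = m + s/2`,
#' `sigma_0 = s`); each later window is warm-started from the previous
#' fit, so component identities track through time. A window whose fit
#' fails carries the previous parameters forward with a flag; windows
#' where the components collapse onto each other (separation below the
#' mean component width) are flagged unidentifiable.
#'
#' @param windowed Windowed SGR table ([windowed_sgr()]) for one
#'   condition.
#' @param kde A [kde_params()].
#' @param min_cells Windows with fewer samples are skipped.
#' @return Object of class `mixture_timecourse`: a `data.frame` with one
#'   row per window (`window_center`, `a`, `f`, `mu_s`, `sigma_s`,
#'   `mu_n`, `sigma_n`, `r2`, `fraction_nonresponsive`, `identifiable`,
#'   `carried_forward`).
#' @export
fit_mixture_sequence <- function(windowed, kde = kde_params(),
                                 min_cells = 20L) {
  centers <- sort(unique(windowed$window_center))
  prev <- NULL
  rows <- vector("list", length(centers))
  for (i in seq_along(centers)) {
    cen <- centers[i]
    x <- windowed$sgr[windowed$window_center == cen]
    if (length(x) < min_cells) next
    dens <- kde_density(x, kde)
    if (is.null(prev)) {
      m_all <- stats::median(x); s_all <- stats::sd(x)
      init <- list(a = max(dens$y), f = 0.5,
                   mu_s = m_all - s_all / 2, sigma_s = s_all,
                   mu_n = m_all + s_all / 2, sigma_n = s_all)
    } else {
      init <- prev[c("a", "f", "mu_s", "sigma_s", "mu_n", "sigma_n")]
    }
    cf <- fit_two_gaussians(dens, init)
    carried <- is.null(cf)
    if (carried) {
      if (is.null(prev)) next  # nothing to carry at the first fittable window
      cf <- prev
    }
    prev <- cf[c("a", "f", "mu_s", "sigma_s", "mu_n", "sigma_n", "r2")]
    # bimodality condition: component means separated by at least the sum
    # of the component standard deviations (sd_i = sigma_i / sqrt(2) in
    # this parameterization)
    identifiable <- abs(cf$mu_n - cf$mu_s) >=
      (cf$sigma_s + cf$sigma_n) / sqrt(2)
    rows[[i]] <- data.frame(window_center = cen, a = cf$a, f = cf$f,
                            mu_s = cf$mu_s, sigma_s = cf$sigma_s,
                            mu_n = cf$mu_n, sigma_n = cf$sigma_n,
                            r2 = cf$r2,
                            fraction_nonresponsive = 1 - cf$f,
                            identifiable = identifiable,
                            carried_forward = carried)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) stop("no window had enough cells for a mixture fit")
  rownames(out) <- NULL
  class(out) <- c("mixture_timecourse", "data.frame")
  out
}

#' @export
print.mixture_timecourse <- function(x, ...) {
  cat(sprintf("Two-Gaussian mixture timecourse over %d windows\n", nrow(x)))
  cat(sprintf("  non-responsive fraction: %.2f -> %.2f\n",
              x$fraction_nonresponsive[1L],
              x$fraction_nonresponsive[nrow(x)]))
  if (any(!x$identifiable)) {
    cat(sprintf("  %d window(s) with unidentifiable split (components overlap)\n",
                sum(!x$identifiable)))
  }
  print.data.frame(utils::head(as.data.frame(x), 10L), digits = 3)
  invisible(x)
}

#' @export
plot.mixture_timecourse <- function(x, ...) {
  graphics::plot(x$window_center, x$fraction_nonresponsive, type = "b",
                 ylim = c(0, 1), xlab = "time (h)",
                 ylab = "non-responsive fraction", ...)
  invisible(x)
}
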