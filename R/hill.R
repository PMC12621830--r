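#' Hill dose-response model for specific growth rate
#'
#' `SGR(C) = Emax + (E0 - Emax) / (1 + (C / EC50)^HS)`, with `E0` the
#' low-dose (control-side) asymptote, `Emax` the high-dose asymptote,
#' `EC50` the inflection concentration and `HS` the Hill slope. `C = 0`
#' returns `E0` exactly; `C = EC50` returns the midpoint `(E0 + Emax)/2`.
#'
#' @param c Concentration(s), >= 0.
#' @param e0,emax Asymptotic SGRs, 1/h.
#' @param ec50 Half-effect concentration (> 0).
#' @param hs Hill slope (> 0).
#' @return SGR value(s), 1/h.
#' @export
hill_model <- function(c, e0, emax, ec50, hs) {
  stopifnot(all(c >= 0), ec50 > 0, hs > 0)
  emax + (e0 - emax) / (1 + (c / ec50)^hs)
}

#' Fit a Hill curve to mean SGR versus dose
#'
#' Nonlinear least squares over (E0, Emax, log10 EC50, HS) with
#' Levenberg-Marquardt (`minpack.lm::nlsLM`). Initialization: E0 from the
#' lowest-dose mean, Emax from the highest-dose mean, EC50 at the geometric
#' mid-dose, HS = 1; EC50 is bounded within [min positive dose / 100,
#' max dose * 100] and HS within (0, 10]. Vehicle controls enter as
#' dose 0, which the model handles analytically (SGR(0) = E0). The fit is
#' flagged degenerate when it does not converge, when the fitted amplitude
#' |E0 - Emax| is below twice the residual RMSE (flat response), or when
#' E0 is not significantly positive, in which case the depth of response
#' is undefined.
#'
#' @param doses Concentrations (>= 0), at least 4 distinct values.
#' @param mean_sgrs Mean SGR per dose, 1/h.
#' @param weights Optional fit weights (e.g. 1/SEM^2).
#' @param fix_hs Fix the Hill slope at this value (e.g. 1 for the
#'   3-parameter model); NULL (default) fits it.
#' @return Object of class `hill_fit`: coefficients (`e0`, `emax`, `ec50`,
#'   `hs`), `dor`, standard errors, residuals, convergence and
#'   identifiability flags.
#' @export
fit_hill <- function(doses, mean_sgrs, weights = NULL, fix_hs = NULL) {
  stopifnot(length(doses) == length(mean_sgrs), all(doses >= 0),
            all(is.finite(mean_sgrs)))
  if (length(unique(doses)) < 4L) stop("need >= 4 distinct doses")
  pos <- doses[doses > 0]
  o <- order(doses)
  d <- doses[o]; y <- mean_sgrs[o]
  w <- if (is.null(weights)) rep(1, length(d)) else weights[o]

  lo_d <- min(pos); hi_d <- max(pos)
  start <- list(e0 = mean(y[d == min(d)]), emax = mean(y[d == max(d)]),
                lec50 = log10(sqrt(lo_d * hi_d)))
  lower <- c(e0 = -Inf, emax = -Inf, lec50 = log10(lo_d) - 2)
  upper <- c(e0 = Inf, emax = Inf, lec50 = log10(hi_d) + 2)
  if (is.null(fix_hs)) {
    form <- y ~ emax + (e0 - emax) / (1 + (d / 10^lec50)^hs)
    start$hs <- 1
    lower <- c(lower, hs = 1e-2)
    upper <- c(upper, hs = 10)
  } else {
    stopifnot(fix_hs > 0)
    form <- y ~ emax + (e0 - emax) / (1 + (d / 10^lec50)^fix_hs)
  }
  env <- list2env(list(d = d, y = y, fix_hs = fix_hs))
  fit <- try(minpack.lm::nlsLM(form, start = start, lower = lower,
                               upper = upper, weights = w,
                               data = env,
                               control = minpack.lm::nls.lm.control(maxiter = 200)),
             silent = TRUE)
  converged <- !inherits(fit, "try-error")
  if (!converged) {
    cf <- c(unlist(start), if (is.null(fix_hs)) NULL)
    est <- c(e0 = unname(cf["e0"]), emax = unname(cf["emax"]),
             ec50 = unname(10^cf["lec50"]), hs = fix_hs %||% 1)
    se <- rep(NA_real_, 4L)
    fitted <- hill_model(d, est["e0"], est["emax"], est["ec50"], est["hs"])
  } else {
    cf <- stats::coef(fit)
    est <- c(e0 = unname(cf["e0"]), emax = unname(cf["emax"]),
             ec50 = unname(10^cf["lec50"]),
             hs = if (is.null(fix_hs)) unname(cf["hs"]) else fix_hs)
    se_t <- try(summary(fit)$coefficients[, "Std. Error"], silent = TRUE)
    if (inherits(se_t, "try-error")) se_t <- rep(NA_real_, length(cf))
    se <- c(se_t["e0"], se_t["emax"],
            log(10) * est["ec50"] * se_t["lec50"],  # delta method to EC50 scale
            if (is.null(fix_hs)) se_t["hs"] else NA_real_)
    fitted <- stats::fitted(fit)
  }
  resid <- y - fitted
  rmse <- sqrt(mean(resid^2))
  amplitude <- abs(est["e0"] - est["emax"])
  flat <- amplitude < 2 * rmse
  ec50_at_bound <- converged &&
    (abs(log10(est["ec50"]) - (log10(lo_d) - 2)) < 1e-6 ||
     abs(log10(est["ec50"]) - (log10(hi_d) + 2)) < 1e-6)
  # EC50 is unidentifiable when its CI spans more than two decades
  se_lec50 <- if (converged && !inherits(se_t, "try-error")) {
    unname(se_t["lec50"])
  } else NA_real_
  ec50_imprecise <- is.finite(se_lec50) && se_lec50 > 1
  e0_se <- se[1L]
  baseline_ok <- est["e0"] > 0 &&
    (is.na(e0_se) || est["e0"] > 2 * e0_se)
  dor <- if (baseline_ok) unname((est["e0"] - est["emax"]) / est["e0"]) else NA_real_
  structure(list(
    coefficients = est,
    se = stats::setNames(unname(se), c("e0", "emax", "ec50", "hs")),
    dor = dor,
    data = data.frame(dose = d, sgr = y, fitted = fitted, residual = resid),
    rmse = rmse, r2 = if (stats::var(y) > 0) 1 - sum(resid^2) / sum((y - mean(y))^2) else NA_real_,
    converged = converged,
    se_log10_ec50 = se_lec50,
    ec50_identifiable = converged && !flat && !ec50_at_bound && !ec50_imprecise,
    dor_defined = baseline_ok,
    degenerate = !converged || flat || !baseline_ok || ec50_at_bound ||
      ec50_imprecise,
    flags = c(flat = unname(flat), ec50_at_bound = ec50_at_bound,
              ec50_imprecise = ec50_imprecise,
              weak_baseline = !baseline_ok),
    fix_hs = fix_hs),
    class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("Hill dose-response fit\n")
  cat(sprintf("  E0   = %.4g 1/h\n  Emax = %.4g 1/h\n  EC50 = %.4g\n  HS   = %.3g%s\n",
              x$coefficients["e0"], x$coefficients["emax"],
              x$coefficients["ec50"], x$coefficients["hs"],
              if (!is.null(x$fix_hs)) " (fixed)" else ""))
  cat(sprintf("  DoR  = %s\n",
              if (is.na(x$dor)) "undefined (baseline not significantly positive)"
              else sprintf("%.3g", x$dor)))
  cat(sprintf("  RMSE = %.3g, R2 = %.3g, n = %d doses\n", x$rmse,
              x$r2 %||% NA, nrow(x$data)))
  if (x$degenerate) {
    cat("  ** degenerate fit:",
        paste(names(x$flags)[x$flags], collapse = ", "),
        if (!x$converged) "no convergence", "\n")
  }
  invisible(x)
}

#' @export
coef.hill_fit <- function(object, ...) object$coefficients

#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$data$dose
       else if (is.data.frame(newdata)) newdata$dose else newdata
  cf <- object$coefficients
  unname(hill_model(d, cf[["e0"]], cf[["emax"]], cf[["ec50"]], cf[["hs"]]))
}

#' @export
residuals.hill_fit <- function(object, ...) object$data$residual

#' @export
plot.hill_fit <- function(x, ...) {
  dat <- x$data
  pos <- dat$dose > 0
  xr <- range(dat$dose[pos])
  grid <- 10^seq(log10(xr[1] / 10), log10(xr[2] * 10), length.out = 200)
  graphics::plot(dat$dose[pos], dat$sgr[pos], log = "x",
                 xlab = "dose", ylab = "SGR (1/h)", ...)
  graphics::lines(grid, predict(x, grid))
  cf <- x$coefficients
  graphics::abline(v = cf["ec50"], lty = 2)
  if (any(!pos)) {
    graphics::points(rep(xr[1] / 10, sum(!pos)), dat$sgr[!pos], pch = 1)
  }
  invisible(x)
}

#' Depth of response of a Hill fit
#'
#' `DoR = (E0 - Emax) / E0`: 0 for no effect, 1 for complete growth
#' arrest, > 1 for net mass loss at high dose. Undefined when E0 = 0.
#'
#' @param fit A `hill_fit`, or the value of `e0` when `emax` is given.
#' @param emax High-dose asymptote (when `fit` is numeric `e0`).
#' @return Dimensionless depth of response.
#' @export
depth_of_response <- function(fit, emax = NULL) {
  if (inherits(fit, "hill_fit")) return(fit$dor)
  e0 <- fit
  if (e0 == 0) stop("depth of response undefined for e0 = 0")
  (e0 - emax) / e0
}

#' Lin's concordance correlation coefficient
#'
#' `rho_c = 2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)` with
#' population (1/n) moments: agreement of two paired measurement series
#' around the identity line.
#'
#' @param x,y Equal-length numeric vectors, n >= 3.
#' @return Concordance coefficient in [-1, 1].
#' @export
concordance <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L,
            all(is.finite(x)), all(is.finite(y)))
  n <- length(x)
  vx <- stats::var(x) * (n - 1) / n
  vy <- stats::var(y) * (n - 1) / n
  cxy <- stats::cov(x, y) * (n - 1) / n
  denom <- vx + vy + (mean(x) - mean(y))^2
  if (denom == 0) stop("concordance undefined: zero total variance")
  2 * cxy / denom
}

#' Mean SGR per dose with SEM
#'
#' Pools per-cell SGR records per condition and dose: the pooled mean is
#' used for the Hill fit, while per-replicate (well) means provide the SEM.
#'
#' @param records SGR table with `sgr`, `dose` and optionally `well`.
#' @return `data.frame`: `dose`, `mean_sgr`, `sem`, `n_cells`.
#' @export
sgr_by_dose <- function(records) {
  stopifnot(all(c("sgr", "dose") %in% names(records)))
  s <- split(records, records$dose)
  rows <- lapply(s, function(df) {
    sem <- if ("well" %in% names(df) && length(unique(df$well)) > 1L) {
      rm <- vapply(split(df$sgr, df$well), mean, numeric(1))
      stats::sd(rm) / sqrt(length(rm))
    } else {
      stats::sd(df$sgr) / sqrt(nrow(df))
    }
    data.frame(dose = df$dose[1L], mean_sgr = mean(df$sgr), sem = sem,
               n_cells = nrow(df))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$dose), ]
  rownames(out) <- NULL
  out
}
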