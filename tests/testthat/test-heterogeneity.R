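kp <- kde_params()  # bandwidth 0.0025 1/h

# exact discretized Gaussian densities on a common grid
gauss_pair <- function(d, s = 0.02, n_grid = 2001L) {
  g <- seq(-6 * s, d + 6 * s, length.out = n_grid)
  list(p = data.frame(x = g, y = dnorm(g, 0, s)),
       q = data.frame(x = g, y = dnorm(g, d, s)))
}

test_that("hellinger_distance matches the equal-variance Gaussian closed form", {
  for (r in c(0, 0.5, 1, 2, 4, 6)) {
    gp <- gauss_pair(r * 0.02)
    expect_equal(hellinger_distance(gp$p, gp$q),
                 sqrt(1 - exp(-r^2 / 8)), tolerance = 1e-4)
  }
  # the worked value: means 0 and 2, unit variance
  g <- seq(-8, 10, length.out = 4001)
  H <- hellinger_distance(data.frame(x = g, y = dnorm(g, 0, 1)),
                          data.frame(x = g, y = dnorm(g, 2, 1)))
  expect_equal(H, sqrt(1 - exp(-0.5)), tolerance = 1e-3)
})

test_that("hellinger_distance is symmetric, bounded, and exact at the extremes", {
  gp <- gauss_pair(0.03)
  expect_equal(hellinger_distance(gp$p, gp$q),
               hellinger_distance(gp$q, gp$p))
  expect_lt(hellinger_distance(gp$p, gp$p), 1e-3)
  # disjoint supports
  g <- seq(0, 1, length.out = 500)
  trapz <- function(y) sum((y[-1] + y[-length(y)]) / 2 * diff(g))
  p <- ifelse(g < 0.4, 5, 0); q <- ifelse(g > 0.6, 5, 0)
  expect_equal(hellinger_distance(p / trapz(p), q / trapz(q), grid = g), 1)
  # unnormalized inputs are renormalized with a warning
  expect_warning(h <- hellinger_distance(gp$p$y * 2, gp$q$y, grid = gp$p$x),
                 "renormaliz")
  expect_equal(h, hellinger_distance(gp$p, gp$q), tolerance = 1e-6)
})

test_that("triangle inequality holds on random density triples", {
  set.seed(41)
  g <- seq(-0.05, 0.05, length.out = 401)
  for (i in 1:5) {
    mk <- function() {
      y <- dnorm(g, runif(1, -0.02, 0.02), runif(1, 0.003, 0.02))
      data.frame(x = g, y = y / sum((y[-1] + y[-length(y)]) / 2 * diff(g)))
    }
    a <- mk(); b <- mk(); c <- mk()
    expect_lte(hellinger_distance(a, c),
               hellinger_distance(a, b) + hellinger_distance(b, c) + 1e-12)
  }
})

test_that("sample-based KDE Hellinger tracks the closed form to within 0.03", {
  s <- 0.02
  errs <- vapply(c(0, 1, 3, 6), function(r) {
    set.seed(500 + r)
    a <- rnorm(1e4, 0, s); b <- rnorm(1e4, r * s, s)
    g <- mqpi:::kde_grid(list(a, b), kp)
    h <- hellinger_distance(kde_density(a, kp, g), kde_density(b, kp, g))
    abs(h - sqrt(1 - exp(-r^2 / 8)))
  }, numeric(1))
  expect_lt(max(errs), 0.03)
})

test_that("kde_density is normalized and localizes the mode", {
  set.seed(6)
  x <- rnorm(1e4, 0, 0.01)
  d <- kde_density(x, kp)
  area <- sum((d$y[-1] + d$y[-nrow(d)]) / 2 * diff(d$x))
  expect_equal(area, 1, tolerance = 1e-6)
  expect_lt(abs(d$x[which.max(d$y)]), 0.002)
  # wider bandwidth smooths: variance of the density increases
  v <- function(dd) {
    w <- dd$y / sum(dd$y); m <- sum(w * dd$x); sum(w * (dd$x - m)^2)
  }
  d2 <- kde_density(x, kde_params(bandwidth = 0.01), grid = d$x)
  expect_gt(v(d2), v(d))
  expect_error(kde_density(0.01), ">= 2 samples")
  expect_warning(kde_density(rep(0.01, 5), kp), "degenerate")
})

test_that("control threshold is the maximum windowed control-control distance", {
  wa <- sim_windows(801, n = 80)
  wb <- sim_windows(802, n = 80)
  thr <- control_threshold(wa, wb, kp)
  ser <- attr(thr, "series")
  expect_equal(as.numeric(thr), max(ser$hellinger, na.rm = TRUE))
  expect_gt(as.numeric(thr), 0)
  expect_lt(as.numeric(thr), 0.5)
  # identical windows in both groups -> zero threshold
  expect_equal(as.numeric(control_threshold(wa, wa, kp)), 0)
  expect_error(control_threshold(wa[0, ], wb, kp), "control groups")
})

test_that("ToR is undefined when treated equals control", {
  w <- sim_windows(803, n = 80)
  tf <- time_of_response(w, w, threshold = 0.05, kde = kp)
  expect_false(tf$responded)
  expect_true(is.na(tf$tor))
  expect_true(all(tf$series$hellinger < 1e-6))
})

test_that("ToR decreases with dose when the response delay shrinks", {
  wa <- sim_windows(804); wb <- sim_windows(805)
  thr <- control_threshold(wa, wb, kp)
  ctrl <- rbind(wa, wb)
  doses <- c(0.3, 1, 3); taus <- c(18, 8, 3)
  tors <- vapply(1:3, function(i) {
    drug <- drug_effect_spec(e0 = 0.02, emax = -0.015, ec50 = 1, hs = 1,
                             response_delay_tau = taus[i])
    time_of_response(sim_windows(810 + i, drug = drug, dose = doses[i]),
                     ctrl, thr, kp)$tor
  }, numeric(1))
  expect_true(all(is.finite(tors)))
  expect_true(all(diff(tors) < 0))
})

test_that("two-Gaussian mixture recovers a 70/30 split at 4 sigma separation", {
  set.seed(7)
  n <- 2000; s <- 0.005
  resp <- runif(n) < 0.7
  x <- ifelse(resp, rnorm(n, -0.01, s), rnorm(n, -0.01 + 4 * s, s))
  win <- data.frame(window_center = 10, track_id = seq_len(n), sgr = x)
  mx <- fit_mixture_sequence(win, kp)
  expect_lt(abs(mx$fraction_nonresponsive - 0.3), 0.05)
  expect_true(mx$identifiable)
  expect_lt(mx$mu_s, mx$mu_n)
  expect_lt(abs(mx$mu_s - (-0.01)), 0.002)
  expect_lt(abs(mx$mu_n - 0.01), 0.002)
  expect_gt(mx$r2, 0.95)
})

test_that("a unimodal population is reported unidentifiable", {
  set.seed(8)
  win <- data.frame(window_center = 10, track_id = 1:1500,
                    sgr = rnorm(1500, 0.005, 0.006))
  mx <- fit_mixture_sequence(win, kp)
  expect_false(mx$identifiable)
})

test_that("the sequential warm start tracks a decaying non-responsive fraction", {
  set.seed(9)
  centers <- seq(6, 28, by = 2)  # 12 windows
  frac_n <- seq(0.8, 0.2, length.out = length(centers))
  s <- 0.005
  win <- do.call(rbind, lapply(seq_along(centers), function(i) {
    n <- 1200
    nonresp <- runif(n) < frac_n[i]
    data.frame(window_center = centers[i], track_id = seq_len(n),
               sgr = ifelse(nonresp, rnorm(n, 0.01, s), rnorm(n, -0.012, s)))
  }))
  mx <- fit_mixture_sequence(win, kp)
  expect_equal(nrow(mx), length(centers))
  expect_lt(max(abs(mx$fraction_nonresponsive - frac_n)), 0.06)
  # globally decreasing trend at the generator slope (-0.6 over 22 h)
  expect_lt(coef(lm(mx$fraction_nonresponsive ~ centers))[[2]], -0.02)
  expect_true(all(!mx$carried_forward))
})
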