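test_that("noiseless control tracks grow at exactly the control rate", {
  tr <- simulate_tracks(quiet_pop(n = 4, sgr = 0.02, seed = 7))
  slopes <- log_slope_by_cell(tr)
  expect_equal(unname(slopes), rep(0.02, 4), tolerance = 1e-12)
  # any sub-window has the same log-slope for exponential growth
  sub <- tr[tr$cell_id == 1 & tr$t_h >= 10 & tr$t_h <= 20, ]
  ls <- coef(lm(log(sub$mass_true_pg) ~ sub$t_h))[[2]]
  expect_equal(ls, 0.02, tolerance = 1e-12)
})

test_that("spec validation rejects degenerate populations", {
  expect_error(population_spec(n_cells = 0), "n_cells")
  expect_error(population_spec(duration = 0), "duration")
  expect_error(population_spec(frame_interval = 0), "frame_interval")
  expect_error(population_spec(
    initial_mass_mix = list(list(weight = 0.5, mean_pg = 300, sd_pg = 10))),
    "sum to 1")
  expect_error(drug_effect_spec(ec50 = 0), "ec50")
  expect_error(drug_effect_spec(resistant_fraction = 1.2), "resistant_fraction")
  expect_error(simulate_tracks(quiet_pop(), dose = -1), "dose")
})

test_that("resistant fraction produces a bimodal SGR distribution at the specified modes", {
  pop <- population_spec(n_cells = 2000, sgr_control = -0.01, sgr_sd = 0.002,
                         noise_sd_mass = 0, seed = 21)
  drug <- drug_effect_spec(e0 = -0.01, emax = -0.01, ec50 = 1, hs = 1,
                           resistant_fraction = 0.5, resistant_sgr = 0.02)
  tr <- simulate_tracks(pop, drug, dose = 1)
  slopes <- log_slope_by_cell(tr)
  lo <- slopes[slopes < 0.005]
  hi <- slopes[slopes >= 0.005]
  expect_gt(length(lo), 800)
  expect_gt(length(hi), 800)
  expect_equal(mean(lo), -0.01, tolerance = 0.02)
  expect_equal(mean(hi), 0.02, tolerance = 0.02)
})

test_that("at the EC50 non-resistant cells grow at the Hill midpoint", {
  pop <- quiet_pop(n = 6, sgr = 0.02, seed = 3)
  drug <- drug_effect_spec(e0 = 0.02, emax = -0.01, ec50 = 2, hs = 1.5,
                           response_delay_tau = 0)
  tr <- simulate_tracks(pop, drug, dose = 2)
  slopes <- log_slope_by_cell(tr)
  expect_equal(unname(slopes), rep((0.02 - 0.01) / 2, 6), tolerance = 1e-10)
})

test_that("exponential onset delays the drug effect", {
  pop <- quiet_pop(n = 1, sgr = 0.02, seed = 9, duration = 60)
  drug <- drug_effect_spec(e0 = 0.02, emax = -0.02, ec50 = 1, hs = 1,
                           response_delay_tau = 8)
  tr <- simulate_tracks(pop, drug, dose = 1e6)  # saturating dose
  m <- tr$mass_true_pg; t <- tr$t_h
  early <- (log(m[4]) - log(m[1])) / (t[4] - t[1])
  late <- (log(m[length(m)]) - log(m[length(m) - 9])) / (t[length(m)] - t[length(m) - 9])
  expect_gt(early, 0)            # still near the control rate
  expect_lt(late, -0.015)        # converged to the high-dose rate
})

test_that("identical specs and seed reproduce bit-identical tracks", {
  pop <- population_spec(n_cells = 10, seed = 123)
  drug <- drug_effect_spec()
  a <- simulate_tracks(pop, drug, dose = 0.5)
  b <- simulate_tracks(pop, drug, dose = 0.5)
  expect_identical(a, b)
  pop2 <- pop; pop2$seed <- 124
  expect_false(identical(simulate_tracks(pop2, drug, dose = 0.5), a))
})

test_that("rendered cells carry their scheduled mass to within 0.5%", {
  pop <- population_spec(n_cells = 1, initial_mass_mix = list(
    list(weight = 1, mean_pg = 300, sd_pg = 0)), sgr_control = 0,
    noise_sd_mass = 0, duration = 1, seed = 5, motion_step = 0)
  tr <- simulate_tracks(pop)
  sc <- scene_spec(image_shape = 128, background_phase_sd = 0)
  mv <- render_phase_movie(tr, sc, seed = 6)
  cst <- mass_constants(wavelength = sc$wavelength,
                        pixel_area = sc$pixel_size^2)
  for (f in seq_along(mv$phase)) {
    m <- compute_cell_mass(mv$phase[[f]], mv$labels[[f]] == 1L, cst)
    expect_equal(m, mv$truth$mass_pg[mv$truth$frame == f], tolerance = 0.005)
  }
})

test_that("empty scenes render as zero phase and two cells give two components", {
  sc <- scene_spec(image_shape = 96, background_phase_sd = 0)
  empty <- simulate_tracks(quiet_pop(n = 1, duration = 1, seed = 1))
  empty$mass_pg <- 0; empty$mass_true_pg <- 0
  mv0 <- render_phase_movie(empty, sc)
  expect_true(all(mv0$phase[[1]] == 0))

  pop <- population_spec(n_cells = 2, duration = 1, seed = 2,
                         field_um = 50, motion_step = 0, noise_sd_mass = 0)
  mv2 <- render_phase_movie(simulate_tracks(pop),
                            scene_spec(image_shape = 128,
                                       cell_radius_mean = 6,
                                       background_phase_sd = 0))
  expect_identical(sort(unique(as.vector(mv2$labels[[1]]))), c(0L, 1L, 2L))
})

test_that("forward DPC model obeys flatness and half-pair symmetry", {
  opt <- optics_spec()
  flat <- render_dpc_intensities(matrix(0, 64, 64), opt, background = 2)[[1]]
  for (img in flat) expect_true(all(img == 2))

  # pure top-bottom gradient: tb pair differs, lr pair identical
  n <- 64
  phi <- matrix(rep(0.05 * sin(2 * pi * (1:n) / n), n), n, n)  # varies along rows
  I <- render_dpc_intensities(phi, opt)[[1]]
  expect_gt(max(abs(I$top - I$bottom)), 1e-4)
  expect_lt(max(abs(I$left - I$right)), 1e-10)
})

test_that("generated dose-response means lie on the specified Hill curve", {
  drug <- drug_effect_spec(e0 = 0.02, emax = -0.01, ec50 = 1, hs = 1)
  doses <- c(0.1, 1, 10)
  for (i in seq_along(doses)) {
    pop <- population_spec(n_cells = 300, sgr_control = 0.02, sgr_sd = 0.004,
                           noise_sd_mass = 0, seed = 30 + i)
    tr <- simulate_tracks(pop, drug, doses[i])
    mean_slope <- mean(log_slope_by_cell(tr))
    expect_equal(mean_slope, hill_model(doses[i], 0.02, -0.01, 1, 1),
                 tolerance = 3 * 0.004 / sqrt(300) / abs(hill_model(doses[i], 0.02, -0.01, 1, 1)))
  }
})
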