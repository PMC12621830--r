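obs_df <- function(x, y, m) data.frame(x_um = x, y_um = y, mass_pg = m)

test_that("identical observation sets link by identity at zero cost", {
  a <- obs_df(c(0, 50, 100), c(0, 20, 40), c(100, 200, 300))
  expect_equal(link_frames(a, a), 1:3)
})

test_that("optimal assignment refuses the more expensive swap", {
  # enumerating the 2x2 cost matrix: staying costs 2 * 1^2, swapping costs
  # 2 * 9^2 in squared displacement -- staying wins
  a <- obs_df(c(0, 10), c(0, 0), c(100, 100))
  b <- obs_df(c(1, 11), c(0, 0), c(100, 100))
  expect_equal(link_frames(a, b, link_cost(spatial_weight = 1, mass_weight = 0)),
               1:2)
  # make swapping cheaper via mass: the heavy cell reappears at the other
  # position, so matching by mass requires crossing in space
  a2 <- obs_df(c(0, 10), c(0, 0), c(500, 100))
  b2 <- obs_df(c(1, 11), c(0, 0), c(100, 500))
  cost <- link_cost(spatial_weight = 1e-4, mass_weight = 1,
                    max_mass_jump = 1)
  expect_equal(link_frames(a2, b2, cost), c(2, 1))
})

test_that("links beyond the gates are refused", {
  a <- obs_df(0, 0, 100)
  far <- obs_df(100, 100, 100)
  expect_true(is.na(link_frames(a, far, link_cost(max_link_distance = 20))))
  heavy <- obs_df(1, 0, 500)
  expect_true(is.na(link_frames(a, heavy, link_cost(max_mass_jump = 0.5))))
  expect_equal(link_frames(a, obs_df(numeric(0), numeric(0), numeric(0))),
               NA_integer_)
  expect_length(link_frames(obs_df(numeric(0), numeric(0), numeric(0)), a),
                0L)
})

test_that("assignment matches brute-force enumeration for small frames", {
  perms <- function(n) {
    if (n == 1) return(matrix(1))
    p <- perms(n - 1)
    do.call(rbind, lapply(seq_len(n), function(k) {
      cbind(k, p + (p >= k))
    }))
  }
  cost <- link_cost(spatial_weight = 1, mass_weight = 1e-4,
                    max_link_distance = Inf, max_mass_jump = Inf)
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(2:6, 1)
    a <- obs_df(runif(n, 0, 50), runif(n, 0, 50), runif(n, 100, 300))
    b <- obs_df(a$x_um + rnorm(n, 0, 5), a$y_um + rnorm(n, 0, 5),
                a$mass_pg + rnorm(n, 0, 20))
    got <- link_frames(a, b, cost)
    cm <- outer(a$x_um, b$x_um, `-`)^2 + outer(a$y_um, b$y_um, `-`)^2 +
      1e-4 * outer(a$mass_pg, b$mass_pg, `-`)^2
    pp <- perms(n)
    best <- pp[which.min(apply(pp, 1, function(s) sum(cm[cbind(1:n, s)]))), ]
    expect_equal(got, as.integer(best))
  }
})

test_that("a single persistent cell yields one full-length track", {
  tr <- simulate_tracks(quiet_pop(n = 1, seed = 5))
  obs <- tr[, c("frame", "x_um", "y_um", "mass_pg")]
  built <- build_tracks(obs, link_cost())
  qc <- attr(built, "qc")
  expect_equal(nrow(qc), 1L)
  expect_equal(qc$length, length(unique(tr$frame)))
})

test_that("distant identical twins are never merged", {
  n_f <- 30
  obs <- rbind(
    data.frame(frame = 1:n_f, x_um = 10, y_um = 10, mass_pg = 200),
    data.frame(frame = 1:n_f, x_um = 200, y_um = 200, mass_pg = 200))
  built <- build_tracks(obs, link_cost())
  qc <- attr(built, "qc")
  expect_equal(nrow(qc), 2L)
  expect_true(all(qc$length == n_f))
  # each track stays at one location
  sp <- split(built$x_um, built$track_id)
  expect_true(all(vapply(sp, function(x) diff(range(x)) == 0, logical(1))))
})

test_that("track identities are recovered from a simulated field of cells", {
  pop <- population_spec(n_cells = 25, seed = 31, noise_sd_mass = 2,
                         duration = 16, field_um = 250)
  tr <- simulate_tracks(pop)
  obs <- tr[, c("frame", "x_um", "y_um", "mass_pg", "cell_id")]
  built <- build_tracks(obs[, 1:4], link_cost())
  built$cell_id <- obs$cell_id[match(
    paste(built$frame, built$x_um, built$y_um),
    paste(obs$frame, obs$x_um, obs$y_um))]
  # every built track contains observations of exactly one true cell
  purity <- vapply(split(built$cell_id, built$track_id),
                   function(ids) length(unique(ids)) == 1L, logical(1))
  expect_true(all(purity))
  qc <- attr(built, "qc")
  expect_equal(sum(qc$length == length(unique(tr$frame))), 25L)
})

test_that("shuffling observations within frames does not change the track partition", {
  pop <- population_spec(n_cells = 8, seed = 13, duration = 6, field_um = 150)
  tr <- simulate_tracks(pop)
  obs <- tr[, c("frame", "x_um", "y_um", "mass_pg")]
  set.seed(99)
  shuffled <- obs[sample(nrow(obs)), ]
  partition <- function(built) {
    key <- paste(built$frame, round(built$x_um, 9), round(built$y_um, 9))
    unname(split(key, built$track_id))
  }
  p1 <- partition(build_tracks(obs, link_cost()))
  p2 <- partition(build_tracks(shuffled, link_cost()))
  norm <- function(p) sort(vapply(p, function(k) paste(sort(k), collapse = "|"),
                                  character(1)))
  expect_equal(norm(p1), norm(p2))
})

test_that("gap closing bridges a single missing frame when enabled", {
  obs <- data.frame(frame = c(1, 2, 4, 5), x_um = 10, y_um = 10,
                    mass_pg = 200)
  no_gap <- attr(build_tracks(obs, link_cost(max_gap_frames = 0L)), "qc")
  expect_equal(nrow(no_gap), 2L)
  gap <- attr(build_tracks(obs, link_cost(max_gap_frames = 1L)), "qc")
  expect_equal(nrow(gap), 1L)
  expect_equal(gap$gaps, 1L)
})
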