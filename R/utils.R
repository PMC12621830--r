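# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`;
# the caller's RNG stream is restored afterwards. seed = NULL is a no-op.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Shrinking-window running median: near the ends the half-width shrinks
# symmetrically (window i +/- min(h, i-1, n-i)), so endpoints are smoothed
# with fewer points instead of padded values, and the window stays centered
# -- a monotone series passes through unchanged.
median_filter <- function(x, k = 5L) {
  stopifnot(k >= 1L, k %% 2L == 1L)
  n <- length(x)
  if (n == 0L || k == 1L) return(x)
  h <- (k - 1L) %/% 2L
  shrink_med <- function(i) {
    hi <- min(h, i - 1L, n - i)
    stats::median(x[(i - hi):(i + hi)])
  }
  if (n <= k) return(vapply(seq_len(n), shrink_med, numeric(1)))
  out <- as.numeric(stats::runmed(x, k, endrule = "keep"))
  ends <- c(seq_len(h), (n - h + 1L):n)
  out[ends] <- vapply(ends, shrink_med, numeric(1))
  out
}

# Least-squares line y ~ t returning slope, intercept, R^2 and the fitted
# value at t0 (the "projected" value at the series start).
line_fit <- function(t, y, t0 = t[1L]) {
  n <- length(t)
  stopifnot(n == length(y), n >= 2L)
  mt <- mean(t); my <- mean(y)
  sxx <- sum((t - mt)^2)
  if (sxx == 0) stop("degenerate time axis: all timepoints identical")
  slope <- sum((t - mt) * (y - my)) / sxx
  intercept <- my - slope * mt
  fitted <- intercept + slope * t
  ssr <- sum((y - fitted)^2)
  sst <- sum((y - my)^2)
  r2 <- if (sst > 0) 1 - ssr / sst else 1
  list(slope = slope, intercept = intercept, r2 = r2,
       y0 = intercept + slope * t0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Canonical md5 of an R list, via its JSON serialization on disk.
config_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f), add = TRUE)
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, null = "null")
  unname(tools::md5sum(f))
}
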