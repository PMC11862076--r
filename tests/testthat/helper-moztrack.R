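# Shared fixtures and independent reference implementations used as oracles.

# a uniform-grid track data.frame from explicit coordinates
make_track <- function(x, y, fps = 50, trial_id = "T_1", strain = "S",
                       track_id = 1L) {
  n <- length(x)
  data.frame(trial_id = trial_id, strain = strain, track_id = track_id,
             frame = seq_len(n) - 1L, t = (seq_len(n) - 1L) / fps,
             x = x, y = y, stringsAsFactors = FALSE)
}

# segment object wrapping a full interpolated track slice
make_segment <- function(x, y, observed = rep(TRUE, length(x)), fps = 50) {
  d <- data.frame(trial_id = "T_1", strain = "S", track_id = 1L,
                  frame = seq_along(x) - 1L, t = (seq_along(x) - 1L) / fps,
                  x = x, y = y, observed = observed)
  list(trial_id = "T_1", strain = "S", track_id = 1L, segment_index = 0L,
       start_t = 0, data = d, quality = quality_score(observed))
}

# a profile that flies in a deterministic straight line (zero velocity noise,
# constant drift, no dither)
straight_profile <- function(speed = 300) {
  strain_profile("straight", "IS", speed_scale = speed, fd_target = 1.1,
                 persistence_phi = 0.99, vy_up_drift = speed,
                 vy_down_drift = speed, state_switch_rate = 0,
                 dither_amp = 0, vy_sigma_frac = 1)
}

big_arena <- function() arena_spec(1e6, 1e6, 50)

# brute-force zero-crossing / extrema counters (independent loops)
ref_zero_cross <- function(v) {
  nz <- sum(v == 0)
  s <- sign(v)[sign(v) != 0]
  ch <- 0L
  if (length(s) > 1L) for (i in 2:length(s)) if (s[i] != s[i - 1]) ch <- ch + 1L
  nz + ch
}
ref_extrema <- function(v) {
  nmin <- 0L; nmax <- 0L
  if (length(v) >= 3L) for (i in 2:(length(v) - 1L)) {
    if (v[i] < v[i - 1] && v[i] < v[i + 1]) nmin <- nmin + 1L
    if (v[i] > v[i - 1] && v[i] > v[i + 1]) nmax <- nmax + 1L
  }
  c(nmin = nmin, nmax = nmax)
}

# brute-force signed-rank two-sided p by full enumeration of all 2^n sign
# assignments (midranks, so ties are handled)
ref_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  sums <- vapply(0:(2^n - 1), function(mask) {
    sum(r[bitwAnd(mask, 2^(0:(n - 1))) > 0])
  }, numeric(1))
  p_ge <- mean(sums >= w - 1e-9)
  p_le <- mean(sums <= w + 1e-9)
  min(1, 2 * min(p_ge, p_le))
}

# brute-force Gaussian smoothing (direct kernel sums with edge
# renormalisation), for the curvature-scale-space oracle
ref_gauss_smooth <- function(z, sigma) {
  h <- max(1L, ceiling(4 * sigma))
  n <- length(z)
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1, i - h):min(n, i + h)
    k <- dnorm(j - i, sd = sigma)
    out[i] <- sum(k * z[j]) / sum(k)
  }
  out
}
ref_css_counts <- function(x, y, fps, n_scales = 8, sigma_range_ms = c(1, 128)) {
  n <- length(x)
  sigmas <- exp(seq(log(sigma_range_ms[1]), log(sigma_range_ms[2]),
                    length.out = n_scales))
  counts <- c()
  for (sm in sigmas) {
    ss <- sm / 1000 * fps
    if (2 * ceiling(4 * ss) + 1 > n) next
    xs <- ref_gauss_smooth(x, max(ss, 1e-3))
    ys <- ref_gauss_smooth(y, max(ss, 1e-3))
    i <- 2:(n - 1)
    xp <- (xs[i + 1] - xs[i - 1]) / 2; yp <- (ys[i + 1] - ys[i - 1]) / 2
    xpp <- xs[i + 1] - 2 * xs[i] + xs[i - 1]
    ypp <- ys[i + 1] - 2 * ys[i] + ys[i - 1]
    den <- (xp^2 + yp^2)^1.5
    kap <- ifelse(den > 0, (xp * ypp - yp * xpp) / den, 0)
    s <- sign(kap[is.finite(kap)]); s <- s[s != 0]
    counts <- c(counts, if (length(s) < 2) 0L else sum(diff(s) != 0))
  }
  counts
}

# small two-strain profile pair for fast pipeline-level tests
tiny_profiles <- function(n_trials = 3, tracks = 6) {
  list(
    S_IS = strain_profile("S_IS", "IS", n_trials = n_trials,
      tracks_per_trial = c(mean = tracks, dispersion = 50),
      duration_meanlog = log(14) - 0.32, duration_sdlog = 0.8,
      speed_scale = 400, fd_target = 1.15, persistence_phi = 0.8741,
      vy_up_drift = 140, vy_down_drift = 140, dither_amp = 0.05,
      vy_sigma_frac = 1),
    S_IR = strain_profile("S_IR", "IR", n_trials = n_trials,
      tracks_per_trial = c(mean = tracks, dispersion = 50),
      duration_meanlog = log(14) - 0.32, duration_sdlog = 0.8,
      speed_scale = 400, fd_target = 1.04, persistence_phi = 0.9951,
      vy_up_drift = 140, vy_down_drift = 60, dither_amp = 0.25,
      vy_sigma_frac = 0.6))
}

vy_stat_names <- function() paste0("vy_", c("mean", "sd", "median", "q1",
  "q3", "skewness", "kurtosis", "n_zero_cross", "n_local_min",
  "n_local_max"))
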