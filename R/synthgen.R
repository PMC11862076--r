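# Synthetic flight-track generator: correlated-velocity model with a two-state
# vertical drift, multiplicative speed dither, reflecting arena boundaries and
# a camera observation-dropout model.

#' Arena specification
#'
#' Rectangular field of view of the tracking system. The default extents match
#' a 1400 x 1050 mm Fresnel-lens field imaged at 50 frames per second.
#'
#' @param width_mm,height_mm Arena extents in mm (positive).
#' @param fps Frames per second of the recording (positive).
#' @return An object of class `arena_spec`.
#' @export
arena_spec <- function(width_mm = 1400, height_mm = 1050, fps = 50) {
  stopifnot(is.numeric(width_mm), width_mm > 0,
            is.numeric(height_mm), height_mm > 0,
            is.numeric(fps), fps > 0)
  structure(list(width_mm = width_mm, height_mm = height_mm, fps = fps),
            class = "arena_spec")
}

#' Strain behavioural profile
#'
#' Parameters of the generative flight model for one mosquito strain.
#' Velocity follows a first-order autoregressive process
#' `v(t+dt) = phi * v(t) + (1 - phi) * mu(state) + eta` with bivariate Gaussian
#' innovations `eta`, where the drift `mu` switches between an ascent state
#' (`+vy_up_drift` on the vertical axis) and a descent state
#' (`-vy_down_drift`) under a two-state Markov chain with mean switch rate
#' `state_switch_rate`; state dwell times are inversely proportional to the
#' state's drift magnitude (brief fast ascents, long slow descents), so the
#' stationary vertical drift is zero and unequal drift magnitudes skew the
#' vertical-velocity distribution. Speed is modulated multiplicatively by
#' `1 + dither_amp * sin(2 * pi * dither_freq_hz * t)`.
#'
#' Insecticide-resistant (IR) profiles must be more persistent than
#' insecticide-susceptible (IS) ones (`fd_target` lower) and descend more
#' slowly than they ascend (`vy_down_drift < vy_up_drift`).
#'
#' @param name Strain label.
#' @param resistance_class `"IR"` or `"IS"`.
#' @param n_trials Number of recording trials for this strain.
#' @param tracks_per_trial Length-2 numeric `c(mean, dispersion)` of the
#'   negative-binomial distribution of track counts per trial.
#' @param duration_meanlog,duration_sdlog Lognormal parameters of track
#'   duration in seconds; durations are truncated to `[1, 700]` s.
#' @param speed_scale Target mean flight speed, mm/s.
#' @param fd_target Target divider fractal dimension of 8 s segments, in
#'   `[1, 2]`.
#' @param persistence_phi Velocity autocorrelation coefficient in `[0, 1)`.
#' @param vy_up_drift,vy_down_drift Vertical drift magnitudes (mm/s) of the
#'   ascent and descent states; both non-negative.
#' @param state_switch_rate Markov switch rate between ascent and descent,
#'   per second.
#' @param dither_amp Relative amplitude of the sinusoidal speed modulation,
#'   in `[0, 1)`.
#' @param dither_freq_hz Modulation frequency, Hz.
#' @param vy_sigma_frac Ratio of vertical to horizontal velocity-noise
#'   standard deviation; values below 1 narrow the vertical velocity
#'   distribution relative to the horizontal one.
#' @return An object of class `strain_profile`.
#' @export
strain_profile <- function(name, resistance_class, n_trials = 4,
                           tracks_per_trial = c(mean = 12, dispersion = 8),
                           duration_meanlog = log(22) - 0.5,
                           duration_sdlog = 1,
                           speed_scale = 400,
                           fd_target = 1.1,
                           persistence_phi = 0.9,
                           vy_up_drift = 140, vy_down_drift = 140,
                           state_switch_rate = 0.5,
                           dither_amp = 0.05, dither_freq_hz = 8,
                           vy_sigma_frac = 1) {
  stopifnot(is.character(name), length(name) == 1L)
  resistance_class <- match.arg(resistance_class, c("IR", "IS"))
  vals <- c(n_trials, tracks_per_trial[1], duration_meanlog, duration_sdlog,
            speed_scale, fd_target, persistence_phi, vy_up_drift,
            vy_down_drift, state_switch_rate, dither_amp, dither_freq_hz,
            vy_sigma_frac)
  if (!all(is.finite(vals))) stop("non-finite profile parameter")
  if (is.na(tracks_per_trial[2]) || tracks_per_trial[2] <= 0)
    stop("tracks_per_trial dispersion must be positive (Inf = fixed count)")
  if (fd_target < 1 || fd_target > 2) stop("fd_target must lie in [1, 2]")
  if (persistence_phi < 0 || persistence_phi >= 1)
    stop("persistence_phi must lie in [0, 1)")
  if (dither_amp < 0 || dither_amp >= 1)
    stop("dither_amp must lie in [0, 1)")
  if (min(vy_up_drift, vy_down_drift, state_switch_rate, dither_freq_hz,
          speed_scale, vy_sigma_frac) < 0)
    stop("rates, drifts and amplitudes must be non-negative")
  structure(list(
    name = name, resistance_class = resistance_class, n_trials = n_trials,
    tracks_per_trial = c(mean = unname(tracks_per_trial[1]),
                         dispersion = unname(tracks_per_trial[2])),
    duration_meanlog = duration_meanlog, duration_sdlog = duration_sdlog,
    speed_scale = speed_scale, fd_target = fd_target,
    persistence_phi = persistence_phi,
    vy_up_drift = vy_up_drift, vy_down_drift = vy_down_drift,
    state_switch_rate = state_switch_rate,
    dither_amp = dither_amp, dither_freq_hz = dither_freq_hz,
    vy_sigma_frac = vy_sigma_frac), class = "strain_profile")
}

#' Default strain profiles
#'
#' Four pseudo-strains emulating the study conditions: two
#' insecticide-susceptible (Kisumu-like with 5 trials, Ngoussu-like with 4)
#' and two insecticide-resistant (Banfora-like and VK7-like, 4 trials each).
#' Mean speeds and track-duration scales follow the published per-strain
#' summaries; fractal-dimension targets are 1.04 (IR) and 1.15 (IS), with the
#' persistence coefficients pre-calibrated by [calibrate_persistence()].
#' IR profiles descend more slowly than they ascend (skewed vertical
#' velocity), carry a narrower vertical velocity distribution
#' (`vy_sigma_frac = 0.6`) and a stronger speed dither.
#'
#' @return Named list of four [strain_profile()] objects.
#' @export
default_strain_profiles <- function() {
  is_common <- list(vy_up_drift = 140, vy_down_drift = 140,
                    state_switch_rate = 0.5, dither_amp = 0.05,
                    dither_freq_hz = 8, vy_sigma_frac = 1,
                    fd_target = 1.15)
  ir_common <- list(vy_up_drift = 140, vy_down_drift = 60,
                    state_switch_rate = 0.5, dither_amp = 0.25,
                    dither_freq_hz = 8, vy_sigma_frac = 0.6,
                    fd_target = 1.04)
  mk <- function(name, class, n_trials, dur_mean, speed, phi, common) {
    do.call(strain_profile, c(list(
      name = name, resistance_class = class, n_trials = n_trials,
      duration_meanlog = log(dur_mean) - 0.5, duration_sdlog = 1,
      speed_scale = speed, persistence_phi = phi), common))
  }
  # persistence_phi values from calibrate_persistence() against each
  # profile's fd_target (8 s segments at 50 fps)
  list(
    Kisumu  = mk("Kisumu",  "IS", 5, 22.39, 344.29, 0.8741, is_common),
    Ngoussu = mk("Ngoussu", "IS", 4, 21.40, 453.78, 0.8741, is_common),
    Banfora = mk("Banfora", "IR", 4, 24.26, 389.57, 0.9951, ir_common),
    VK7     = mk("VK7",     "IR", 4, 17.04, 429.54, 0.9951, ir_common))
}

# Stationary occupancy of the ascent state. Dwell times are inversely
# proportional to the state's drift magnitude (brief fast ascents, long slow
# descents), which gives the vertical velocity zero stationary mean and a
# positive skew whenever vy_down_drift < vy_up_drift.
ascent_occupancy <- function(profile) {
  tot <- profile$vy_up_drift + profile$vy_down_drift
  if (tot == 0) return(0.5)
  profile$vy_down_drift / tot
}

# Per-component velocity-noise sds (sigma_x, sigma_y) chosen so that the
# stationary mean speed approximates speed_scale given the state drifts:
# E|v|^2 = E[mu^2] + sigma_x^2 + sigma_y^2 and for a 2D Gaussian the mean
# modulus is close to sqrt(E[mu^2] + (pi/2) * mean(sigma^2)).
profile_sigmas <- function(profile) {
  w_up <- ascent_occupancy(profile)
  emu2 <- w_up * profile$vy_up_drift^2 +
    (1 - w_up) * profile$vy_down_drift^2
  sbar2 <- max(0, (profile$speed_scale^2 - emu2) / (pi / 2))
  f <- profile$vy_sigma_frac
  sx2 <- 2 * sbar2 / (1 + f^2)
  c(sx = sqrt(sx2), sy = f * sqrt(sx2))
}

# alternating-state sequence with drift-proportional exit rates
simulate_states <- function(profile, n, dt) {
  rate <- profile$state_switch_rate
  tot <- profile$vy_up_drift + profile$vy_down_drift
  if (tot == 0) {
    r_up <- r_dn <- rate
  } else {  # mean switch rate preserved, exits proportional to drift
    r_up <- rate * 2 * profile$vy_up_drift / tot
    r_dn <- rate * 2 * profile$vy_down_drift / tot
  }
  p_up <- min(1, r_up * dt)
  p_dn <- min(1, r_dn * dt)
  cur <- if (stats::runif(1) < ascent_occupancy(profile)) 1L else 2L
  states <- integer(0)
  total <- 0L
  while (total < n) {
    p <- if (cur == 1L) p_up else p_dn
    len <- if (p <= 0) n else stats::rgeom(1, p) + 1L
    states <- c(states, rep(cur, len))
    total <- total + len
    cur <- 3L - cur
  }
  states[seq_len(n)]
}

# Reflect free coordinates into [0, w] (triangle-wave folding; exact for
# specular reflection at the boundaries).
reflect_into <- function(z, w) {
  z <- z %% (2 * w)
  w - abs(z - w)
}

#' Simulate one flight track
#'
#' Draws a fully observed track on the uniform `1/fps` grid from the
#' autoregressive velocity model described in [strain_profile()], integrating
#' positions with reflecting boundaries at the arena edges.
#'
#' @param profile A [strain_profile()].
#' @param duration Track duration in seconds (at least 1 s).
#' @param arena An [arena_spec()].
#' @param seed Integer seed; the same seed yields an identical track.
#' @param trial_id,track_id Provenance labels carried into the output.
#' @return A `data.frame` with columns
#'   `trial_id, strain, track_id, frame, t, x, y`.
#' @export
simulate_track <- function(profile, duration, arena = arena_spec(),
                           seed = NULL, trial_id = "T1", track_id = 1L) {
  stopifnot(inherits(profile, "strain_profile"), inherits(arena, "arena_spec"))
  if (!is.finite(duration) || duration < 1)
    stop("track duration must be at least 1 s")
  if (!is.null(seed)) set.seed(seed)
  dt <- 1 / arena$fps
  n <- round(duration * arena$fps) + 1L
  tt <- (seq_len(n) - 1L) * dt
  phi <- profile$persistence_phi
  sig <- profile_sigmas(profile)

  # two-state Markov drift on the vertical axis (1 = ascent)
  state <- simulate_states(profile, n, dt)
  mu_y <- ifelse(state == 1L, profile$vy_up_drift, -profile$vy_down_drift)

  # AR(1) velocity with stationary per-component sds sig
  se <- sqrt(1 - phi^2)
  innov_x <- stats::rnorm(n, 0, sig["sx"] * se)
  innov_y <- (1 - phi) * mu_y + stats::rnorm(n, 0, sig["sy"] * se)
  v0x <- stats::rnorm(1, 0, sig["sx"])
  v0y <- stats::rnorm(1, mu_y[1], sig["sy"])
  vx <- as.numeric(stats::filter(innov_x, phi, "recursive", init = v0x))
  vy <- as.numeric(stats::filter(innov_y, phi, "recursive", init = v0y))

  # multiplicative speed dither
  mod <- 1 + profile$dither_amp * sin(2 * pi * profile$dither_freq_hz * tt)
  vx <- vx * mod
  vy <- vy * mod

  x0 <- stats::runif(1, 0, arena$width_mm)
  y0 <- stats::runif(1, 0, arena$height_mm)
  x <- reflect_into(x0 + cumsum(c(0, vx[-n])) * dt, arena$width_mm)
  y <- reflect_into(y0 + cumsum(c(0, vy[-n])) * dt, arena$height_mm)

  data.frame(trial_id = trial_id, strain = profile$name,
             track_id = as.integer(track_id), frame = seq_len(n) - 1L,
             t = tt, x = x, y = y, stringsAsFactors = FALSE)
}

#' Calibrate velocity persistence against a fractal-dimension target
#'
#' Bisection search for the autoregressive coefficient `phi` at which the
#' mean divider fractal dimension of simulated 8 s segments matches
#' `fd_target`. The estimated dimension decreases monotonically in `phi`
#' (more persistent velocities give straighter paths); common random numbers
#' are used across evaluations so the search is reproducible given `seed`.
#'
#' @param profile A [strain_profile()]; all parameters except
#'   `persistence_phi` are held fixed.
#' @param fd_target Target dimension in (1, 2); defaults to the profile's.
#' @param arena An [arena_spec()].
#' @param seed Integer seed.
#' @param n_segments Segments per evaluation (default 100).
#' @param segment_s Segment duration, s (default 8).
#' @param tol Absolute tolerance on the achieved mean dimension.
#' @return The calibrated `phi`, with the achieved mean dimension in
#'   attribute `"fd_achieved"`.
#' @export
calibrate_persistence <- function(profile, fd_target = profile$fd_target,
                                  arena = arena_spec(), seed = 1L,
                                  n_segments = 100L, segment_s = 8,
                                  tol = 0.02) {
  if (fd_target <= 1 || fd_target >= 2) stop("fd_target must lie in (1, 2)")
  mean_fd <- function(phi) {
    p <- profile
    p$persistence_phi <- phi
    set.seed(seed)
    fds <- vapply(seq_len(n_segments), function(i) {
      tr <- simulate_track(p, segment_s, arena)
      fractal_dimension(tr$x, tr$y)
    }, numeric(1))
    mean(fds, na.rm = TRUE)
  }
  lo <- 0; hi <- 0.999
  fd_lo <- mean_fd(lo); fd_hi <- mean_fd(hi)  # fd_lo is the roughest
  if (fd_target > fd_lo + tol || fd_target < fd_hi - tol)
    stop(sprintf(paste0("fd_target %.3f unreachable within phi in [0, 0.999]",
                        " (achievable range [%.3f, %.3f])"),
         fd_target, fd_hi, fd_lo))
  for (i in seq_len(40)) {
    mid <- (lo + hi) / 2
    fd_mid <- mean_fd(mid)
    if (abs(fd_mid - fd_target) <= tol / 2 || (hi - lo) < 1e-4) break
    if (fd_mid > fd_target) lo <- mid else hi <- mid
  }
  structure(mid, fd_achieved = fd_mid)
}

#' Camera observation-dropout model
#'
#' At each frame-to-frame transition an observation gap begins with
#' probability `p_gap`; gap durations are lognormal, rounded to whole frames
#' and floored at `min_gap_s` (a one-frame gap is indistinguishable from no
#' gap after interpolation). With probability `1 - p_gap` the next frame is
#' observed, so the marginal inter-observation interval is a mixture of the
#' frame interval and the gap law.
#'
#' @param p_gap Per-transition gap probability, in `[0, 1)`.
#' @param gap_meanlog,gap_sdlog Lognormal parameters of gap duration (s).
#' @param min_gap_s Minimum gap duration, at least two frame intervals.
#' @param fps Frames per second.
#' @return An object of class `dropout_model`.
#' @export
dropout_model <- function(p_gap, gap_meanlog, gap_sdlog,
                          min_gap_s = 2 / fps, fps = 50) {
  stopifnot(p_gap >= 0, p_gap < 1, gap_sdlog >= 0, fps > 0)
  if (min_gap_s < 2 / fps - 1e-12)
    stop("min_gap_s must be at least two frame intervals")
  structure(list(p_gap = p_gap, gap_meanlog = gap_meanlog,
                 gap_sdlog = gap_sdlog, min_gap_s = min_gap_s, fps = fps),
            class = "dropout_model")
}

#' Calibrate the dropout model by moment matching
#'
#' Solves the first two moment equations of the interval mixture
#' `I = dt` with probability `1 - p_gap`, `I = G` (lognormal) otherwise:
#' `p_gap * E[G] = target_mean - (1 - p_gap) * dt` and the corresponding
#' second-moment identity, for the lognormal parameters of `G` at the given
#' `p_gap`. The target median must equal the frame interval (so `p_gap`
#' below one half leaves the median untouched).
#'
#' @param target_median Target median interval, s; must equal `1/fps`.
#' @param target_mean,target_sd Target interval mean and sd, s. Defaults are
#'   the study's observed 0.07 s and 0.16 s.
#' @param fps Frames per second.
#' @param p_gap Gap probability at which the moments are matched.
#' @return A [dropout_model()].
#' @export
calibrate_dropout <- function(target_median = 0.02, target_mean = 0.07,
                              target_sd = 0.16, fps = 50, p_gap = 0.1) {
  dt <- 1 / fps
  if (abs(target_median - dt) > 1e-9)
    stop("target_median must equal the frame interval 1/fps")
  if (target_mean < target_median)
    stop("target_mean must be at least the frame interval")
  if (target_mean == dt && target_sd == 0)
    return(dropout_model(0, log(dt), 0, fps = fps))
  m1 <- (target_mean - (1 - p_gap) * dt) / p_gap          # E[G]
  m2 <- (target_sd^2 + target_mean^2 - (1 - p_gap) * dt^2) / p_gap  # E[G^2]
  if (m1 <= 0) stop("infeasible targets: implied E[G] is not positive")
  if (m2 <= m1^2)
    stop("infeasible moment combination: requires E[G^2] > E[G]^2 ",
         "(increase p_gap or target_sd)")
  sdlog <- sqrt(log(m2 / m1^2))
  meanlog <- log(m1) - sdlog^2 / 2
  dropout_model(p_gap, meanlog, sdlog, fps = fps)
}

# iid inter-observation intervals (in frames) under the dropout model
interval_sequence <- function(model, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gap <- stats::runif(n) < model$p_gap
  iv <- rep(1L, n)
  if (any(gap)) {
    g <- stats::rlnorm(sum(gap), model$gap_meanlog, model$gap_sdlog)
    frames <- pmax(round(model$min_gap_s * model$fps),
                   as.integer(round(g * model$fps)))
    iv[gap] <- frames
  }
  iv
}

#' Simulate inter-observation intervals
#'
#' Draws `n` marginal inter-observation intervals (seconds) from a
#' [dropout_model()], for checking the calibrated interval moments.
#'
#' @param model A [dropout_model()].
#' @param n Number of intervals.
#' @param seed Integer seed.
#' @return Numeric vector of interval durations, s.
#' @export
simulate_intervals <- function(model, n, seed = NULL) {
  interval_sequence(model, n, seed) / model$fps
}

# delete rows of a uniform-grid track according to a sequence of
# inter-observation intervals given in frames
apply_intervals <- function(track, intervals) {
  n <- nrow(track)
  keep_frames <- cumsum(c(0L, intervals))
  keep_frames <- keep_frames[keep_frames <= n - 1L]
  keep_frames <- unique(c(keep_frames, n - 1L))  # always retain the endpoint
  track[track$frame %in% keep_frames, , drop = FALSE]
}

#' Apply observation dropout to a track
#'
#' Removes observation rows in contiguous runs according to the dropout
#' model. The first and last samples are always retained, and every
#' inter-observation interval is either one frame or at least the model's
#' minimum gap.
#'
#' @param track Uniform-grid track `data.frame` from [simulate_track()].
#' @param model A [dropout_model()]; with `p_gap = 0` the track is returned
#'   unchanged.
#' @param seed Integer seed.
#' @return The track with unobserved rows removed.
#' @export
apply_dropout <- function(track, model, seed = NULL) {
  stopifnot(inherits(model, "dropout_model"))
  if (model$p_gap == 0) return(track)
  n <- nrow(track)
  iv <- interval_sequence(model, n, seed)
  apply_intervals(track, iv)
}

#' Generate a synthetic multi-trial dataset
#'
#' Simulates every trial of every strain profile, applies observation
#' dropout, and (optionally) writes one CSV per trial plus a JSON manifest
#' recording the seed and all model parameters. Output is deterministic
#' given `seed`.
#'
#' @param profiles List of [strain_profile()]s (default
#'   [default_strain_profiles()], i.e. 5 + 4 + 4 + 4 = 17 trials).
#' @param dropout A [dropout_model()]; `NULL` disables dropout. Defaults to
#'   the calibrated model of [calibrate_dropout()].
#' @param arena An [arena_spec()].
#' @param seed Integer seed.
#' @param dir Output directory; `NULL` keeps the dataset in memory only.
#' @param overwrite Overwrite existing trial files in `dir`.
#' @return Invisibly, a list with `tracks` (one `data.frame` of all rows),
#'   `manifest`, and `files` (paths written, or `NULL`).
#' @export
generate_dataset <- function(profiles = default_strain_profiles(),
                             dropout = calibrate_dropout(),
                             arena = arena_spec(), seed = 1L,
                             dir = NULL, overwrite = FALSE) {
  set.seed(seed)
  all_tracks <- list()
  files <- NULL
  for (p in profiles) {
    for (tr in seq_len(p$n_trials)) {
      trial_id <- sprintf("%s_%d", p$name, tr)
      disp <- p$tracks_per_trial["dispersion"]
      n_tracks <- if (!is.finite(disp)) {
        max(1L, round(p$tracks_per_trial["mean"]))
      } else {
        max(1L, stats::rnbinom(1, size = disp,
                               mu = p$tracks_per_trial["mean"]))
      }
      trial_rows <- vector("list", n_tracks)
      for (k in seq_len(n_tracks)) {
        repeat {  # truncated lognormal duration in [1, 700] s
          dur <- stats::rlnorm(1, p$duration_meanlog, p$duration_sdlog)
          if (dur >= 1 && dur <= 700) break
        }
        tk <- simulate_track(p, dur, arena, seed = NULL,
                             trial_id = trial_id, track_id = k)
        if (!is.null(dropout)) tk <- apply_dropout(tk, dropout)
        trial_rows[[k]] <- tk
      }
      all_tracks[[trial_id]] <- do.call(rbind, trial_rows)
    }
  }
  tracks <- do.call(rbind, all_tracks)
  rownames(tracks) <- NULL
  manifest <- list(seed = seed,
                   arena = unclass(arena),
                   dropout = if (is.null(dropout)) NULL else unclass(dropout),
                   profiles = lapply(profiles, unclass))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- character(0)
    for (trial_id in names(all_tracks)) {
      f <- file.path(dir, paste0(trial_id, ".csv"))
      if (file.exists(f) && !overwrite)
        stop("output file exists (use overwrite = TRUE): ", f)
      d <- all_tracks[[trial_id]]
      d$t <- sprintf("%.6f", d$t)
      data.table::fwrite(d, f)
      files <- c(files, f)
    }
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(tracks = tracks, manifest = manifest, files = files))
}
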