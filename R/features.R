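# Per-segment kinematic signals and shape descriptors. All statistics are
# evaluated only at samples whose finite-difference stencil touches observed
# (non-interpolated) positions.

wrap_angle <- function(a) {
  # wrap to (-pi, pi]
  w <- (a + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

#' Kinematic signals of a segment
#'
#' Computes the per-sample signals used for feature extraction: velocity
#' components `vx`, `vy` (central differences, mm/s), `speed` (mm/s),
#' acceleration components `ax`, `ay` (second central differences, mm/s^2),
#' flight-angle change `dtheta` wrapped to `(-pi, pi]` (rad), angular
#' velocity `omega` (rad/s), angular acceleration `angacc` (rad/s^2),
#' centroid distance `cdist` (mm) and curvature `curvature` (1/mm). Each
#' signal carries a validity mask that is `FALSE` wherever any sample of its
#' finite-difference stencil was interpolated, or where the quantity is
#' undefined (zero displacement for angles, zero speed for curvature).
#'
#' @param seg_data Segment sample `data.frame` with columns `x`, `y`,
#'   `observed` on the uniform grid.
#' @param fps Frames per second.
#' @return Named list of signals, each a list with `values` and `valid`.
#' @export
kinematic_signals <- function(seg_data, fps) {
  dt <- 1 / fps
  x <- seg_data$x; y <- seg_data$y; obs <- seg_data$observed
  n <- length(x)
  i <- 2:(n - 1)

  vx <- (x[i + 1] - x[i - 1]) / (2 * dt)
  vy <- (y[i + 1] - y[i - 1]) / (2 * dt)
  v_valid <- obs[i - 1] & obs[i + 1]
  speed <- sqrt(vx^2 + vy^2)

  ax <- (x[i + 1] - 2 * x[i] + x[i - 1]) / dt^2
  ay <- (y[i + 1] - 2 * y[i] + y[i - 1]) / dt^2
  a_valid <- obs[i - 1] & obs[i] & obs[i + 1]

  # flight angle over forward steps j -> j+1
  dxs <- diff(x); dys <- diff(y)
  disp <- sqrt(dxs^2 + dys^2)
  theta <- atan2(dys, dxs)
  th_valid <- obs[-n] & obs[-1] & disp > 0
  dtheta <- wrap_angle(diff(theta))          # at samples 2..n-1
  dth_valid <- th_valid[-(n - 1)] & th_valid[-1]
  omega <- dtheta / dt
  angacc <- diff(omega) / dt                 # at samples 2..n-2
  angacc_valid <- dth_valid[-length(dth_valid)] & dth_valid[-1]

  cx <- mean(x[obs]); cy <- mean(y[obs])
  cdist <- sqrt((x - cx)^2 + (y - cy)^2)

  xp <- vx * dt; yp <- vy * dt               # per-frame central differences
  xpp <- ax * dt^2; ypp <- ay * dt^2
  denom <- (xp^2 + yp^2)^1.5
  curv <- ifelse(denom > 0, (xp * ypp - yp * xpp) / denom, NA_real_)
  curv_valid <- a_valid & denom > 0

  list(
    vx = list(values = vx, valid = v_valid),
    vy = list(values = vy, valid = v_valid),
    speed = list(values = speed, valid = v_valid),
    ax = list(values = ax, valid = a_valid),
    ay = list(values = ay, valid = a_valid),
    dtheta = list(values = dtheta, valid = dth_valid),
    omega = list(values = omega, valid = dth_valid),
    angacc = list(values = angacc, valid = angacc_valid),
    cdist = list(values = cdist, valid = obs),
    curvature = list(values = curv, valid = curv_valid & !is.na(curv)))
}

SIGNAL_STATS <- c("mean", "sd", "median", "q1", "q3", "skewness", "kurtosis",
                  "n_zero_cross", "n_local_min", "n_local_max")

#' Summary statistics of a signal
#'
#' Returns the ten per-signal statistics: mean, sd (n-1 denominator),
#' median, first and third quartiles (linear-interpolation quantiles),
#' Fisher skewness and excess kurtosis (bias-uncorrected moment estimators;
#' 0 for degenerate signals), the number of zero crossings (strict sign
#' changes between consecutive valid samples plus the count of exact zero
#' values), and the numbers of strict interior local minima and maxima
#' within runs of valid samples.
#'
#' @param values Numeric signal values.
#' @param valid Logical validity mask (default all valid).
#' @return Named numeric vector of length 10, or `NULL` when fewer than 4
#'   valid samples are available (the segment is then dropped).
#' @export
summarise_signal <- function(values, valid = rep(TRUE, length(values))) {
  v <- values[valid]
  if (length(v) < 4L) return(NULL)
  m <- mean(v)
  m2 <- mean((v - m)^2)
  skew <- if (m2 > 0) mean((v - m)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((v - m)^4) / m2^2 - 3 else 0
  qs <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)

  # zero crossings over the ordered subsequence of valid samples
  nz <- sum(v == 0)
  s <- sign(v); s <- s[s != 0]
  ncross <- if (length(s) > 1L) sum(diff(s) != 0) else 0L

  # strict interior extrema within maximal runs of valid samples
  nmin <- 0L; nmax <- 0L
  r <- rle(valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values & r$lengths >= 3L)) {
    u <- values[starts[k]:ends[k]]
    j <- 2:(length(u) - 1L)
    nmin <- nmin + sum(u[j] < u[j - 1] & u[j] < u[j + 1])
    nmax <- nmax + sum(u[j] > u[j - 1] & u[j] > u[j + 1])
  }
  stats::setNames(c(m, stats::sd(v), qs[2], qs[1], qs[3], skew, kurt,
                    nz + ncross, nmin, nmax), SIGNAL_STATS)
}

#' Divider (Richardson) fractal dimension of a 2D path
#'
#' Estimates the fractal dimension by measuring the resampled path length
#' `L(eps)` at geometrically spaced ruler sizes `eps`: the path is resampled
#' at equal arclength spacing `eps` and the chord lengths summed. The
#' dimension is `1 - slope` of the least-squares fit of `log L(eps)` on
#' `log eps`, clamped to `[1, 2]`. Values near 1 indicate straight, directed
#' paths; values towards 2 indicate convoluted, plane-filling paths.
#'
#' @param x,y Coordinates of the (observed) path samples, mm.
#' @param n_scales Number of ruler sizes (at least 6), spanning twice the
#'   median step up to a quarter of the bounding-box diagonal.
#' @return Estimated dimension in `[1, 2]`, or `NA` when the path is
#'   degenerate (fewer than 16 samples or zero length).
#' @export
fractal_dimension <- function(x, y, n_scales = 8L) {
  n <- length(x)
  if (n < 16L) return(NA_real_)
  steps <- sqrt(diff(x)^2 + diff(y)^2)
  s <- c(0, cumsum(steps))
  total <- s[n]
  if (total <= 0) return(NA_real_)
  extent <- sqrt(diff(range(x))^2 + diff(range(y))^2)
  eps_min <- 2 * stats::median(steps[steps > 0])
  eps_max <- extent / 4
  if (!is.finite(eps_min) || eps_min <= 0) return(NA_real_)
  if (eps_max <= eps_min) eps_max <- eps_min * 4  # degenerate span guard
  n_scales <- max(6L, n_scales)
  eps <- exp(seq(log(eps_min), log(eps_max), length.out = n_scales))
  lens <- vapply(eps, function(e) {
    grid <- seq(0, total, by = e)
    if (length(grid) < 2L) return(NA_real_)
    rx <- stats::approx(s, x, xout = grid, ties = "ordered")$y
    ry <- stats::approx(s, y, xout = grid, ties = "ordered")$y
    # close the walk at the true endpoint
    sum(sqrt(diff(c(rx, x[n]))^2 + diff(c(ry, y[n]))^2))
  }, numeric(1))
  ok <- is.finite(lens) & lens > 0
  if (sum(ok) < 2L) return(NA_real_)
  slope <- stats::coef(stats::lm(log(lens[ok]) ~ log(eps[ok])))[2]
  min(2, max(1, 1 - unname(slope)))
}

#' Tortuosity of a path
#'
#' Path length divided by end-to-end Euclidean distance, always at least 1.
#' A zero end-to-end displacement is capped at the sentinel `1e6` and
#' flagged via attribute `"capped"`.
#'
#' @param x,y Coordinates of the (observed) path samples, mm.
#' @return Tortuosity (dimensionless, >= 1).
#' @export
tortuosity <- function(x, y) {
  n <- length(x)
  path_len <- sum(sqrt(diff(x)^2 + diff(y)^2))
  disp <- sqrt((x[n] - x[1])^2 + (y[n] - y[1])^2)
  if (disp == 0) return(structure(1e6, capped = TRUE))
  max(1, path_len / disp)
}

#' Convex hull area of a segment's positions
#'
#' Area (mm^2) of the 2D convex hull of the observed positions; 0 for fewer
#' than 3 distinct non-collinear points.
#'
#' @param x,y Coordinates of the (observed) path samples, mm.
#' @return Hull area, mm^2.
#' @export
convex_hull_area <- function(x, y) {
  pts <- unique(cbind(x, y))
  if (nrow(pts) < 3L) return(0)
  h <- grDevices::chull(pts[, 1], pts[, 2])
  hx <- pts[h, 1]; hy <- pts[h, 2]
  abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
}

# Gaussian smoothing with edge renormalisation ("same" convolution divided
# by the local kernel mass)
gauss_smooth <- function(z, sigma_samples) {
  h <- max(1L, ceiling(4 * sigma_samples))
  k <- stats::dnorm(-h:h, sd = sigma_samples)
  num <- stats::convolve(z, rev(k), type = "open")[(h + 1):(h + length(z))]
  den <- stats::convolve(rep(1, length(z)), rev(k),
                         type = "open")[(h + 1):(h + length(z))]
  num / den
}

count_sign_changes <- function(z) {
  s <- sign(z[is.finite(z)])
  s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  sum(diff(s) != 0)
}

#' Curvature scale space descriptors
#'
#' Smooths the coordinate series with Gaussian kernels over a geometric
#' grid of time scales, computes the signed curvature at each scale, and
#' counts its zero crossings. Sharply turning paths retain crossings at
#' coarse scales; straight paths have none at any scale.
#'
#' @param x,y Segment coordinates on the uniform grid, mm.
#' @param fps Frames per second.
#' @param n_scales Number of smoothing scales (default 8).
#' @param sigma_range_ms Range of Gaussian sigmas, in milliseconds
#'   (default 1 to 128 ms, geometric).
#' @return Named vector `c(css_median, css_mean)` of the per-scale crossing
#'   counts; scales whose kernel exceeds the segment length are skipped.
#' @export
css_features <- function(x, y, fps, n_scales = 8L,
                         sigma_range_ms = c(1, 128)) {
  n <- length(x)
  if (n < 32L) return(c(css_median = NA_real_, css_mean = NA_real_))
  sigmas_ms <- exp(seq(log(sigma_range_ms[1]), log(sigma_range_ms[2]),
                       length.out = n_scales))
  counts <- c()
  for (sm in sigmas_ms) {
    sigma_samples <- sm / 1000 * fps
    if (2 * ceiling(4 * sigma_samples) + 1 > n) next  # kernel too wide
    xs <- gauss_smooth(x, max(sigma_samples, 1e-3))
    ys <- gauss_smooth(y, max(sigma_samples, 1e-3))
    i <- 2:(n - 1)
    xp <- (xs[i + 1] - xs[i - 1]) / 2
    yp <- (ys[i + 1] - ys[i - 1]) / 2
    xpp <- xs[i + 1] - 2 * xs[i] + xs[i - 1]
    ypp <- ys[i + 1] - 2 * ys[i] + ys[i - 1]
    denom <- (xp^2 + yp^2)^1.5
    kappa <- ifelse(denom > 0, (xp * ypp - yp * xpp) / denom, 0)
    counts <- c(counts, count_sign_changes(kappa))
  }
  if (length(counts) == 0L)
    return(c(css_median = NA_real_, css_mean = NA_real_))
  c(css_median = stats::median(counts), css_mean = mean(counts))
}

SCALAR_FEATURES <- c("fractal_dimension", "tortuosity", "convex_hull_area",
                     "css_median", "css_mean")

drop_segment <- function(reason) {
  structure(list(reason = reason), class = "moz_drop")
}

# feature vector of one segment, or a "moz_drop" marker naming the failed
# precondition
segment_features <- function(seg, fps) {
  sig <- kinematic_signals(seg$data, fps)
  stats_list <- lapply(sig, function(s) summarise_signal(s$values, s$valid))
  if (any(vapply(stats_list, is.null, logical(1)))) {
    failed <- names(stats_list)[vapply(stats_list, is.null, logical(1))]
    return(drop_segment(paste0("fewer than 4 valid samples for: ",
                               paste(failed, collapse = ","))))
  }
  vec <- unlist(lapply(names(stats_list), function(nm)
    stats::setNames(stats_list[[nm]], paste0(nm, "_", SIGNAL_STATS))))
  obs <- seg$data$observed
  ox <- seg$data$x[obs]; oy <- seg$data$y[obs]
  fd <- fractal_dimension(ox, oy)
  if (is.na(fd))
    return(drop_segment("degenerate path for fractal dimension"))
  css <- css_features(seg$data$x, seg$data$y, fps)
  vec <- c(vec, fractal_dimension = fd,
           tortuosity = as.numeric(tortuosity(ox, oy)),
           convex_hull_area = convex_hull_area(ox, oy), css)
  vec[!is.finite(vec)] <- 0  # documented degenerate-statistic fallback
  vec
}

#' Build the segment feature matrix
#'
#' Computes the full feature battery (10 signals x 10 statistics plus the
#' scalar shape descriptors, 105 features) for every segment, with
#' provenance columns for grouping. Segments failing a precondition (too
#' few valid samples, degenerate path) are dropped; the dropped count and
#' reasons are recorded in attribute `"run_log"`.
#'
#' @param segments List of segments from [segment_track()] (quality-filtered).
#' @param fps Frames per second.
#' @return A `data.frame` with provenance columns
#'   `strain, trial_id, track_id, segment_index, start_t, quality` followed
#'   by the feature columns.
#' @export
build_feature_matrix <- function(segments, fps) {
  rows <- vector("list", length(segments))
  log_lines <- character(0)
  for (k in seq_along(segments)) {
    fv <- segment_features(segments[[k]], fps)
    if (inherits(fv, "moz_drop")) {
      s <- segments[[k]]
      log_lines <- c(log_lines,
        sprintf("dropped %s/%s seg %d: %s", s$trial_id, s$track_id,
                s$segment_index, fv$reason))
      next
    }
    rows[[k]] <- fv
  }
  keep <- !vapply(rows, is.null, logical(1))
  if (!any(keep)) stop("no segments survived feature extraction")
  feat <- do.call(rbind, rows[keep])
  meta <- do.call(rbind, lapply(segments[keep], function(s)
    data.frame(strain = s$strain, trial_id = s$trial_id,
               track_id = s$track_id, segment_index = s$segment_index,
               start_t = s$start_t, quality = s$quality,
               stringsAsFactors = FALSE)))
  out <- cbind(meta, as.data.frame(feat))
  rownames(out) <- NULL
  structure(out, run_log = log_lines,
            feature_names = colnames(feat))
}

#' Feature column names of a feature matrix
#'
#' @param fm A feature matrix from [build_feature_matrix()].
#' @return Character vector of feature column names (provenance excluded).
#' @export
feature_names <- function(fm) {
  fn <- attr(fm, "feature_names")
  if (!is.null(fn)) return(fn)
  setdiff(names(fm), c("strain", "trial_id", "track_id", "segment_index",
                       "start_t", "quality", "label"))
}

#' Simulate a fractional Brownian motion graph
#'
#' Generates the planar graph `(t_i, B_H(t_i))` of a standard fractional
#' Brownian motion with Hurst exponent `H` on `[0, 1]`, via circulant
#' embedding of fractional Gaussian noise. The graph's divider dimension is
#' `2 - H`, which makes it the reference input for validating
#' [fractal_dimension()].
#'
#' @param n Number of steps.
#' @param H Hurst exponent in (0, 1).
#' @param seed Integer seed.
#' @return A two-column matrix of `x` (time) and `y` (motion) coordinates.
#' @export
sim_fbm_graph <- function(n, H, seed = NULL) {
  stopifnot(H > 0, H < 1)
  if (!is.null(seed)) set.seed(seed)
  # autocovariance of fGn at lags 0..n-1 (unit-variance increments)
  k <- 0:(n - 1)
  g <- 0.5 * (abs(k - 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k + 1)^(2 * H))
  # circulant embedding (first row of the 2n-circulant)
  c_row <- c(g, 0, rev(g[-1]))
  ev <- Re(stats::fft(c_row))
  ev[ev < 0] <- 0  # tiny negative eigenvalues from rounding
  m <- length(c_row)
  z <- stats::rnorm(m) + 1i * stats::rnorm(m)
  w <- stats::fft(sqrt(ev / m) * z)
  incr <- Re(w)[1:n] * n^(-H)  # scale increments to grid spacing 1/n
  cbind(x = k / n, y = c(0, cumsum(incr))[1:n])
}
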