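# Track ingestion, gap interpolation, moving-window segmentation and
# segment-quality filtering.

TRACK_COLUMNS <- c("trial_id", "strain", "track_id", "frame", "t", "x", "y")

#' Read track files
#'
#' Reads one or more track CSV files (columns
#' `trial_id,strain,track_id,frame,t,x,y`) into a single validated
#' `data.frame`, sorted by trial, track and time.
#'
#' @param path A directory containing `*.csv` track files, or a character
#'   vector of file paths.
#' @return A `data.frame` of track rows.
#' @export
read_tracks <- function(path) {
  files <- if (length(path) == 1L && dir.exists(path)) {
    list.files(path, pattern = "\\.csv$", full.names = TRUE)
  } else path
  if (length(files) == 0L) stop("no track files found at: ", path)
  parts <- lapply(files, function(f) {
    d <- as.data.frame(data.table::fread(f))
    if (!identical(names(d), TRACK_COLUMNS))
      stop("malformed header in ", f, ": expected columns ",
           paste(TRACK_COLUMNS, collapse = ","))
    for (cc in c("t", "x", "y")) {
      d[[cc]] <- suppressWarnings(as.numeric(d[[cc]]))
      if (anyNA(d[[cc]]))
        stop("non-numeric values in column '", cc, "' of ", f)
    }
    d
  })
  tracks <- do.call(rbind, parts)
  tracks <- tracks[order(tracks$trial_id, tracks$track_id, tracks$t), ,
                   drop = FALSE]
  rownames(tracks) <- NULL
  key <- paste(tracks$trial_id, tracks$track_id)
  dup <- unlist(tapply(tracks$t, key, function(tt) duplicated(tt)))
  if (any(dup)) {
    bad <- unique(key[dup])
    stop("duplicated timestamps within track(s): ",
         paste(utils::head(bad, 5), collapse = "; "))
  }
  tracks
}

# split a track collection into a list of single-track data.frames
split_tracks <- function(tracks) {
  split(tracks, paste(tracks$trial_id, tracks$track_id, sep = "//"),
        drop = TRUE)
}

#' Filter tracks by minimum duration
#'
#' Keeps tracks whose time span is strictly greater than `min_s` (the study
#' imposes a strict lower duration limit of 1 s).
#'
#' @param tracks Track `data.frame`.
#' @param min_s Minimum duration, s.
#' @return The filtered track `data.frame`.
#' @export
filter_min_duration <- function(tracks, min_s = 1.0) {
  if (nrow(tracks) == 0L) return(tracks)
  key <- paste(tracks$trial_id, tracks$track_id, sep = "//")
  span <- tapply(tracks$t, key, function(tt) max(tt) - min(tt))
  keep <- names(span)[span > min_s]
  out <- tracks[key %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Inter-observation gap statistics
#'
#' Median, mean and standard deviation of the time differences between
#' consecutive observed samples, pooled across all (raw, pre-interpolation)
#' tracks.
#'
#' @param tracks Track `data.frame`.
#' @return Named numeric vector `c(median, mean, sd)`, in seconds.
#' @export
gap_statistics <- function(tracks) {
  key <- paste(tracks$trial_id, tracks$track_id, sep = "//")
  ivs <- unlist(tapply(tracks$t, key, diff), use.names = FALSE)
  if (length(ivs) == 0L)
    stop("no inter-observation intervals (all tracks have a single sample)")
  c(median = stats::median(ivs), mean = mean(ivs), sd = stats::sd(ivs))
}

#' Interpolate observation gaps onto a uniform grid
#'
#' Resamples one track onto the uniform `1/fps` grid anchored at its first
#' sample, filling missing grid times by linear interpolation between the
#' bracketing observed samples. The `observed` flag marks samples that
#' existed before interpolation (an observed sample maps to the nearest grid
#' time within half a frame).
#'
#' @param track Single-track `data.frame` (rows of one `trial_id, track_id`).
#' @param fps Frames per second of the grid.
#' @return A `data.frame` with columns
#'   `trial_id, strain, track_id, frame, t, x, y, observed`.
#' @export
interpolate_gaps <- function(track, fps) {
  dt <- 1 / fps
  t0 <- track$t[1]
  span <- track$t[nrow(track)] - t0
  if (span < dt) stop("track spans fewer than 2 frames")
  n <- round(span / dt) + 1L
  grid_t <- t0 + (seq_len(n) - 1L) * dt
  idx <- round((track$t - t0) / dt) + 1L
  ok <- abs(track$t - (t0 + (idx - 1L) * dt)) <= dt / 2 & idx >= 1L & idx <= n
  observed <- logical(n)
  observed[idx[ok]] <- TRUE
  x <- stats::approx(track$t, track$x, xout = grid_t, rule = 2)$y
  y <- stats::approx(track$t, track$y, xout = grid_t, rule = 2)$y
  # keep original coordinates exactly at observed grid points
  x[idx[ok]] <- track$x[ok]
  y[idx[ok]] <- track$y[ok]
  data.frame(trial_id = track$trial_id[1], strain = track$strain[1],
             track_id = track$track_id[1], frame = seq_len(n) - 1L,
             t = grid_t, x = x, y = y, observed = observed,
             stringsAsFactors = FALSE)
}

#' Segmentation configuration
#'
#' @param window_s Window duration, s; positive multiple of the frame
#'   interval.
#' @param overlap_s Overlap between consecutive windows, s; non-negative
#'   multiple of the frame interval, strictly less than `window_s`. The
#'   defaults (8 and 7.5 s) are the tuned values of the gradient-boosted
#'   IR-vs-IS task.
#' @param fps Frames per second.
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(window_s = 8, overlap_s = 7.5, fps = 50) {
  dt <- 1 / fps
  if (window_s <= 0 || abs(window_s / dt - round(window_s / dt)) > 1e-9)
    stop("window_s must be a positive multiple of the frame interval")
  if (overlap_s < 0 || overlap_s >= window_s ||
      abs(overlap_s / dt - round(overlap_s / dt)) > 1e-9)
    stop("overlap_s must be a multiple of the frame interval in [0, window_s)")
  structure(list(window_s = window_s, overlap_s = overlap_s, fps = fps),
            class = "segmentation_config")
}

#' Split an interpolated track into fixed-duration segments
#'
#' Windows start at offsets `k * (window_s - overlap_s)` from the track
#' start, for as long as the whole window fits inside the track; tracks
#' shorter than the window yield zero segments. Every emitted segment has
#' exactly `window_s * fps + 1` samples, which removes track duration as a
#' (direct or indirect) feature.
#'
#' @param itrack Interpolated track from [interpolate_gaps()].
#' @param config A [segmentation_config()].
#' @return A list of segments; each segment is a list with the parent ids,
#'   `segment_index`, `start_t`, the sample `data` slice, and its
#'   [quality_score()].
#' @export
segment_track <- function(itrack, config) {
  stopifnot(inherits(config, "segmentation_config"))
  L <- round(config$window_s * config$fps) + 1L
  step <- round((config$window_s - config$overlap_s) * config$fps)
  n <- nrow(itrack)
  if (n < L) return(list())
  starts <- seq(1L, n - L + 1L, by = step)
  lapply(seq_along(starts), function(k) {
    rows <- starts[k]:(starts[k] + L - 1L)
    d <- itrack[rows, , drop = FALSE]
    list(trial_id = itrack$trial_id[1], strain = itrack$strain[1],
         track_id = itrack$track_id[1], segment_index = k - 1L,
         start_t = itrack$t[starts[k]], data = d,
         quality = quality_score(d$observed))
  })
}

#' Segment quality score
#'
#' Fraction of the segment occupied by its longest run of consecutively
#' interpolated samples: 0 for a fully observed segment, approaching 1 when
#' a single interpolated run spans the segment. Higher scores mean less
#' information content.
#'
#' @param observed Logical vector: `TRUE` where the sample was observed.
#' @return Score in `[0, 1]`.
#' @export
quality_score <- function(observed) {
  if (all(observed)) return(0)
  r <- rle(!observed)
  max(r$lengths[r$values]) / length(observed)
}

# plug-in mutual information (nats) between a numeric feature (16
# equal-frequency bins) and a discrete label, with the Miller-Madow bias
# subtracted and the estimate floored at zero
mi_binned <- function(x, y, bins = 16L) {
  qs <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1L),
                               names = FALSE, type = 7))
  if (length(qs) < 2L) return(0)  # constant feature
  bx <- cut(x, breaks = qs, include.lowest = TRUE)
  tab <- table(bx, y)
  n <- sum(tab)
  p <- tab / n
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  mi <- sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
  bias <- (sum(px > 0) - 1) * (sum(py > 0) - 1) / (2 * n)
  max(0, mi - bias)
}

# weighted average of per-feature maximising thresholds
combine_max_mi_thresholds <- function(tau_star, w) {
  if (sum(w) == 0) return(NA_real_)
  sum(w * tau_star) / sum(w)
}

#' Select the segment-quality threshold by mutual information
#'
#' For each feature and each candidate threshold, segments with quality at
#' most the threshold are retained and the mutual information between the
#' feature and the class label is estimated. Each feature votes for the
#' largest threshold attaining its maximal mutual information; the final
#' threshold is the average of these votes weighted by the features' maximal
#' mutual information. When no feature carries any information the maximum
#' of the grid is returned (no filtering).
#'
#' @param qualities Numeric vector of per-segment quality scores.
#' @param features Numeric matrix or `data.frame`, one row per segment.
#' @param labels Class label per segment.
#' @param grid Candidate thresholds (default 21 evenly spaced on `[0, 1]`).
#' @return The selected threshold, with the per-feature votes and weights in
#'   attribute `"votes"`.
#' @export
select_quality_threshold <- function(qualities, features, labels,
                                     grid = seq(0, 1, length.out = 21)) {
  if (length(grid) == 0L) stop("empty threshold grid")
  features <- as.data.frame(features)
  labels <- as.factor(labels)
  grid <- sort(grid)
  tau_star <- numeric(ncol(features))
  w <- numeric(ncol(features))
  for (j in seq_along(features)) {
    mis <- rep(NA_real_, length(grid))
    for (g in seq_along(grid)) {
      keep <- qualities <= grid[g]
      if (min(table(labels[keep])) < 2L || sum(keep) < 4L) next
      mis[g] <- mi_binned(features[keep, j], labels[keep])
    }
    if (all(is.na(mis))) next
    best <- max(mis, na.rm = TRUE)
    tau_star[j] <- grid[max(which(mis == best))]  # the LARGEST maximiser
    w[j] <- best
  }
  out <- combine_max_mi_thresholds(tau_star, w)
  if (is.na(out)) out <- max(grid)
  structure(out, votes = data.frame(feature = names(features),
                                    tau_star = tau_star, weight = w))
}

#' Filter segments by quality
#'
#' Keeps segments whose quality score does not exceed the threshold.
#'
#' @param segments List of segments from [segment_track()].
#' @param threshold Quality threshold in `[0, 1]`.
#' @return The retained segments.
#' @export
filter_segments <- function(segments, threshold) {
  segments[vapply(segments, function(s) s$quality <= threshold, logical(1))]
}

# interpolate and segment a whole track collection; returns a flat segment
# list
segment_collection <- function(tracks, config) {
  out <- lapply(split_tracks(tracks), function(tr) {
    if (nrow(tr) < 2L) return(list())
    it <- interpolate_gaps(tr, config$fps)
    segment_track(it, config)
  })
  unlist(out, recursive = FALSE, use.names = FALSE)
}
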