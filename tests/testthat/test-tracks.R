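write_track_csv <- function(tracks, file) {
  d <- tracks
  d$t <- sprintf("%.6f", d$t)
  data.table::fwrite(d, file)
  file
}

test_that("track files are read, sorted and validated", {
  dir <- file.path(tempdir(), "mt_read"); unlink(dir, recursive = TRUE)
  dir.create(dir)
  tr <- do.call(rbind, lapply(1:3, function(k)
    make_track(seq(0, 99) + k, seq(0, 99) * 2, track_id = k)))
  write_track_csv(tr, file.path(dir, "S_1.csv"))
  got <- read_tracks(dir)
  expect_equal(nrow(got), 300L)
  expect_equal(length(unique(got$track_id)), 3L)

  # out-of-order rows come back sorted
  shuffled <- tr[sample(nrow(tr)), ]
  write_track_csv(shuffled, file.path(dir, "S_1.csv"))
  expect_equal(read_tracks(file.path(dir, "S_1.csv")), got)

  # duplicated timestamp names the offending track
  dup <- rbind(tr, tr[5, ])
  write_track_csv(dup, file.path(dir, "S_dup.csv"))
  expect_error(read_tracks(file.path(dir, "S_dup.csv")),
               "duplicated timestamps.*T_1 1")

  # malformed header
  writeLines(c("a,b,c", "1,2,3"), file.path(dir, "bad.csv"))
  expect_error(read_tracks(file.path(dir, "bad.csv")), "malformed header")

  # non-numeric coordinates
  bad <- tr; bad$x <- as.character(bad$x); bad$x[3] <- "oops"
  write_track_csv2 <- data.table::fwrite(bad, file.path(dir, "nn.csv"))
  expect_error(read_tracks(file.path(dir, "nn.csv")), "non-numeric.*'x'")
})

test_that("duration filtering is strict at the 1 s limit", {
  tr <- rbind(make_track(0:25 / 5, 0:25 / 5, track_id = 1),      # 0.50 s
              make_track(0:50, 0:50, track_id = 2),              # 1.00 s
              make_track(0:51, 0:51, track_id = 3))              # 1.02 s
  out <- filter_min_duration(tr, 1.0)
  expect_equal(unique(out$track_id), 3L)
  expect_equal(nrow(filter_min_duration(tr[0, ], 1.0)), 0L)
  long <- make_track(0:500, 0:500)
  expect_equal(filter_min_duration(long, 1.0), long)
})

test_that("gap interpolation fills linearly and flags interpolated samples", {
  tr <- make_track(c(0, 1, 3), c(0, 2, 6))
  tr$t <- c(0, 0.02, 0.06)
  it <- interpolate_gaps(tr, 50)
  expect_equal(nrow(it), 4L)
  expect_equal(it$x, c(0, 1, 2, 3))
  expect_equal(it$observed, c(TRUE, TRUE, FALSE, TRUE))

  # gap-free track: identity with all-observed mask
  tr2 <- make_track(seq(0, 10, length.out = 101), rnorm(101))
  it2 <- interpolate_gaps(tr2, 50)
  expect_true(all(it2$observed))
  expect_equal(it2$x, tr2$x)
  expect_equal(it2$y, tr2$y)

  # 25-frame gap: 24 interpolated samples, collinear with the anchors
  # (the parent track is linear, so interpolation must reproduce it exactly)
  full <- make_track((0:99) * 3, (0:99) * 1.5)
  gappy <- full[-(41:64), ]
  it3 <- interpolate_gaps(gappy, 50)
  expect_equal(nrow(it3), 100L)
  expect_equal(sum(!it3$observed), 24L)
  expect_equal(it3$x, full$x)
  expect_equal(it3$y, full$y)
})

test_that("pooled gap statistics follow their definition", {
  # nine intervals of 0.02 s and one of 0.50 s
  tt <- cumsum(c(0, rep(0.02, 5), 0.5, rep(0.02, 4)))
  tr <- make_track(seq_along(tt), seq_along(tt))
  tr$t <- tt
  gs <- gap_statistics(tr)
  expect_equal(unname(gs["median"]), 0.02)
  expect_equal(unname(gs["mean"]), 0.068)

  tr2 <- make_track(0:100, 0:100)
  gs2 <- gap_statistics(tr2)
  expect_equal(unname(gs2), c(0.02, 0.02, 0), tolerance = 1e-12)

  expect_error(gap_statistics(make_track(1, 1)), "no inter-observation")
})

test_that("moving-window segmentation has the expected counts and uniform length", {
  cfg <- segmentation_config(8, 7.5, 50)
  it <- interpolate_gaps(make_track(0:500, rnorm(501)), 50)   # 10.0 s
  segs <- segment_track(it, cfg)
  expect_length(segs, 5L)
  expect_equal(sapply(segs, `[[`, "start_t"), c(0, 0.5, 1, 1.5, 2))
  expect_true(all(sapply(segs, function(s) nrow(s$data)) == 401L))

  short <- interpolate_gaps(make_track(0:394, rnorm(395)), 50)  # 7.88 s
  expect_length(segment_track(short, cfg), 0L)

  exact <- interpolate_gaps(make_track(0:400, rnorm(401)), 50)  # 8.00 s
  expect_length(segment_track(exact, cfg), 1L)

  # zero overlap tiles the track prefix exactly
  cfg0 <- segmentation_config(2, 0, 50)
  segs0 <- segment_track(it, cfg0)
  tiled <- do.call(rbind, lapply(segs0, function(s) s$data[-nrow(s$data), ]))
  expect_equal(tiled$x, it$x[seq_len(nrow(tiled))])

  expect_error(segmentation_config(8, 8, 50), "overlap")
  expect_error(segmentation_config(8, 7.503, 50), "multiple")
})

test_that("quality score is the longest interpolated run fraction", {
  expect_equal(quality_score(rep(TRUE, 100)), 0)
  obs <- rep(TRUE, 400)
  obs[101:140] <- FALSE        # longest run 40
  obs[301:310] <- FALSE        # shorter run
  expect_equal(quality_score(obs), 0.10)
  obs2 <- c(TRUE, rep(FALSE, 399), TRUE)
  expect_equal(quality_score(obs2), 399 / 401)
})

test_that("quality-threshold selection implements the weighted maximum-MI rule", {
  # weighted-average formula: (0.5 * 0.2 + 0.1 * 0.6) / 0.6
  expect_equal(moztrack:::combine_max_mi_thresholds(c(0.2, 0.6), c(0.5, 0.1)),
               0.26666667, tolerance = 1e-6)

  set.seed(1)
  n <- 400
  labels <- rep(c("A", "B"), each = n / 2)
  informative <- ifelse(labels == "A", 0, 3) + rnorm(n)

  # all qualities zero: MI identical at every threshold, so the largest
  # maximiser (max of the grid) wins
  thr <- select_quality_threshold(rep(0, n), data.frame(f = informative),
                                  labels, grid = seq(0, 1, 0.25))
  expect_equal(as.numeric(thr), 1)

  # constant features carry zero MI: fallback to max(grid), weights all 0
  thr2 <- select_quality_threshold(runif(n),
                                   data.frame(f1 = rep(1, n), f2 = rep(2, n)),
                                   labels, grid = seq(0, 1, 0.25))
  expect_equal(as.numeric(thr2), 1)
  expect_true(all(attr(thr2, "votes")$weight == 0))

  expect_error(select_quality_threshold(rep(0, n), data.frame(f = informative),
                                        labels, grid = numeric(0)), "empty")

  # an informative feature whose signal lives in low-quality segments only:
  # the selected threshold lies strictly inside the grid
  qual <- runif(n)
  noisy <- informative
  noisy[qual > 0.5] <- rnorm(sum(qual > 0.5))  # signal destroyed above 0.5
  thr3 <- select_quality_threshold(qual, data.frame(f = noisy), labels)
  expect_lt(as.numeric(thr3), 1)
})

test_that("segment filtering keeps qualities at or below the threshold", {
  mk <- function(q) {
    obs <- rep(TRUE, 100)
    if (q > 0) obs[seq_len(round(q * 100))] <- FALSE
    make_segment(rnorm(100), rnorm(100), obs)
  }
  segs <- lapply(c(0, 0.1, 0.5), mk)
  expect_length(filter_segments(segs, 1.0), 3L)
  expect_length(filter_segments(segs, 0.1), 2L)
  kept0 <- filter_segments(segs, 0)
  expect_length(kept0, 1L)
  expect_true(all(kept0[[1]]$data$observed))
})
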