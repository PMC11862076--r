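test_that("kinematic signals reproduce closed forms for uniform and circular motion", {
  fps <- 50; dt <- 1 / fps
  tt <- (0:200) * dt

  # uniform straight motion x = 50 t
  seg <- make_segment(50 * tt, rep(0, length(tt)))
  sig <- kinematic_signals(seg$data, fps)
  expect_equal(unique(round(sig$vx$values, 9)), 50)
  expect_equal(unique(sig$vy$values), 0)
  expect_equal(unique(sig$dtheta$values), 0)
  expect_true(all(sig$curvature$values[sig$curvature$valid] == 0))

  # uniform circular motion (two full revolutions): |omega| = s / r,
  # |kappa| = 1 / r
  r <- 100; w <- pi; s <- r * w
  seg2 <- make_segment(r * cos(w * tt), r * sin(w * tt))
  sig2 <- kinematic_signals(seg2$data, fps)
  expect_equal(mean(abs(sig2$omega$values)), w, tolerance = 0.02)
  expect_equal(mean(abs(sig2$curvature$values[sig2$curvature$valid])), 1 / r,
               tolerance = 0.02)
  expect_equal(mean(sig2$speed$values), s, tolerance = 0.02)
  # points on a circle: centroid distance nearly constant at the radius
  expect_lt(sd(sig2$cdist$values) / r, 0.01)

  # an interpolated sample invalidates every stencil that touches it
  obs <- rep(TRUE, length(tt)); obs[100] <- FALSE
  sig3 <- kinematic_signals(make_segment(50 * tt, tt, obs)$data, fps)
  expect_false(any(sig3$vx$valid[c(98, 100)]))  # v at i=99,101 uses sample 100
  expect_true(sig3$vx$valid[99])                # v at i=100 does not
  expect_false(any(sig3$ax$valid[c(98, 99, 100)]))
})

test_that("signal summaries match independent reference implementations", {
  # frozen spec cases
  expect_equal(unname(summarise_signal(c(1, -1, 1, -1))["n_zero_cross"]), 3)
  expect_equal(unname(summarise_signal(c(1, 0, 1, 2))["n_zero_cross"]), 1)
  s <- summarise_signal(c(3, 1, 4, 1, 5))
  expect_equal(unname(s["n_local_min"]), 2)
  expect_equal(unname(s["n_local_max"]), 1)

  expect_null(summarise_signal(rnorm(10), valid = c(rep(TRUE, 3), rep(FALSE, 7))))

  # randomised comparison against brute-force loops and e1071 moments
  set.seed(42)
  for (i in 1:200) {
    v <- switch(1 + i %% 3,
                rnorm(sample(6:40, 1)),
                as.numeric(sample(-2:2, sample(6:40, 1), replace = TRUE)),
                round(rnorm(sample(6:40, 1)), 1))
    got <- summarise_signal(v)
    expect_equal(unname(got["mean"]), mean(v))
    expect_equal(unname(got["sd"]), sd(v))
    expect_equal(unname(got[c("q1", "median", "q3")]),
                 unname(quantile(v, c(0.25, 0.5, 0.75), type = 7)))
    if (sd(v) > 0) {
      expect_equal(unname(got["skewness"]), e1071::skewness(v, type = 1))
      expect_equal(unname(got["kurtosis"]), e1071::kurtosis(v, type = 1))
    }
    expect_equal(unname(got["n_zero_cross"]), ref_zero_cross(v))
    ex <- ref_extrema(v)
    expect_equal(unname(got["n_local_min"]), unname(ex["nmin"]))
    expect_equal(unname(got["n_local_max"]), unname(ex["nmax"]))
  }

  # masking: statistics are computed over valid samples only
  v <- c(100, 1, 2, 3, 4, -100)
  valid <- c(FALSE, TRUE, TRUE, TRUE, TRUE, FALSE)
  expect_equal(unname(summarise_signal(v, valid)["mean"]), 2.5)
})

test_that("the divider estimator recovers known dimensions", {
  x <- seq(0, 100, length.out = 401)
  expect_equal(fractal_dimension(x, 0.25 * x), 1.0, tolerance = 0.01)

  # planar Brownian graph: dimension 2 - H = 1.5
  fds <- sapply(1:12, function(i) {
    g <- sim_fbm_graph(4000, 0.5, seed = i)
    fractal_dimension(g[, 1], g[, 2])
  })
  expect_lt(abs(mean(fds) - 1.5), 0.05)

  # rougher paths measure higher than smoother ones
  g3 <- mean(sapply(1:8, function(i) {
    g <- sim_fbm_graph(4000, 0.3, seed = i); fractal_dimension(g[, 1], g[, 2])
  }))
  g9 <- mean(sapply(1:8, function(i) {
    g <- sim_fbm_graph(4000, 0.9, seed = i); fractal_dimension(g[, 1], g[, 2])
  }))
  expect_gt(g3, g9 + 0.4)

  expect_true(is.na(fractal_dimension(rep(1, 20), rep(2, 20))))  # zero length
  expect_true(is.na(fractal_dimension(1:10, 1:10)))              # too short
})

test_that("tortuosity and hull area follow their geometric definitions", {
  x <- seq(0, 10, length.out = 100)
  expect_equal(as.numeric(tortuosity(x, 2 * x)), 1.0, tolerance = 1e-12)

  # semicircular arc: pi * r over chord 2 r
  th <- seq(0, pi, length.out = 2000)
  expect_equal(as.numeric(tortuosity(cos(th), sin(th))), pi / 2,
               tolerance = 1e-4)

  loop <- tortuosity(c(cos(2 * pi * th / pi), 1), c(sin(2 * pi * th / pi), 1e-8))
  expect_gt(as.numeric(loop), 1e4)
  capped <- tortuosity(c(0, 1, 0), c(0, 1, 0))
  expect_equal(as.numeric(capped), 1e6)
  expect_true(attr(capped, "capped"))

  expect_equal(convex_hull_area(c(0, 1, 1, 0), c(0, 0, 1, 1)), 1.0)
  expect_equal(convex_hull_area(c(0, 2, 0), c(0, 0, 2)), 2.0)
  expect_equal(convex_hull_area(1:10, 2 * (1:10)), 0)
  # permutation invariance
  set.seed(3)
  px <- rnorm(50); py <- rnorm(50); o <- sample(50)
  expect_equal(convex_hull_area(px, py), convex_hull_area(px[o], py[o]))
})

test_that("curvature-scale-space counts match a brute-force smoothing oracle", {
  fps <- 50
  tt <- (0:400) / fps

  # straight line: zero crossings at every scale
  css0 <- css_features(100 * tt, 50 * tt, fps)
  expect_equal(unname(css0["css_median"]), 0)
  expect_equal(unname(css0["css_mean"]), 0)

  # sinusoidal path with 8 periods: about 2 crossings per period at the
  # period-resolving scales
  ys <- 30 * sin(2 * pi * 1 * tt)
  oracle <- ref_css_counts(200 * tt, ys, fps)
  expect_equal(max(oracle), 16, tolerance = 0.15)

  # exact agreement with the independent oracle on random walks, and the
  # coarsest scale never exceeds the finest
  set.seed(11)
  for (i in 1:12) {
    x <- cumsum(rnorm(80)); y <- cumsum(rnorm(80))
    counts_pkg <- ref_css_counts(x, y, fps)
    # package medians/means must equal the oracle's
    expect_equal(unname(css_features(x, y, fps)),
                 unname(c(median(counts_pkg), mean(counts_pkg))))
    expect_lte(counts_pkg[length(counts_pkg)], counts_pkg[1])
  }
})

test_that("the feature matrix has a stable schema and the stated invariances", {
  set.seed(9)
  segs <- lapply(1:3, function(i) {
    x <- cumsum(rnorm(401, 2)); y <- cumsum(rnorm(401))
    make_segment(x, y)
  })
  fm <- build_feature_matrix(segs, 50)
  feats <- feature_names(fm)
  expect_length(feats, 105L)  # 10 signals x 10 statistics + 5 scalars
  expect_equal(nrow(fm), 3L)
  expect_false(any(!is.finite(as.matrix(fm[, feats]))))

  # constant-velocity segment: dispersion and crossing features vanish
  tt <- (0:400) / 50
  fm0 <- build_feature_matrix(list(make_segment(100 * tt, 40 * tt)), 50)
  expect_equal(fm0$vx_sd, 0, tolerance = 1e-9)
  expect_equal(fm0$vy_n_zero_cross, 0)
  expect_equal(fm0$speed_sd, 0, tolerance = 1e-9)

  # translation invariance of every feature
  seg <- segs[[1]]
  seg_t <- make_segment(seg$data$x + 500, seg$data$y - 300)
  fm_t <- build_feature_matrix(list(seg, seg_t), 50)
  expect_equal(unlist(fm_t[1, feats]), unlist(fm_t[2, feats]),
               tolerance = 1e-8)

  # rotation: speed/shape features invariant, axis-anchored ones not
  a <- pi / 3
  seg_r <- make_segment(cos(a) * seg$data$x - sin(a) * seg$data$y,
                        sin(a) * seg$data$x + cos(a) * seg$data$y)
  fm_r <- build_feature_matrix(list(seg, seg_r), 50)
  for (f in c("speed_mean", "fractal_dimension", "tortuosity",
              "convex_hull_area", "cdist_mean", "cdist_sd"))
    expect_equal(fm_r[1, f], fm_r[2, f], tolerance = 1e-4)
  expect_gt(abs(fm_r$vy_mean[1] - fm_r$vy_mean[2]), 1e-3)

  # degenerate segments are dropped and logged
  still <- make_segment(rep(1, 401), rep(1, 401))
  fm_d <- build_feature_matrix(list(segs[[2]], still), 50)
  expect_equal(nrow(fm_d), 1L)
  expect_length(attr(fm_d, "run_log"), 1L)
})
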