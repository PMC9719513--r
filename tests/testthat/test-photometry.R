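# detrending, dF/F, event alignment, binarization, correlations

test_that("detrending is the identity on trendless input and flattens decay", {
  tr <- make_trace(function(t) rep(100, length(t)))
  adj <- detrend_trace(tr)
  expect_true(max(abs(adj$F_adj - adj$F_raw)) < 1e-3 * mean(adj$F_raw))
  # pure exponential decay: detrended trace has negligible residual slope
  tr2 <- make_trace(function(t) 50 * exp(-t / 60) + 50, duration_s = 300)
  adj2 <- detrend_trace(tr2)
  sl <- stats::coef(stats::lm(adj2$F_adj ~ adj2$time_s))[2]
  expect_lt(abs(sl) * 300, 0.01 * mean(adj2$F_adj))
})

test_that("detrending recovers transient amplitudes under bleaching", {
  fs <- 100
  t <- seq(0, 300, by = 1 / fs)
  # ten planted 1-s boxcar transients of known fractional amplitude
  onsets <- seq(20, 290, length.out = 10)
  amp <- 0.25
  drive <- rep(0, length(t))
  for (o in onsets) drive[t >= o & t < o + 1] <- amp
  f <- exp(-t / 500) * 100 * (1 + drive)
  adj <- detrend_trace(fluor_trace(t, f))
  # fractional amplitude against the local pre-transient baseline: the
  # additive correction preserves each transient's size relative to the
  # fluorescence level it rides on
  rec <- vapply(onsets, function(o) {
    base_adj <- mean(adj$F_adj[t >= o - 2 & t < o - 0.1])
    base_raw <- mean(adj$F_raw[t >= o - 2 & t < o - 0.1])
    (max(adj$F_adj[t >= o & t < o + 1]) - base_adj) / base_raw
  }, numeric(1))
  expect_true(all(abs(rec - amp) / amp < 0.05))
})

test_that("running-percentile detrending is available and additive", {
  tr <- make_trace(function(t) 100 + 0 * t)
  adj <- detrend_trace(tr, method = "running_percentile")
  expect_equal(adj$F_adj, adj$F_raw)
  expect_identical(attr(adj, "detrend")$method, "running_percentile")
})

test_that("dF/F follows (F - F0)/F0 with context-specific baselines", {
  t <- seq(0, 120, by = 0.01)
  f <- ifelse(t < 60, 100, 110)
  tr <- fluor_trace(t, f, F_adj = f)
  d <- compute_dff(tr, baseline_spec("open_field_pre_object",
                                     stimulus_in_s = 60))
  expect_equal(attr(d, "F0"), 100)
  expect_equal(d$dff[t > 60.01], rep(0.10, sum(t > 60.01)))
  expect_equal(mean(d$dff[t < 60]), 0, tolerance = 1e-9)
  # plus-maze convention: F0 is the whole-trial mean, so mean dF/F is 0
  d2 <- compute_dff(tr, baseline_spec("epm_whole_trial", trial_end_s = 120))
  expect_lt(abs(mean(d2$dff)), 1e-6)
  # inverse: F0 * (1 + dff) reproduces F_adj to machine precision
  expect_equal(attr(d, "F0") * (1 + d$dff), tr$F_adj, tolerance = 1e-12)
  bad <- fluor_trace(t, f, F_adj = f - 200)
  expect_error(compute_dff(bad, baseline_spec("epm_whole_trial",
                                              trial_end_s = 120)),
               "F0 <= 0")
})

test_that("zone means equal a brute-force group-by of frame-matched values", {
  arena <- open_field_arena()
  set.seed(33)
  n <- 250
  tr <- trajectory(seq(0, by = 0.04, length.out = n),
                   runif(n, 0, 40), runif(n, 0, 40), 25)
  z <- assign_zones(tr, arena)
  d <- make_dff(rnorm(1000), fs = 100)
  zm <- zone_mean_dff(d, z)
  vals <- d$dff[sapply(tr$time_s, function(x) which.min(abs(d$time_s - x)))]
  for (lab in c("center", "middle", "peripheral")) {
    sel <- z$zone == lab
    if (any(sel)) expect_equal(unname(zm[lab]), mean(vals[sel]))
  }
  # constant dF/F gives that constant in every visited zone
  dc <- make_dff(rep(0.02, 1000), fs = 100)
  zc <- zone_mean_dff(dc, z)
  expect_true(all(abs(zc[!is.na(zc)] - 0.02) < 1e-12))
})

test_that("event alignment averages events first, then animals", {
  d1 <- make_dff(c(0, 1, 2, 0, 3, 4, 0, 0), fs = 1)
  # windows of 1 sample pre/post around onsets catching [1,2] and [3,4]
  ea <- suppressWarnings(align_to_events(list(a = d1), list(a = c(1.5, 4.5)),
                                         pre_s = 0, post_s = 1))
  expect_equal(unname(ea$per_animal[1, ]), c(2, 3))
  d2 <- make_dff(c(4, 5, 0, 0, 4, 5, 0, 0), fs = 1)
  ea2 <- align_to_events(list(a = d1, b = d2),
                         list(a = c(1.5, 4.5), b = c(0.5, 4.5)),
                         pre_s = 0, post_s = 1)
  expect_equal(unname(ea2$mean), c(3, 4))
  expect_equal(ea2$n_animals, 2)
  # group mean lies within the per-animal envelope
  expect_true(all(ea2$mean >= apply(ea2$per_animal, 2, min) - 1e-12 &
                  ea2$mean <= apply(ea2$per_animal, 2, max) + 1e-12))
})

test_that("nested averaging differs from event pooling when counts differ", {
  set.seed(5)
  fs <- 10
  mk <- function(n_ev, amp) {
    v <- rep(0, 2000)
    on <- seq(40, 1900, length.out = n_ev)
    for (o in on) v[o:(o + 5)] <- amp
    list(dff = make_dff(v, fs = fs), onsets = on / fs)
  }
  a <- mk(10, 1); b <- mk(2, 3)
  ea <- align_to_events(list(a = a$dff, b = b$dff),
                        list(a = a$onsets, b = b$onsets),
                        pre_s = 0.5, post_s = 0.5)
  # brute-force nested oracle
  seg <- function(d, on) t(sapply(on, function(o) {
    i <- which.min(abs(d$time_s - o)); d$dff[(i - 5):(i + 5)]
  }))
  nested <- colMeans(rbind(colMeans(seg(a$dff, a$onsets)),
                           colMeans(seg(b$dff, b$onsets))))
  pooled <- colMeans(rbind(seg(a$dff, a$onsets), seg(b$dff, b$onsets)))
  expect_equal(unname(ea$mean), unname(nested))
  expect_gt(max(abs(nested - pooled)), 0.1)
  # invariance to event and animal order
  ea_r <- align_to_events(list(b = b$dff, a = a$dff),
                          list(b = rev(b$onsets), a = rev(a$onsets)),
                          pre_s = 0.5, post_s = 0.5)
  expect_equal(ea_r$mean, ea$mean)
})

test_that("partial event windows are dropped with a warning", {
  d <- make_dff(rep(1, 100), fs = 10)
  expect_warning(ea <- align_to_events(list(a = d), list(a = c(0.2, 5)),
                                       pre_s = 1, post_s = 1),
                 "partial")
  expect_equal(ea$n_events, 1L)
})

test_that("stimulus windows tile the recording and match direct slicing", {
  d <- make_dff(rep(0, 9000), fs = 10)           # 900 s of zeros
  sw <- stimulus_window_means(d, 450)
  expect_true(all(sw$mean_dff == 0))
  expect_equal(sw$window, c(-15:-1, 1:14))
  # step from 0 to 0.1 at the stimulus
  v <- ifelse((seq_len(9000) - 1) / 10 >= 450, 0.1, 0)
  d2 <- make_dff(v, fs = 10)
  sw2 <- stimulus_window_means(d2, 450)
  expect_true(all(sw2$mean_dff[sw2$window < 0] == 0))
  expect_true(all(abs(sw2$mean_dff[sw2$window > 0] - 0.1) < 1e-12))
  # ramp: direct slicing oracle
  v3 <- seq(0, 1, length.out = 9000)
  d3 <- make_dff(v3, fs = 10)
  sw3 <- stimulus_window_means(d3, 450)
  for (i in seq_len(nrow(sw3))) {
    sel <- d3$time_s >= sw3$start_s[i] & d3$time_s < sw3$end_s[i]
    expect_equal(sw3$mean_dff[i], mean(d3$dff[sel]))
  }
  expect_error(stimulus_window_means(d, 1e5), "outside")
})

test_that("approach-end series excludes the first approach and pairs latencies", {
  d <- make_dff(seq(0, 1, length.out = 1001), fs = 10)  # 100 s ramp
  b <- bout_table(rep(c("approach", "retreat"), 3),
                  c(10, 12, 40, 42, 70, 72), c(12, 14, 42, 44, 72, 74))
  ae <- approach_end_series(d, b)
  expect_equal(nrow(ae), 2)
  expect_equal(ae$end_s, c(42, 72))
  expect_equal(ae$dff_end, d$dff[c(421, 721)])
  expect_equal(ae$latency_s[1], 70 - 42)
  expect_true(is.na(ae$latency_s[2]))
  ae_all <- approach_end_series(d, b, exclude_first = FALSE)
  expect_equal(nrow(ae_all), 3)
  expect_warning(approach_end_series(d, bout_table()), "no approaches")
})

test_that("binarization thresholds at k SD with expected tail fractions", {
  set.seed(11)
  x <- rnorm(2e5)
  tr <- fluor_trace(seq_along(x) / 100, x, F_adj = x)
  up <- binarize_signal(tr)
  expect_equal(mean(up), pnorm(2, lower.tail = FALSE), tolerance = 0.08)
  two <- binarize_signal(tr, sided = "two")
  expect_equal(mean(two), 2 * pnorm(2, lower.tail = FALSE), tolerance = 0.08)
  cst <- fluor_trace(1:100 / 10, rep(1, 100), F_adj = rep(1, 100))
  expect_error(binarize_signal(cst), "SD = 0")
})

test_that("binary Spearman equals the phi coefficient (property over masks)", {
  expect_equal(binarized_activity_correlation(c(1, 1, 0, 0),
                                              c(1, 0, 1, 0))$r, 0)
  m <- c(TRUE, TRUE, FALSE, TRUE, FALSE)
  expect_equal(binarized_activity_correlation(m, m)$r, 1)
  set.seed(99)
  for (i in 1:200) {
    n <- sample(20:200, 1)
    a <- runif(n) < runif(1, 0.1, 0.9)
    b <- runif(n) < runif(1, 0.1, 0.9)
    if (length(unique(a)) < 2 || length(unique(b)) < 2) next
    phi <- {
      t11 <- sum(a & b); t10 <- sum(a & !b)
      t01 <- sum(!a & b); t00 <- sum(!a & !b)
      (t11 * t00 - t10 * t01) /
        sqrt((t11 + t10) * (t01 + t00) * (t11 + t01) * (t10 + t00))
    }
    expect_equal(binarized_activity_correlation(a, b)$r, phi,
                 tolerance = 1e-12)
  }
  # independent long masks decorrelate
  a <- runif(1e5) < 0.3; b <- runif(1e5) < 0.3
  expect_lt(abs(binarized_activity_correlation(a, b)$r), 0.01)
  # constant mask flagged
  expect_true(binarized_activity_correlation(rep(TRUE, 5),
                                             c(1, 0, 1, 0, 1))$degenerate)
})

test_that("summary correlations match rank and linear oracles", {
  x <- 1:10
  p <- summary_correlation(x, 2 * x + 1, "pearson")
  expect_equal(p$r, 1); expect_equal(p$r_squared, 1)
  s <- summary_correlation(x, x^3, "spearman")
  expect_equal(s$r, 1)
  # hand-ranked oracle on 5 fixed pairs (no ties): 1 - 6*sum(d^2)/(n(n^2-1))
  xf <- c(10, 20, 30, 40, 50); yf <- c(1.2, 0.9, 3.5, 2.0, 4.1)
  d2 <- sum((rank(xf) - rank(yf))^2)
  expect_equal(summary_correlation(xf, yf, "spearman")$r,
               1 - 6 * d2 / (5 * 24))
  expect_error(summary_correlation(1:2, 1:2), "at least 3")
})

test_that("spatial heatmap equals a brute-force 2-D group-by", {
  set.seed(21)
  n <- 400
  tr <- trajectory(seq(0, by = 0.04, length.out = n),
                   runif(n, 0, 40), runif(n, 0, 40), 25)
  vals <- rnorm(n)
  d <- make_dff(vals, fs = 25, t0 = 0)
  hm <- spatial_heatmap(d, tr, bin_cm = 4, arena = open_field_arena())
  xi <- pmin(findInterval(tr$x_cm, seq(0, 44, 4)), 11)
  yi <- pmin(findInterval(tr$y_cm, seq(0, 44, 4)), 11)
  for (cx in 1:11) for (cy in 1:11) {
    sel <- xi == cx & yi == cy
    if (any(sel)) expect_equal(hm$mean[cx, cy], mean(vals[sel]))
    else expect_true(is.na(hm$mean[cx, cy]))
  }
  expect_equal(sum(hm$count), n)
  # uniform dF/F fills every visited bin with that value
  du <- make_dff(rep(0.5, n), fs = 25)
  hu <- spatial_heatmap(du, tr, bin_cm = 4, arena = open_field_arena())
  expect_true(all(abs(hu$mean[!is.na(hu$mean)] - 0.5) < 1e-12))
  expect_error(spatial_heatmap(d, tr, bin_cm = 0), "positive")
})
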