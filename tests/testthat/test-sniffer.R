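test_that("background is the window mean and short windows are rejected", {
  tr <- make_trace(co2 = rep(600, 300), ch4 = rep(20, 300))
  expect_equal(estimate_background(tr, "pre"),
               c(bg_ch4 = 20, bg_co2 = 600))
  ramp <- make_trace(co2 = 500:799, ch4 = rep(20, 300))
  expect_equal(estimate_background(ramp, "post")[["bg_co2"]], 649.5)
  expect_error(estimate_background(make_trace(co2 = rep(600, 30)), "pre"),
               "60 s")
})

test_that("the 500-ppm head-position filter retains exactly the right seconds", {
  tr <- make_trace(co2 = c(1200, 1050, 1099, 1101),
                   ch4 = c(120, 100, 105, 110))
  bg <- c(bg_ch4 = 20, bg_co2 = 600)
  out <- correct_and_filter(tr, bg)
  expect_equal(out$t, c(0, 3))                       # diffs 600, 450, 499, 501
  expect_equal(out$co2_corr, c(600, 501))
  expect_equal(out$ch4_corr, c(100, 90))
  # threshold 0 is a vacuous filter; equal-to-background retains nothing
  expect_equal(nrow(correct_and_filter(tr, bg, co2_threshold = 0)), 4)
  flat <- make_trace(co2 = rep(600, 10))
  expect_equal(nrow(correct_and_filter(flat, bg)), 0)
  # corrected CH4 is clipped at zero
  low <- make_trace(co2 = rep(1200, 5), ch4 = rep(5, 5))
  expect_true(all(correct_and_filter(low, bg)$ch4_corr == 0))
  # empty trace passes through as empty, not as an error
  expect_equal(nrow(correct_and_filter(flat[0, ], bg)), 0)
  expect_error(correct_and_filter(tr, c(bg_ch4 = NA, bg_co2 = 600)),
               "finite")
})

test_that("raising the CO2 threshold never increases retained seconds", {
  set.seed(7)
  bg <- c(bg_ch4 = 20, bg_co2 = 600)
  for (i in 1:10) {
    tr <- make_trace(co2 = 600 + runif(200, -200, 3000))
    kept <- vapply(c(0, 250, 500, 750, 1000), function(th) {
      nrow(correct_and_filter(tr, bg, co2_threshold = th))
    }, numeric(1))
    expect_true(all(diff(kept) <= 0))
  }
})

test_that("visit ratio is the ratio of corrected means with a validity floor", {
  corr <- data.frame(t = 0:1, ch4_corr = c(50, 70), co2_corr = c(600, 800))
  vr <- visit_ratio(corr, min_retained = 2)
  expect_equal(vr$ratio, 60 / 700)
  expect_true(vr$valid)
  # proportional series: ratio recovers the constant exactly
  co2 <- runif(100, 500, 3000)
  prop <- data.frame(t = seq_along(co2), ch4_corr = 0.09 * co2,
                     co2_corr = co2)
  expect_equal(visit_ratio(prop, min_retained = 60)$ratio, 0.09)
  # mean-of-ratios sensitivity variant also equals k on proportional series
  expect_equal(visit_ratio(prop, min_retained = 60,
                           method = "mean_of_ratios")$ratio, 0.09)
  # below the retained-second floor the visit is invalid
  short <- prop[1:10, ]
  vr10 <- visit_ratio(short, min_retained = 60)
  expect_false(vr10$valid)
  expect_true(is.na(vr10$ratio))
  # visit ratio lies between the per-second ratio extremes
  set.seed(11)
  for (i in 1:10) {
    d <- data.frame(t = 1:80, ch4_corr = runif(80, 10, 300),
                    co2_corr = runif(80, 500, 3000))
    r <- visit_ratio(d, min_retained = 60)$ratio
    rs <- d$ch4_corr / d$co2_corr
    expect_gte(r, min(rs))
    expect_lte(r, max(rs))
  }
})

test_that("visit ratio is invariant to a common additive shift of trace and background", {
  set.seed(3)
  tr <- make_trace(co2 = 600 + c(rep(0, 20), runif(180, 600, 3000)),
                   ch4 = 20 + c(rep(0, 20), runif(180, 50, 300)))
  bg <- c(bg_ch4 = 20, bg_co2 = 600)
  shift <- 137.5
  tr2 <- tr
  tr2$ch4 <- tr$ch4 + shift
  tr2$co2 <- tr$co2 + shift
  bg2 <- bg + shift
  r1 <- visit_ratio(correct_and_filter(tr, bg))
  r2 <- visit_ratio(correct_and_filter(tr2, bg2))
  expect_equal(r1$ratio, r2$ratio)
  expect_equal(r1$n_retained, r2$n_retained)
})

test_that("peak detection counts well-separated spikes exactly", {
  # 3 isolated spikes in 120 s -> 1.5 peaks/min
  x <- make_spike_train(120, c(20, 60, 100), amplitude = 1)
  er <- eructation_rate(x, duration_s = 120)
  expect_equal(er$n_peaks, 3)
  expect_equal(er$rate, 1.5)
  # flat series has no peaks
  expect_equal(eructation_rate(rep(0.08, 120), 120)$rate, 0)
  expect_error(eructation_rate(x, duration_s = 30), "60 s")
  # injected count recovered exactly for any spacing >= min_distance
  set.seed(5)
  for (i in 1:10) {
    k <- sample(3:8, 1)
    centers <- sort(sample(seq(10, 290, by = 12), k))
    x <- make_spike_train(300, centers, amplitude = runif(1, 0.5, 2))
    expect_equal(eructation_rate(x, 300)$n_peaks, k)
  }
  # peaks closer than min_distance collapse to the taller one
  x2 <- make_spike_train(120, c(50, 55), amplitude = 1)
  expect_equal(eructation_rate(x2, 120, min_distance = 10)$n_peaks, 1)
})

test_that("time after eating measures from the end of the last eating bin", {
  log <- data.frame(
    bin_start = c(27000, 27600, 28200, 28800),   # 07:30..08:00 in 10-min bins
    activity = c("eating", "eating", "ruminating", "lying"))
  # last eating bin 07:40-07:50 ends at 07:50; visit at 10:20 -> 2.5 h
  expect_equal(time_after_eating(log, 37200), 2.5)
  # eating ending exactly at the visit start -> 0 h
  expect_equal(time_after_eating(log, 28200), 0)
  # no prior eating -> missing-covariate flag
  none <- data.frame(bin_start = c(0, 600), activity = c("lying", "lying"))
  expect_true(is.na(time_after_eating(none, 36000)))
  # eating bins after the visit don't count
  expect_true(is.na(time_after_eating(log, 27300)))
})

test_that("ratio adjustment to 0 h inverts the linear time decay", {
  fit <- list(
    fixed = data.frame(
      term = c("intercept", "time", "time:dietLF", "time:dietMF",
               "dietLF", "dietMF"),
      coefficient = c(0.102, -0.0034, 0, 0.001, -0.026, -0.016),
      stringsAsFactors = FALSE),
    diet_levels = c("HF", "LF", "MF"))
  expect_equal(adjust_ratio_to_zero(0.085, 2, "LF", fit), 0.0918)
  expect_equal(adjust_ratio_to_zero(0.085, 0, "LF", fit), 0.085)
  # interaction shifts the diet-specific slope
  expect_equal(adjust_ratio_to_zero(0.085, 2, "MF", fit),
               0.085 + (0.0034 - 0.001) * 2)
  expect_error(adjust_ratio_to_zero(0.085, 2, "XX", fit), "unknown diet")
  # exact inverse of a noise-free generator decay whose diet-specific slope
  # matches the fitted coefficients (slope + interaction per diet)
  truth <- list(slope = -0.0034, offsets = c(HF = 0, LF = -0.026,
                                             MF = -0.016),
                interaction = c(HF = 0, LF = 0, MF = 0.001))
  for (diet in names(truth$offsets)) {
    t <- c(0.5, 2, 6)
    latent0 <- 0.102 + truth$offsets[[diet]]
    measured <- latent0 + (truth$slope + truth$interaction[[diet]]) * t
    expect_equal(adjust_ratio_to_zero(measured, t, diet, fit),
                 rep(latent0, 3))
  }
})

test_that("process_visit assembles a coherent visit summary", {
  set.seed(21)
  cfg <- trace_config(seed = NULL)
  g <- gen_ams_visit(list(cow_id = "c1", base_ratio = 0.102, diet = "HF"),
                     cfg, time_after_eating = 2)
  bg <- gen_background_trace(cfg)
  log <- data.frame(bin_start = c(0, 600), activity = c("eating", "lying"))
  vs <- process_visit(g$trace, bg, activity_log = log, visit_start = 8400,
                      visit_id = "v1", cow_id = "c1", diet = "HF")
  expect_true(vs$valid)
  # the eating bin 0-600 s ends at 600 s; visit at 8400 s
  expect_equal(vs$time_after_eating, (8400 - 600) / 3600)
  expect_lte(vs$n_retained, vs$duration)
  expect_gt(vs$ratio, 0)
  expect_equal(vs$ratio, g$truth$latent_ratio, tolerance = 0.05)
  # pre+post backgrounds are averaged
  vs2 <- process_visit(g$trace, list(pre = bg, post = bg), visit_id = "v1")
  expect_equal(vs2$bg_co2, mean(bg$co2))
})
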