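test_that("positive-control gate calibrates to its own quantile", {
  ctrl <- generate_cytometry_events(cytometry_truth(5000, 0), seed = 1,
                                    label = "FCCP")
  same <- generate_cytometry_events(cytometry_truth(5000, 0), seed = 2)
  pct <- percent_above_threshold(same, ctrl, q = 0.95)
  # a sample from the control distribution sits ~5% above the 95% gate;
  # binomial sd at n = 5000 is ~0.3 pp
  expect_lt(abs(pct - 5), 1.5)
  # all events below the control minimum gate at exactly 0%
  lo <- event_sample(rep(0.001, 50))
  expect_equal(as.numeric(percent_above_threshold(lo, ctrl)), 0)
  expect_warning(percent_above_threshold(ctrl, event_sample(1:10)), "100")
})

test_that("gating is invariant under monotone transforms of both samples", {
  ctrl <- generate_cytometry_events(cytometry_truth(2000, 0), seed = 3)
  samp <- generate_cytometry_events(cytometry_truth(2000, 0.4), seed = 4)
  p0 <- as.numeric(percent_above_threshold(samp, ctrl))
  tf <- function(s, f) event_sample(f(s$intensity), s$label)
  expect_equal(as.numeric(percent_above_threshold(tf(samp, log1p),
                                                  tf(ctrl, log1p))), p0)
  expect_equal(as.numeric(percent_above_threshold(tf(samp, sqrt),
                                                  tf(ctrl, sqrt))), p0)
})

test_that("mixture recovery is unbiased within binomial error across seeds", {
  ctrl <- generate_cytometry_events(cytometry_truth(10000, 0), seed = 100,
                                    label = "control")
  pcts <- vapply(1:50, function(s) {
    smp <- generate_cytometry_events(cytometry_truth(10000, 0.7), seed = s)
    as.numeric(percent_above_threshold(smp, ctrl, q = 0.95))
  }, numeric(1))
  # the q = 0.95 gate passes 5% of low-population events by design, so the
  # expected readout is pi_high + (1 - pi_high) * 0.05 = 71.5%
  expected <- 100 * (0.7 + 0.3 * 0.05)
  binom_sd <- 100 * sqrt(0.715 * 0.285 / 10000)
  expect_true(all(abs(pcts - expected) < 4 * binom_sd))
  # aggregate recovery of the planted mixing proportion
  expect_lt(abs(mean(pcts) - 70), 2)
})

test_that("event statistics match hand-computed values and scale linearly", {
  s <- event_sample(c(1, 2, 4, 8))
  st <- event_statistics(s)
  expect_equal(st$mean, 3.75)
  expect_equal(st$median, 3)
  expect_equal(st$geo_mean, (1 * 2 * 4 * 8)^(1 / 4))  # 2.828
  # constant sample: all three equal the constant
  stc <- event_statistics(event_sample(rep(7, 10)))
  expect_equal(unlist(stc[c("mean", "median", "geo_mean")]),
               c(mean = 7, median = 7, geo_mean = 7))
  # doubling doubles all three
  st2 <- event_statistics(event_sample(c(2, 4, 8, 16)))
  expect_equal(unlist(st2[c("mean", "median", "geo_mean")]),
               2 * unlist(st[c("mean", "median", "geo_mean")]))
  # zeros are excluded from the geometric mean and counted
  stz <- event_statistics(event_sample(c(0, 0, 1, 4)))
  expect_equal(stz$geo_mean, 2)
  expect_equal(stz$n_zero, 2)
  expect_true(is.na(event_statistics(event_sample(c(0, 0)))$geo_mean))
})

test_that("ratio-to-normalizer handles plate and densitometry dialects", {
  pt <- data.frame(well = c("a", "b"), group = c("g1", "g1"),
                   signal = c(300, 500), normalizer = c(150, 250))
  r <- ratio_to_normalizer(pt)
  expect_equal(r$units$ratio, c(2, 2))
  expect_equal(r$groups$ratio_mean, 2)
  # common gain cancels
  pt2 <- pt; pt2$signal <- pt2$signal * 3.7; pt2$normalizer <- pt2$normalizer * 3.7
  expect_equal(ratio_to_normalizer(pt2)$units$ratio, r$units$ratio)
  expect_error(ratio_to_normalizer(
    data.frame(well = "w", group = "g", signal = 1, normalizer = 0)), "w")
})

test_that("densitometry ratios recover the planted fold structure", {
  # lanes built as (target, control) = (6.72 k, k): group mean ratio 6.72
  dt <- data.frame(lane = paste0("L", 1:3), group = "scr",
                   target = "asyn", control = "Alix",
                   target_intensity = 6.72 * c(800, 1000, 1300),
                   control_intensity = c(800, 1000, 1300))
  r <- ratio_to_normalizer(dt)
  expect_equal(r$groups$ratio_mean, 6.72)
  # reference-group rescaling: reference reports exactly 1
  dt2 <- generate_densitometry_table(c(ctrl = 1.5, tr = 3.0), n_lanes = 4,
                                     seed = 11)
  rr <- ratio_to_normalizer(dt2, reference = "ctrl")
  expect_equal(rr$groups$ratio_mean[rr$groups$group == "ctrl"], 1)
  expect_equal(rr$groups$ratio_mean[rr$groups$group == "tr"],
               2, tolerance = 0.15)  # ~ratio of planted ratios
  expect_error(ratio_to_normalizer(dt2, reference = "nope"), "not found")
})

test_that("event samples round-trip through both CSV dialects", {
  s <- generate_cytometry_events(cytometry_truth(200, 0.5), seed = 6,
                                 label = "tmrm")
  f1 <- tempfile(fileext = ".csv")
  write.csv(data.frame(intensity = s$intensity), f1, row.names = FALSE)
  b1 <- read_event_csv(f1)
  expect_equal(b1$intensity, s$intensity)
  f2 <- tempfile(fileext = ".csv")
  write.csv(data.frame(sample = rep(c("a", "b"), each = 100),
                       intensity = s$intensity), f2, row.names = FALSE)
  b2 <- read_event_csv(f2)
  expect_named(b2, c("a", "b"))
  expect_equal(b2$a$intensity, s$intensity[1:100])
})
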