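test_that("noise-free flux plates reproduce the phase structure exactly", {
  plate <- canonical_plate()
  d <- plate$data
  expect_equal(nrow(d), 13)  # 4 basal + 3 per injection
  expect_identical(rle(d$phase)$values, c("basal", "oligo", "fccp", "rot_aa"))
  expect_identical(rle(d$phase)$lengths, c(4L, 3L, 3L, 3L))
  means <- tapply(d$OCR, d$phase, mean)
  # post-oligomycin = nonmito + (1 - coupled) * (basal - nonmito) = 40
  expect_equal(as.numeric(means[c("basal", "oligo", "fccp", "rot_aa")]),
               c(100, 40, 180, 20))
  expect_equal(d$ECAR, rep(10, 13))
  # cycle timestamps: 30 s mix + 3 min acquisition each
  expect_equal(d$time_min, 3.5 * (1:13))
})

test_that("flux generator is seed-deterministic and scales with cell count", {
  tr <- flux_truth(100, 20, 0.75, 180, noise_sd = 5, scale = c(1, 2),
                   n_wells = 2)
  p1 <- generate_flux_plate(tr, seed = 11)
  p2 <- generate_flux_plate(tr, seed = 11)
  p3 <- generate_flux_plate(tr, seed = 12)
  expect_identical(p1$data, p2$data)
  expect_identical(p1$norm_signal, p2$norm_signal)
  expect_false(identical(p1$data$OCR, p3$data$OCR))
  # doubled cell count roughly doubles signal and OCR
  expect_gt(p1$norm_signal[["W02"]] / p1$norm_signal[["W01"]], 1.8)
})

test_that("flux truth and schedule invariants are enforced", {
  expect_error(flux_truth(100, 120, 0.5, 180), "non-mito")
  expect_error(flux_truth(100, 20, 1.5, 180), "coupled_frac")
  expect_error(flux_truth(100, 20, 0.5, 80), "maximal")
  expect_s3_class(flux_truth(100, 20, 0.5, 80, allow_low_maximal = TRUE),
                  "flux_truth")
  expect_error(flux_truth(100, 20, 0.5, 180, noise_sd = -1), "noise_sd")
  expect_error(injection_schedule(c(oligo = 3L, basal = 4L, fccp = 3L,
                                    rot_aa = 3L)), "order")
  expect_error(injection_schedule(c(basal = 0L, oligo = 3L, fccp = 3L,
                                    rot_aa = 3L)), "positive")
})

test_that("planted ellipses carry their analytic shape truth", {
  tr <- mito_truth_fixed(
    data.frame(a = c(10, 20), b = c(10, 5), theta = c(0, 1),
               row = c(50, 150), col = c(50, 150)), size = 224)
  expect_equal(tr$objects$a / tr$objects$b, c(1, 4))   # aspect ratio
  expect_equal(tr$objects$b / tr$objects$a, c(1, 0.25)) # roundness
  expect_error(mito_truth_fixed(data.frame(a = 5, b = 10, theta = 0,
                                           row = 50, col = 50)), "a >= b")
  expect_error(mito_truth_fixed(data.frame(a = 30, b = 10, theta = 0,
                                           row = 10, col = 50)), "inside")
})

test_that("zero objects give a blank image and empty label map", {
  im <- generate_mito_image(mito_truth(0, size = 64, noise_sd = 1))
  expect_equal(max(im$labels), 0)
  expect_lt(diff(range(im$image)), 10)  # background noise only
})

test_that("random packing errors out when infeasible and labels match image", {
  expect_error(mito_truth(500, size = 64), "packing")
  im <- generate_mito_image(mito_truth(8, size = 128, noise_sd = 2, seed = 4))
  expect_equal(max(im$labels), 8)
  # labeled pixels sit well above background: mean + 2 sd rule
  bg <- im$image[im$labels == 0]
  expect_true(all(im$image[im$labels > 0] > mean(bg) + 2 * sd(bg)))
  # determinism
  im2 <- generate_mito_image(mito_truth(8, size = 128, noise_sd = 2, seed = 4))
  expect_identical(im$image, im2$image)
})

test_that("tandem generator enforces reporter topology and exposes truth", {
  im <- generate_tandem_reporter_image(red_counts = c(10, 5, 7, 0),
                                       green_counts = c(4, 0, 7, 0),
                                       tiles_r = 2, tiles_c = 2, seed = 2)
  expect_equal(im$cells$autolysosomes, c(6, 5, 0, 0))
  expect_equal(im$cells$autophagosomes, c(4, 0, 7, 0))
  expect_true(all(im$cells$red >= im$cells$green))
  expect_error(generate_tandem_reporter_image(red_counts = 3, green_counts = 5,
                                              tiles_r = 1, tiles_c = 1),
               "green")
})

test_that("cytometry mixture generator hits its mixing proportion", {
  tr <- cytometry_truth(10000, pi_high = 0.6)
  s <- generate_cytometry_events(tr, seed = 9)
  midpoint <- exp((tr$meanlog_low + tr$meanlog_high) / 2)
  frac <- mean(s$intensity > midpoint)
  # binomial sd at n = 10000 is sqrt(.6*.4/1e4) ~ 0.005; allow 4 sd
  expect_lt(abs(frac - 0.6), 0.02)
  # degenerate mixtures
  lo <- generate_cytometry_events(cytometry_truth(500, 0), seed = 1)
  hi <- generate_cytometry_events(cytometry_truth(500, 1), seed = 1)
  expect_true(all(lo$intensity < midpoint))
  expect_true(all(hi$intensity > midpoint))
  expect_identical(generate_cytometry_events(tr, seed = 9)$intensity,
                   s$intensity)
})

test_that("plate and densitometry table generators are seeded and structured", {
  pt <- generate_plate_table(c(control = 1, treated = 3), n_wells = 4,
                             seed = 5)
  expect_equal(nrow(pt), 8)
  expect_true(all(pt$normalizer > 0))
  expect_identical(pt, generate_plate_table(c(control = 1, treated = 3),
                                            n_wells = 4, seed = 5))
  dt <- generate_densitometry_table(c(a = 1, b = 2.5), n_lanes = 3, seed = 5)
  expect_equal(nrow(dt), 6)
  expect_true(all(dt$control_intensity > 0))
})
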