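test_that("phase summary reproduces the hand-worked respiration partition", {
  s <- summarize_phases(canonical_plate())
  expect_equal(s$ocr_tot, 100)
  expect_equal(s$ocr_mito, 80)      # basal - rot/AA
  expect_equal(s$ocr_coupled, 60)   # basal - post-oligomycin
  expect_equal(s$ocr_leak, 20)      # post-oligomycin - rot/AA
  expect_equal(s$src_pct, 180)      # maximal / basal x 100
  # decomposition identities, exact
  expect_identical(s$ocr_coupled + s$ocr_leak, s$ocr_mito)
  expect_identical(s$ocr_coupled + s$ocr_leak + s$ocr_ra, s$ocr_tot)
})

test_that("phase summary averages cycles and supports last-cycle mode", {
  plate <- canonical_plate()
  plate$data$OCR[plate$data$phase == "basal"] <- c(90, 100, 110, 100)
  expect_equal(summarize_phases(plate)$ocr_tot, 100)
  expect_equal(summarize_phases(plate, method = "last")$ocr_tot, 100)
  plate$data$OCR[plate$data$phase == "oligo"] <- c(60, 45, 42)
  expect_equal(summarize_phases(plate, method = "last")$ocr_oligo, 42)
  # basal = maximal gives SRC exactly 100%
  tr <- flux_truth(100, 20, 0.75, 100, noise_sd = 0)
  expect_equal(summarize_phases(generate_flux_plate(tr))$src_pct, 100)
})

test_that("missing phases and disordered phases are reported by well", {
  plate <- canonical_plate()
  plate$data <- plate$data[plate$data$phase != "fccp", ]
  expect_error(summarize_phases(plate), "W01.*fccp")
  plate2 <- canonical_plate()
  plate2$data$phase <- rev(plate2$data$phase)
  expect_error(summarize_phases(plate2), "order")
})

test_that("glycolytic PPR matches the calculator-checked formula value", {
  k <- bioenergetic_constants(ph = 7.4, pk1 = 6.093, buffering_power = 0.1,
                              max_h_per_o2 = 1)
  # hand evaluation: 10/0.1 - 80 * 10^1.307 / (1 + 10^1.307)
  hand <- 100 - 80 * (10^1.307 / (1 + 10^1.307))
  expect_equal(compute_ppr_glyc(10, 80, k), hand, tolerance = 1e-10)
  # CO2 term vanishes without mitochondrial respiration
  expect_equal(compute_ppr_glyc(10, 0, k), 100)
  # at pH = pK1 the CO2 correction factor is exactly 1/2
  k2 <- bioenergetic_constants(ph = 6.5, pk1 = 6.5, buffering_power = 1,
                               max_h_per_o2 = 1)
  expect_equal(suppressWarnings(compute_ppr_glyc(0, 2, k2)), -1)
  expect_warning(compute_ppr_glyc(0.01, 80, k), "negative")
})

test_that("ATP partition follows the stated stoichiometry", {
  k <- bioenergetic_constants(buffering_power = 0.1, po_oxphos = 2.5,
                              po_tca = 0.1, po_glyc = 0.1,
                              atp_per_lactate = 1)
  s <- data.frame(well = "W01", ocr_coupled = 60, ocr_mito = 80,
                  ecar_tot = 10)
  a <- compute_atp_rates(s, ppr_glyc = 20, constants = k)
  expect_equal(a$atp_ox, 60 * 2 * 2.5 + 80 * 2 * 0.1)  # 316
  expect_equal(a$atp_glyc, 20 * 1 + 80 * 2 * 0.1)      # 36
  expect_equal(a$atp_total, 352)
  # all-zero summary gives all-zero rates
  z <- compute_atp_rates(data.frame(well = "z", ocr_coupled = 0,
                                    ocr_mito = 0, ecar_tot = 0),
                         constants = k)
  expect_equal(unlist(z[c("ppr_glyc", "atp_glyc", "atp_ox", "atp_total")]),
               c(ppr_glyc = 0, atp_glyc = 0, atp_ox = 0, atp_total = 0))
})

test_that("total ATP conservation and ECAR monotonicity hold on random inputs", {
  set.seed(101)
  n <- 1000
  s <- data.frame(well = sprintf("w%04d", 1:n),
                  ocr_coupled = runif(n, 0, 200),
                  ocr_mito = runif(n, 0, 300),
                  ecar_tot = runif(n, 0, 50))
  k <- bioenergetic_constants()
  a <- suppressWarnings(compute_atp_rates(s, constants = k))
  expect_identical(a$atp_total, a$atp_ox + a$atp_glyc)  # exact, all inputs
  # strictly increasing in ECAR, everything else fixed
  s2 <- s; s2$ecar_tot <- s$ecar_tot + 1
  a2 <- suppressWarnings(compute_atp_rates(s2, constants = k))
  expect_true(all(a2$ppr_glyc > a$ppr_glyc))
  expect_true(all(a2$atp_glyc > a$atp_glyc))
  expect_identical(a2$atp_ox, a$atp_ox)
})

test_that("fully coupled, no-residual limit recovers the total-OCR bound", {
  tr <- flux_truth(basal = 120, nonmito = 0, coupled_frac = 1, maximal = 150,
                   noise_sd = 0)
  s <- summarize_phases(generate_flux_plate(tr))
  k <- bioenergetic_constants()
  a <- compute_atp_rates(s, ppr_glyc = 0, constants = k)
  expect_equal(a$atp_ox, 120 * 2 * k$po_oxphos + 120 * 2 * k$po_tca)
})

test_that("cell-density normalization rescales wells against the plate mean", {
  s <- data.frame(well = c("a", "b"), ocr_tot = c(100, 200),
                  src_pct = c(180, 180))
  sig <- c(a = 1000, b = 1000)
  expect_equal(normalize_by_signal(s, sig)$ocr_tot, c(100, 200))  # identity
  sig2 <- c(a = 1000, b = 2000)
  n2 <- normalize_by_signal(s, sig2)
  # well b has double the signal: rates halved relative to well a
  expect_equal(n2$ocr_tot[2] / n2$ocr_tot[1], 1)
  expect_equal(n2$src_pct, c(180, 180))  # ratios of rates are untouched
  expect_error(normalize_by_signal(s, c(a = 1000, b = -5)), "b")
  expect_error(normalize_by_signal(s, c(a = 1000)), "signal")
})

test_that("normalization recovers per-cell rates under 2-fold density spread", {
  # scales average exactly 1, spanning 2-fold
  scales <- rep(c(2 / 3, 1, 4 / 3), each = 4)
  tr <- flux_truth(100, 20, 0.75, 180, noise_sd = 2, scale = scales,
                   n_wells = 12)
  plate <- generate_flux_plate(tr, seed = 21)
  raw <- summarize_phases(plate)
  norm <- normalize_by_signal(raw, plate$norm_signal)
  expect_gt(max(abs(raw$ocr_tot - 100)), 15)   # raw is density-confounded
  expect_lt(max(abs(norm$ocr_tot - 100)), 10)  # normalized recovers truth
  expect_lt(abs(mean(norm$ocr_tot) - 100), 2)
})

test_that("flux plates round-trip through CSV", {
  plate <- canonical_plate(noise_sd = 3, n_wells = 2, seed = 8)
  csv <- tempfile(fileext = ".csv"); norm <- tempfile(fileext = ".csv")
  write_flux_plate(plate, csv, norm)
  back <- read_flux_plate(csv, norm)
  expect_equal(back$data, plate$data)
  expect_equal(back$norm_signal, plate$norm_signal)
  expect_equal(analyze_flux_plate(back), analyze_flux_plate(plate))
  # column remapping for external dialects
  d2 <- plate$data
  names(d2)[names(d2) == "OCR"] <- "ocr_pmol_min"
  f2 <- tempfile(fileext = ".csv")
  write.csv(d2, f2, row.names = FALSE)
  back2 <- read_flux_plate(f2, column_map = c(OCR = "ocr_pmol_min"))
  expect_equal(back2$data$OCR, plate$data$OCR)
})
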