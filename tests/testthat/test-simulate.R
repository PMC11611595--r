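test_that("simulation is bit-identical under a fixed seed", {
  cfg <- small_sim(seed = 3)
  lib1 <- build_formula_library(cfg)
  lib2 <- build_formula_library(cfg)
  expect_identical(lib1, lib2)
  s1 <- simulate_peak_tables(cfg, lib1)
  s2 <- simulate_peak_tables(cfg, lib2)
  expect_identical(s1, s2)
  q1 <- suppressWarnings(simulate_quant_tables(cfg))
  q2 <- suppressWarnings(simulate_quant_tables(cfg))
  expect_identical(q1, q2)
})

test_that("catalog respects element bounds and the detection window", {
  cfg <- small_sim(seed = 6)
  cfg$formula_library_size <- 300
  lib <- build_formula_library(cfg)
  expect_equal(nrow(lib), 300)
  expect_true(all(lib$C >= 5 & lib$C <= 56))
  expect_true(all(lib$N >= 0 & lib$N <= 3))
  expect_true(all(lib$S <= 3 & lib$P <= 2))
  expect_true(all(lib$mz >= 200 & lib$mz <= 900))
  expect_equal(mean(lib$N > 0), cfg$n_fraction, tolerance = 0.12)
  expect_false(any(duplicated(lib$formula)))
})

test_that("forced formulas enter the catalog at the right mass", {
  cfg <- small_sim(seed = 2)
  cfg$formula_library_size <- 1
  cfg$n_calibration_series <- 0
  lib <- build_formula_library(cfg, force_formulas = "C13H21O3N3")
  expect_true("C13H21N3O3" %in% lib$formula)
  expect_equal(round(lib$mz[lib$formula == "C13H21N3O3"], 3), 266.151)
  bad <- small_sim(seed = 2)
  bad$formula_library_size <- 0
  bad$n_calibration_series <- 0
  expect_error(build_formula_library(bad), "configuration error")
})

test_that("emitted peaks carry the configured calibration offset", {
  cfg <- small_sim(seed = 4, calibration_offset_ppm = 2,
                   mass_jitter_ppm = 0, n_noise_peaks = 0,
                   isotopologue_rate = 0, blank_contaminant_count = 0)
  sim <- simulate_peak_tables(cfg)
  gt <- sim$ground_truth$catalog
  for (s in sim$samples[1:5]) {
    obs <- s$peaks$mz
    ppm <- vapply(obs, function(m) {
      i <- which.min(abs(gt$mz - m / (1 + 2e-6)))
      (m / gt$mz[i] - 1) * 1e6
    }, numeric(1))
    expect_equal(ppm, rep(2, length(ppm)), tolerance = 1e-6)
  }
})

test_that("isotopologue partners follow the 1.1% per carbon model", {
  cfg <- small_sim(seed = 8, isotopologue_rate = 1, mass_jitter_ppm = 0,
                   n_noise_peaks = 0, blank_contaminant_count = 0,
                   n_calibration_series = 0)
  cfg$formula_library_size <- 1
  lib <- build_formula_library(cfg, force_formulas = "C20H32O8")
  lib <- lib[lib$formula == "C20H32O8", , drop = FALSE]
  lib$base_presence <- 1
  sim <- simulate_peak_tables(cfg, lib)
  s <- sim$samples[[1]]
  expect_equal(n_peaks(s), 2)
  expect_equal(diff(s$peaks$mz), 1.003355, tolerance = 1e-6)
  expect_equal(s$peaks$intensity[2] / s$peaks$intensity[1],
               0.011 * 20, tolerance = 1e-9)
})

test_that("zero presence boost gives exchangeable treatments", {
  cfg <- small_sim(seed = 10, drought_presence_boost = 0)
  sim <- simulate_peak_tables(cfg)
  mm <- truth_molecule_matrix(sim)
  # same presence-generating process: per-molecule presence rates agree
  d <- mm$metadata$treatment == "drought"
  rate_d <- colMeans(mm$presence[d, ])
  rate_c <- colMeans(mm$presence[!d, ])
  expect_equal(mean(rate_d), mean(rate_c), tolerance = 0.02)
  # and day-level response ratios are centred near zero over replicates;
  # the ratio statistic carries an O(CV^2) small-sample bias, so this is
  # checked at a catalog size where day-mean RA noise is small
  rrs <- vapply(1:20, function(seed) {
    s <- simulate_peak_tables(sim_config(formula_library_size = 1000,
                                         seed = seed,
                                         drought_presence_boost = 0))
    mean(response_ratio_series(truth_molecule_matrix(s))$response_ratio)
  }, numeric(1))
  se <- sd(rrs) / sqrt(length(rrs))
  expect_lt(abs(mean(rrs)), 2 * se + 1e-9)
})

test_that("ground truth accounts for every non-noise, non-isotopologue peak", {
  cfg <- small_sim(seed = 12, n_noise_peaks = 0, isotopologue_rate = 0,
                   blank_contaminant_count = 0, mass_jitter_ppm = 0,
                   calibration_offset_ppm = 1.5)
  sim <- simulate_peak_tables(cfg)
  gt <- sim$ground_truth$catalog
  off <- 1 + 1.5e-6
  for (s in sim$samples[c(1, 45, 90)]) {
    back <- s$peaks$mz / off
    i <- vapply(back, function(m) which.min(abs(gt$mz - m)), integer(1))
    expect_equal(back, gt$mz[i], tolerance = 1e-8)
    pres <- sim$ground_truth$presence[s$sample_id, ]
    expect_true(all(pres[gt$id[i]] == 1))
  }
})

test_that("quantitative tables express the configured drought effects", {
  # law of large numbers on the generator: pool many seeds
  ratios <- vapply(1:30, function(seed) {
    q <- suppressWarnings(simulate_quant_tables(small_sim(seed = seed)))
    b <- exudate_balance(q)
    tr <- b[b$phase == "treatment", ]
    mean(tr$TON_conc[tr$treatment == "drought"]) /
      mean(tr$TON_conc[tr$treatment == "control"])
  }, numeric(1))
  expect_equal(mean(ratios), 1.69, tolerance = 0.08)
  q <- suppressWarnings(simulate_quant_tables(small_sim(seed = 1)))
  expect_true(all(q$NH4N_conc == 0))
  # inorganic N is about 20% of total N
  expect_equal(mean(q$NO3N_conc / q$TN_conc), 0.2, tolerance = 0.03)
  # null effects: no systematic treatment difference
  cfg0 <- small_sim(seed = 2)
  cfg0$quant_effects <- list(
    treatment = c(TOC = 1, TON = 1, amino_acids = 1),
    recovery = c(TOC = 1, TON = 1, amino_acids = 1))
  means <- rowMeans(vapply(1:25, function(s) {
    cfg0$seed <- s
    q0 <- suppressWarnings(simulate_quant_tables(cfg0))
    tr <- q0[q0$phase == "treatment", ]
    c(mean(tr$TOC_conc[tr$treatment == "drought"]),
      mean(tr$TOC_conc[tr$treatment == "control"]))
  }, numeric(2)))
  expect_equal(means[1], means[2], tolerance = 1.5)
})

test_that("written datasets are reproducible and complete", {
  d <- withr::local_tempdir()
  cfg <- small_sim(seed = 5)
  sim <- simulate_peak_tables(cfg)
  q <- suppressWarnings(simulate_quant_tables(cfg))
  write_simulated_dataset(sim, d, quant = q)
  expect_true(file.exists(file.path(d, "design.tsv")))
  expect_true(file.exists(file.path(d, "blanks.tsv")))
  expect_true(file.exists(file.path(d, "quant.tsv")))
  expect_true(file.exists(file.path(d, "ground_truth.json")))
  files <- list.files(file.path(d, "peaks"))
  expect_equal(length(files), nrow(sim$design))
  # a written table reads back into the same spectrum
  s1 <- sim$samples[[1]]
  back <- read_peak_table(file.path(d, "peaks",
                                    paste0(s1$sample_id, ".tsv")))
  expect_equal(back$peaks$mz, s1$peaks$mz, tolerance = 1e-12)
})
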