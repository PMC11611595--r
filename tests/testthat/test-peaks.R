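test_that("peak tables are read, sorted, and validated", {
  d <- withr::local_tempdir()
  path <- file.path(d, "s1.tsv")
  tab <- data.frame(mz = c(500.1, 210.2, 330.3), intensity = c(1, 2, 3),
                    snr = c(10, 20, 30))
  write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  spec <- read_peak_table(path)
  expect_equal(n_peaks(spec), 3)
  expect_identical(spec$sample_id, "s1")
  expect_false(is.unsorted(spec$peaks$mz))
  expect_equal(sort(spec$peaks$intensity), c(1, 2, 3))

  bad <- file.path(d, "bad.tsv")
  write.table(data.frame(mass = 1, intensity = 2, snr = 3), bad,
              sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_peak_table(bad), "mz")
  expect_error(read_peak_table(file.path(d, "absent.tsv")), "no such file")
})

test_that("S/N filter is strictly greater-than", {
  spec <- mk_spec(c(300, 301, 302), snr = c(7.0, 7.01, 6.99))
  out <- filter_snr(spec)
  expect_equal(out$peaks$mz, 301)
  expect_equal(n_peaks(filter_snr(spec, 0)), 3)
  # oracle: brute-force list filter on a random spectrum
  r <- random_spec(200, seed = 3)
  expect_equal(filter_snr(r, 12)$peaks,
               r$peaks[r$peaks$snr > 12, ], ignore_attr = TRUE)
})

test_that("m/z window is closed at both ends", {
  spec <- mk_spec(c(199.99, 200.00, 550, 900.00, 900.01))
  out <- filter_mz_window(spec)
  expect_equal(out$peaks$mz, c(200.00, 550, 900.00))
  expect_equal(n_peaks(filter_mz_window(spec, 0, 1e6)), 5)
  expect_error(filter_mz_window(spec, 900, 200), "low")
})

test_that("S/N and window filters commute", {
  for (seed in 1:5) {
    r <- random_spec(120, seed = seed)
    a <- filter_mz_window(filter_snr(r, 10))
    b <- filter_snr(filter_mz_window(r), 10)
    expect_equal(a$peaks, b$peaks)
  }
})

# CH2 series at exact theoretical masses, scaled by a ppm offset
series_spec <- function(offset_ppm = 0, n = 8, extra_mz = numeric(0)) {
  base <- formula_mass(parse_formula("C10H16O5"), "deprotonated_mz")
  mz <- base + 14.0156500638 * (0:(n - 1))
  mk_spec(sort(c(mz * (1 + offset_ppm * 1e-6), extra_mz)))
}

test_that("internal calibration recovers a uniform ppm offset", {
  cal0 <- calibrate_internal(series_spec(0))
  expect_true(cal0$calibrated)
  expect_lt(abs(cal0$model$intercept_ppm), 0.05)
  cal2 <- calibrate_internal(series_spec(2))
  expect_true(cal2$calibrated)
  expect_equal(cal2$model$intercept_ppm, 2, tolerance = 0.05)
  # corrected masses are back at theory
  base <- formula_mass(parse_formula("C10H16O5"), "deprotonated_mz")
  expect_equal(cal2$spectrum$peaks$mz[1], base, tolerance = 1e-4)
})

test_that("calibration degrades to identity without a series", {
  spec <- mk_spec(c(211.1, 305.7, 517.3))
  cal <- calibrate_internal(spec)
  expect_false(cal$calibrated)
  expect_equal(cal$spectrum$peaks, spec$peaks)
  expect_match(cal$spectrum$warnings, "series")
})

test_that("calibration is idempotent", {
  cal1 <- calibrate_internal(series_spec(1.5))
  cal2 <- calibrate_internal(cal1$spectrum)
  expect_lt(abs(cal2$model$intercept_ppm), 0.1)
  expect_equal(cal2$spectrum$peaks$mz, cal1$spectrum$peaks$mz,
               tolerance = 1e-7)
})

test_that("13C isotopologues are removed, parents retained", {
  spec <- mk_spec(c(300.000000, 301.003355),
                  intensity = c(1000, 150))
  out <- remove_isotopologues(spec)
  expect_equal(out$peaks$mz, 300)
  # equal intensities fail the ratio test: both retained
  eq <- mk_spec(c(300.000000, 301.003355), intensity = c(1000, 1000))
  expect_equal(n_peaks(remove_isotopologues(eq)), 2)
  # no pair within tolerance: identity
  far <- mk_spec(c(300, 302, 310))
  expect_equal(remove_isotopologues(far)$peaks, far$peaks)
})

test_that("blank subtraction removes matching peaks from all samples", {
  s1 <- mk_spec(c(250.0000, 300.0000, 400.0000), id = "a")
  s2 <- mk_spec(c(300.0000, 500.0000), id = "b")
  blank <- mk_spec(300.0000 * (1 + 0.3e-6), id = "blank")
  out <- subtract_blanks(list(s1, s2), list(blank))
  expect_equal(out[[1]]$peaks$mz, c(250, 400))
  expect_equal(out[[2]]$peaks$mz, 500)
  # empty blanks: identity with a warning flag
  out2 <- subtract_blanks(list(s1), list())
  expect_equal(out2[[1]]$peaks, s1$peaks)
  expect_match(out2[[1]]$warnings, "blank")
  # total overlap: empty spectra, pipeline continues
  out3 <- subtract_blanks(list(s1), list(s1))
  expect_equal(n_peaks(out3[[1]]), 0)
})

test_that("every QC stage returns a subset of its input", {
  r <- random_spec(300, seed = 8)
  stages <- list(function(s) filter_snr(s),
                 function(s) filter_mz_window(s),
                 function(s) remove_isotopologues(s),
                 function(s) filter_intensity(s, 100))
  for (f in stages) {
    out <- f(r)
    expect_true(all(out$peaks$mz %in% r$peaks$mz))
    expect_lte(n_peaks(out), n_peaks(r))
  }
})
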