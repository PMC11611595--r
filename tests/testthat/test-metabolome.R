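test_that("presence/absence transform is exact and idempotent", {
  m <- matrix(c(523.1, 0, NA, 2.5), 2, 2)
  p <- presence_absence(m)
  expect_identical(as.vector(p), c(1L, 0L, 0L, 1L))
  expect_identical(presence_absence(p), p)
  expect_error(presence_absence(matrix(-1)), "negative")
})

test_that("relative abundance counts N molecules over all molecules", {
  pres <- matrix(1, 1, 10)
  mm <- mk_matrix(pres, N = c(rep(1, 4), rep(0, 6)))
  expect_equal(relative_abundance(mm)$RA, 40)
  # whole-study proportion: 1,616 of 3,985 rounds to 41%
  expect_equal(round(100 * 1616 / 3985), 41)
  empty <- mk_matrix(matrix(0, 1, 3), N = c(1, 0, 0))
  ra <- relative_abundance(empty)
  expect_true(is.na(ra$RA) && ra$flag_empty)
  none <- mk_matrix(matrix(1, 1, 3), N = c(0, 0, 0))
  expect_equal(relative_abundance(none)$RA, 0)
})

test_that("response ratio normalizes the drought-control difference", {
  expect_equal(response_ratio(40, 40)$response_ratio, 0)
  expect_equal(response_ratio(40, 30)$response_ratio, 25)
  r0 <- response_ratio(0, 10)
  expect_true(is.na(r0$response_ratio) && r0$flag_undefined)
  # bounded above by 100 whenever control RA is non-negative
  set.seed(3)
  rd <- runif(50, 1, 100); rc <- runif(50, 0, 100)
  expect_true(all(response_ratio(rd, rc)$response_ratio < 100))
})

test_that("class proportions sum to one and reconstruct counts", {
  pres <- matrix(1, 2, 5)
  mm <- mk_matrix(pres, N = c(1, 1, 1, 1, 0), S = c(0, 1, 0, 1, 0),
                  P = c(0, 0, 1, 1, 0))
  cp <- class_proportions(mm)
  expect_equal(rowSums(cp[, ELEMENTAL_CLASSES]), c(1, 1),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(unlist(cp[1, ELEMENTAL_CLASSES]),
               c(CHON = 0.2, `CHON-S` = 0.2, `CHON-P` = 0.2,
                 `CHON-SP` = 0.2, nonN = 0.2))
  counts <- cp[1, ELEMENTAL_CLASSES] * cp$n_present[1]
  expect_equal(unlist(counts), round(unlist(counts)), ignore_attr = TRUE)
})

test_that("element totals are occurrence-weighted and additive", {
  pres <- rbind(c(1, 1, 0), c(1, 0, 1), c(1, 1, 1))
  mm <- mk_matrix(pres, N = c(1, 0, 2), C = c(10L, 20L, 30L),
                  day = c(0, 2, 2))
  tot <- element_totals(mm, group_by = NULL)
  expect_equal(tot$n_molecules, 7)
  expect_equal(tot$sum_C, 3 * 10 + 2 * 20 + 2 * 30)
  expect_equal(tot$sum_N, 3 * 1 + 2 * 2)
  expect_equal(tot$mass_CN, (130 * 12.011) / (7 * 14.007))
  by_phase <- element_totals(mm, group_by = "phase")
  expect_equal(sum(by_phase$n_molecules), tot$n_molecules)
  expect_equal(sum(by_phase$sum_C), tot$sum_C)
  expect_equal(sum(by_phase$sum_N), tot$sum_N)
  # single molecule C10 N1 present once
  one <- element_totals(mk_matrix(matrix(1, 1, 1), N = 1L, C = 10L),
                        group_by = NULL)
  expect_equal(one$mass_CN, 10 * 12.011 / 14.007)  # 8.57
  expect_equal(one$mass_CN, 8.57, tolerance = 0.001)
})

test_that("molecular-weight bins split at 600 amu", {
  expect_identical(mw_bin(c(599.99, 600.00, 266.15, 900)),
                   c("LMW", "HMW", "LMW", "HMW"))
  expect_identical(mw_bin(200), "LMW")
  expect_error(mw_bin(199.9), "window")
  expect_error(mw_bin(900.1), "window")
})

test_that("mass densities integrate to one and track drought enrichment", {
  sim <- simulate_peak_tables(small_sim(seed = 17))
  mm <- truth_molecule_matrix(sim)
  dens <- mw_density(mm)
  for (d in dens) {
    if (is.null(d)) next
    area <- sum(d$y) * diff(d$x[1:2])
    expect_equal(area, 1, tolerance = 1e-2)
  }
  # drought density mass inside the induced windows exceeds control's
  win_mass <- function(d) {
    inwin <- (d$x >= 275 & d$x <= 390) | (d$x >= 450 & d$x <= 550)
    sum(d$y[inwin]) * diff(d$x[1:2])
  }
  expect_gt(win_mass(dens[["treatment.drought"]]),
            win_mass(dens[["treatment.control"]]))
})

test_that("venn partition equals brute-force set algebra", {
  set.seed(9)
  pres <- matrix(rbinom(20 * 30, 1, 0.3), 20, 30)
  mm <- mk_matrix(pres, N = rep(c(1L, 0L), 15),
                  treatment = rep(c("control", "drought"), each = 10),
                  day = rep(c(2, 4), 10))
  v <- venn_partition(mm, phase = "treatment")
  idn <- mm$molecules$id[mm$molecules$N > 0]
  a <- idn[colSums(pres[1:10, mm$molecules$N > 0]) > 0]
  b <- idn[colSums(pres[11:20, mm$molecules$N > 0]) > 0]
  expect_setequal(v$unique_A, setdiff(a, b))
  expect_setequal(v$unique_B, setdiff(b, a))
  expect_setequal(v$shared, intersect(a, b))
  # conservation: the three parts partition the observed molecules
  expect_equal(length(v$unique_A) + length(v$unique_B) + length(v$shared),
               length(union(a, b)))
  expect_length(intersect(v$unique_A, v$shared), 0)
})

test_that("degenerate venn cases behave", {
  pres <- rbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
  mm <- mk_matrix(pres, N = rep(1L, 4),
                  treatment = c("control", "drought"), day = c(2, 2))
  v <- venn_partition(mm, phase = "treatment")
  expect_length(v$shared, 0)
  same <- mk_matrix(rbind(c(1, 1, 1, 0), c(1, 1, 1, 0)), N = rep(1L, 4),
                    treatment = c("control", "drought"), day = c(2, 2))
  v2 <- venn_partition(same, phase = "treatment")
  expect_length(v2$unique_A, 0)
  expect_length(v2$unique_B, 0)
  one <- mk_matrix(pres, N = rep(1L, 4),
                   treatment = c("control", "control"), day = c(2, 2))
  expect_error(venn_partition(one, phase = "treatment"), "two levels")
})

test_that("important-molecule selection applies day and occurrence rules", {
  days <- c(2, 2, 4, 4, 7, 7, 9, 9, 11, 11)
  pres <- cbind(c(1, 1, 1, 1, 1, 1, 0, 0, 0, 0),   # 3 days, 6 occurrences
                c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0),   # 2 days, 4 occurrences
                c(1, 0, 1, 0, 1, 0, 1, 0, 0, 0))   # 4 days, 4 occurrences
  mm <- mk_matrix(pres, N = rep(1L, 3), treatment = rep("drought", 10),
                  day = days)
  ids <- mm$molecules$id
  sel <- select_important(mm, ids, min_days = 3, min_occurrence = 5)
  expect_identical(sel$id, ids[1])        # occurrence rule rejects m3
  expect_equal(sel$days_present, 3)
  expect_equal(sel$occurrence, 6)
  sel3 <- select_important(mm, ids, min_days = 3, min_occurrence = 3)
  expect_setequal(sel3$id, ids[c(1, 3)])  # day rule still rejects m2
  expect_equal(nrow(select_important(mm, character(0))), 0)
})

test_that("KEGG annotation hook returns no matches by default", {
  mm <- mk_matrix(matrix(1, 1, 2), N = c(1L, 0L))
  expect_equal(nrow(kegg_annotate(mm)), 0)
})
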