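test_that("bootstrap t-test behaves at the null and under separation", {
  x <- c(1.2, 1.9, 2.4, 3.1, 2.2)
  same <- bootstrap_t_test(x, x, n_boot = 2000, seed = 1)
  expect_gt(same$p_value, 0.9)
  set.seed(5)
  a <- rnorm(5); b <- rnorm(5, 3)
  sep <- bootstrap_t_test(a, b, n_boot = 2000, seed = 2)
  expect_lt(sep$p_value, 0.05)
  # deterministic given the seed; p never exactly 0
  sep2 <- bootstrap_t_test(a, b, n_boot = 2000, seed = 2)
  expect_identical(sep$p_value, sep2$p_value)
  expect_gt(sep$p_value, 0)
  expect_error(bootstrap_t_test(1, c(1, 2)), "at least 2")
  # observed statistic is the Welch t
  expect_equal(sep$statistic, unname(t.test(a, b)$statistic))
})

test_that("BH adjustment matches the step-up form and p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 4)), rep(1, 4))
  set.seed(8)
  for (i in 1:10) {
    p <- runif(sample(2:40, 1))
    expect_equal(bh_adjust(p), p.adjust(p, "BH"))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("KS statistic equals the brute-force ECDF scan", {
  expect_equal(ks_two_sample(1:5, 1:5)$statistic, 0)
  expect_equal(ks_two_sample(1:5, 6:10)$statistic, 1)
  set.seed(12)
  for (i in 1:20) {
    x <- rnorm(sample(5:40, 1)); y <- rnorm(sample(5:40, 1), sd = 2)
    d_brute <- max(vapply(c(x, y), function(v) {
      abs(mean(x <= v) - mean(y <= v))
    }, numeric(1)))
    expect_equal(ks_two_sample(x, y)$statistic, d_brute)
  }
})

test_that("KS p-values agree with the reference implementation", {
  set.seed(13)
  # exact small-sample path
  for (i in 1:10) {
    x <- rnorm(sample(4:9, 1)); y <- rnorm(sample(4:9, 1), 0.5)
    ours <- ks_two_sample(x, y)
    ref <- suppressWarnings(ks.test(x, y, exact = TRUE))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
  }
  # asymptotic path
  # asymptotic path: ours carries the finite-sample lambda correction, the
  # reference does not, so agreement is approximate
  x <- rnorm(60); y <- rnorm(70, 0.3)
  ours <- ks_two_sample(x, y, exact = FALSE)
  ref <- suppressWarnings(ks.test(x, y, exact = FALSE))
  expect_lt(abs(ours$p_value - ref$p.value), 0.02)
  expect_error(ks_two_sample(numeric(0), 1:3), "non-empty")
})

test_that("binary Bray-Curtis matches the closed form and vegan", {
  m <- rbind(a = c(1, 1, 1, 0, 0, 0, 0, 0),
             b = c(1, 1, 0, 1, 1, 1, 0, 0))
  d <- bray_curtis_binary(m)
  expect_equal(as.numeric(d), (3 + 5 - 2 * 2) / (3 + 5))   # 0.5
  expect_equal(as.numeric(bray_curtis_binary(rbind(m[1, ], m[1, ]))), 0)
  disjoint <- rbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
  expect_equal(as.numeric(bray_curtis_binary(disjoint)), 1)
  set.seed(2)
  big <- matrix(rbinom(200, 1, 0.4), 10, 20)
  big[1, ] <- 1  # avoid empty samples
  ours <- as.matrix(bray_curtis_binary(big))
  ref <- as.matrix(vegan::vegdist(big, method = "bray"))
  expect_equal(ours, ref, ignore_attr = TRUE, tolerance = 1e-12)
  expect_warning(bray_curtis_binary(rbind(c(0, 0), c(0, 0))), "all-empty")
})

test_that("PERMANOVA pseudo-F reduces to the classical ANOVA F", {
  set.seed(31)
  y <- c(rnorm(6), rnorm(6, 1.5))
  g <- rep(c("A", "B"), each = 6)
  d <- dist(y)   # univariate Euclidean
  ours <- permanova(d, data.frame(g = g), "g", n_perm = 99, seed = 1)
  classical <- anova(lm(y ~ g))
  expect_equal(ours$F[1], classical$`F value`[1], tolerance = 1e-9)
  expect_equal(ours$SS[1:2], classical$`Sum Sq`, tolerance = 1e-9)
  expect_equal(ours$df, c(1, 10, 11))
})

test_that("PERMANOVA degrees of freedom and R2 follow the design", {
  set.seed(32)
  m <- matrix(rbinom(10 * 30, 1, 0.4), 10, 30)
  m[rowSums(m) == 0, 1] <- 1
  d <- bray_curtis_binary(m)
  des <- data.frame(treatment = rep(c("control", "drought"), each = 5))
  out <- permanova(d, des, "treatment", n_perm = 199, seed = 4)
  expect_equal(out$df, c(1, 8, 9))
  expect_equal(sum(out$R2[1:2]), 1, tolerance = 1e-9)
  expect_true(out$p_value[1] > 0 && out$p_value[1] <= 1)
  expect_error(permanova(d, data.frame(x = rep("u", 10)), "x"), "aliased")
})

test_that("PERMANOVA agrees with vegan::adonis2 on SS, F and R2", {
  set.seed(33)
  m <- matrix(rbinom(20 * 40, 1, 0.35), 20, 40)
  m[rowSums(m) == 0, 1] <- 1
  des <- data.frame(treatment = rep(c("c", "d"), each = 10),
                    day = factor(rep(c(2, 4, 7, 9), 5)))
  d <- bray_curtis_binary(m)
  ours <- permanova(d, des, c("treatment", "day"), n_perm = 199, seed = 5)
  ref <- vegan::adonis2(d ~ treatment + day, data = des,
                        permutations = 199, by = "terms")
  expect_equal(ours$SS[1:2], ref$SumOfSqs[1:2], tolerance = 1e-9)
  expect_equal(ours$F[1:2], ref$F[1:2], tolerance = 1e-9)
  expect_equal(ours$R2[1:2], ref$R2[1:2], tolerance = 1e-9)
})

test_that("stochastic procedures are reproducible bit-for-bit", {
  set.seed(41)
  m <- matrix(rbinom(12 * 25, 1, 0.4), 12, 25)
  m[rowSums(m) == 0, 1] <- 1
  d <- bray_curtis_binary(m)
  des <- data.frame(t = rep(c("a", "b"), 6))
  p1 <- permanova(d, des, "t", n_perm = 199, seed = 9)
  p2 <- permanova(d, des, "t", n_perm = 199, seed = 9)
  expect_identical(p1, p2)
})

test_that("PCA squared cosines capture representation quality", {
  set.seed(51)
  n <- 30
  base <- rnorm(n)
  x <- cbind(v1 = base, v2 = base * 2 + 3, v3 = rnorm(n))
  res <- pca_squared_cosines(x)
  # two perfectly correlated variables load on one component
  expect_equal(res$sq_cos["v1", 1], res$sq_cos["v2", 1], tolerance = 1e-9)
  expect_gt(res$sq_cos["v1", 1], 0.5)
  # per-variable squared cosines sum to one across all components
  expect_equal(unname(rowSums(res$sq_cos)), rep(1, 3), tolerance = 1e-9)
  # explained variance non-increasing, sums to 1, matches eigen oracle
  expect_true(all(diff(res$explained) <= 1e-12))
  expect_equal(sum(res$explained), 1, tolerance = 1e-9)
  ev <- eigen(cov(scale(x)))$values
  expect_equal(res$explained, ev[seq_along(res$explained)] / sum(ev),
               tolerance = 1e-9)
})

test_that("rank-1 data put all representation on component 1", {
  base <- seq_len(12)
  x <- cbind(a = base, b = -3 * base)
  res <- pca_squared_cosines(x)
  expect_equal(res$explained[1], 1, tolerance = 1e-9)
  expect_equal(unname(res$sq_cos[, 1]), c(1, 1), tolerance = 1e-9)
})

test_that("supplementary variables are projected without influencing axes", {
  set.seed(52)
  x <- matrix(rnorm(40 * 4), 40, 4,
              dimnames = list(NULL, paste0("v", 1:4)))
  sup <- data.frame(treatment = rep(c("c", "d"), 20))
  with_sup <- pca_squared_cosines(x, supplementary = sup)
  without <- pca_squared_cosines(x)
  expect_equal(with_sup$scores, without$scores)
  expect_equal(with_sup$explained, without$explained)
  expect_true(all(with_sup$sq_cos_supplementary >= 0 &
                    with_sup$sq_cos_supplementary <= 1))
  # zero-variance variable dropped with warning
  x2 <- cbind(x, const = 1)
  expect_warning(res <- pca_squared_cosines(x2), "zero-variance")
  expect_false("const" %in% rownames(res$sq_cos))
})

test_that("quantitative drought effects are detected with BH control", {
  q <- suppressWarnings(simulate_quant_tables(small_sim(seed = 19)))
  b <- exudate_balance(q)
  qt <- quant_tests(b, n_boot = 2000, seed = 3)
  expect_true(all(qt$p_adjusted >= qt$p_value - 1e-12))
  expect_true(all(qt$p_value > 0 & qt$p_value <= 1))
  # the large simulated TON effect at end of treatment is significant
  ton <- qt[qt$day == 11 & qt$analyte == "TON_conc", ]
  expect_lt(ton$p_adjusted, 0.05)
})
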