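test_that("size factors match the median-of-ratios oracle", {
  set.seed(5)
  m <- matrix(rnbinom(600, mu = 100, size = 10), ncol = 6)
  expect_equal(size_factors(m), brute_size_factors(m), tolerance = 1e-12,
               ignore_attr = TRUE)
  # identical samples -> all factors 1
  mi <- matrix(rep(rpois(50, 80), 4), ncol = 4)
  expect_equal(size_factors(mi), rep(1, 4), ignore_attr = TRUE)
  # one sample exactly doubled -> factor ratio 2
  md <- cbind(mi, mi[, 1] * 2L)
  sf <- size_factors(md)
  expect_equal(sf[5] / sf[1], 2, ignore_attr = TRUE)
  # all-zero-containing features only -> library-size fallback
  mz <- rbind(c(0, 5, 5, 5), c(5, 0, 5, 5))
  expect_message(size_factors(mz), "library-size")
})

test_that("Wald DE test: flat features are null, planted effects are found", {
  # identical counts in every sample: log2fc 0, p ~ 1
  raw <- matrix(rep(c(100L, 250L, 30L), 6), ncol = 6,
                dimnames = list(c("f1", "f2", "f3"), paste0("s", 1:6)))
  conds <- stats::setNames(rep(c("SEN", "SEN+M"), each = 3), paste0("s", 1:6))
  de <- de_test(raw, conds, "SEN", "SEN+M")
  expect_equal(de$log2fc, rep(0, 3), tolerance = 1e-6)
  expect_true(all(de$p > 0.99))
  expect_false(any(de$called))

  # power on planted 4-fold effects
  ef <- data.frame(feature = 1:20, pattern = "linear-up", fc1 = 4, fc2 = 1)
  cfg <- count_sim_config(n_features = 400L, conditions = c("SEN", "SEN+M"),
                          baseline_meanlog = log(500), baseline_sdlog = 0,
                          dispersion = 0.05, effects = ef, seed = 42)
  sim <- simulate_counts(cfg)
  dep <- de_test(sim$counts, sim$conditions, "SEN", "SEN+M")
  expect_gte(mean(dep$called[1:20]), 0.9)
  expect_lte(mean(dep$called[-(1:20)]), 0.05)
  expect_true(all(dep$log2fc[1:20] > 1))    # ~log2(4) = 2
  # the call rule is exactly fdr < 0.05 & |log2fc| >= log2(1.5)
  expect_equal(dep$called,
               !is.na(dep$fdr) & dep$fdr < 0.05 &
                 abs(dep$log2fc) >= log2(1.5))
  # all-zero feature: NA p, excluded from BH
  raw0 <- rbind(sim$counts[1:10, ], zero = 0L)
  de0 <- de_test(raw0, sim$conditions, "SEN", "SEN+M")
  expect_true(is.na(de0$p[11]))
  expect_false(de0$called[11])
})

test_that("LRT trend test finds U shapes and is null on equal means", {
  raw <- matrix(rep(c(100L, 250L), 9), ncol = 9,
                dimnames = list(c("f1", "f2"), NULL))
  conds <- rep(c("Young", "SEN", "SEN+M"), each = 3)
  tr <- lrt_trend(raw, conds)
  expect_true(all(tr$lrt_stat < 1e-6))
  expect_true(all(tr$p > 0.99))
  expect_identical(tr$shape, c("flat", "flat"))

  ef <- data.frame(feature = 1:10, pattern = "U", fc1 = 0.25, fc2 = 16)
  cfg <- count_sim_config(n_features = 200L, baseline_meanlog = log(500),
                          baseline_sdlog = 0, dispersion = 0.05,
                          effects = ef, seed = 43)
  sim <- simulate_counts(cfg)
  tru <- lrt_trend(sim$counts, sim$conditions)
  expect_true(all(tru$fdr[1:10] < 0.05))
  expect_true(all(tru$shape[1:10] == "U"))
})

test_that("shape classification follows the transition signs", {
  m <- rbind(c(10, 100, 1000), c(10, 100, 12), c(100, 10, 90),
             c(1000, 100, 10), c(50, 50, 50))
  fdr <- c(0.001, 0.001, 0.001, 0.001, 0.001)
  expect_identical(classify_shape(m, fdr),
                   c("linear-up", "inverted-U", "U", "linear-down", "flat"))
  # non-significant features are flat regardless of means
  expect_identical(classify_shape(m, rep(0.5, 5)), rep("flat", 5))
  # invariant under monotone rescaling
  expect_identical(classify_shape(log2(m + 1), fdr), classify_shape(m, fdr))
  expect_identical(classify_shape(m * 1000, fdr), classify_shape(m, fdr))
})

test_that("two-proportion z-test matches its definition and Fisher", {
  expect_equal(ztest_proportions(50, 100, 50, 100), 1)
  expect_equal(ztest_proportions(0, 100, 0, 50), 1)      # degenerate
  expect_equal(ztest_proportions(100, 100, 50, 50), 1)   # degenerate
  p <- ztest_proportions(4429, 10000, 5505, 10000)
  expect_lt(p, 0.001)
  # hand-computed pooled z
  ph <- (4429 + 5505) / 20000
  z <- (0.4429 - 0.5505) / sqrt(ph * (1 - ph) * 2e-4)
  expect_equal(p, 2 * pnorm(-abs(z)), tolerance = 1e-12)
  # agreement with the exact test at moderate counts
  set.seed(10)
  for (i in 1:10) {
    n1 <- sample(200:500, 1); n2 <- sample(200:500, 1)
    x1 <- rbinom(1, n1, 0.3); x2 <- rbinom(1, n2, 0.4)
    pz <- ztest_proportions(x1, n1, x2, n2)
    pf <- fisher.test(matrix(c(x1, n1 - x1, x2, n2 - x2), 2))$p.value
    expect_lt(abs(pz - pf) / pf, 0.25)
  }
})

test_that("global category homogeneity test behaves at both extremes", {
  a <- c(canonical = 500, del3 = 300, add3 = 200)
  expect_equal(global_category_test(a, a), 1, tolerance = 1e-12)
  b1 <- c(canonical = 900, del3 = 100)
  b2 <- c(canonical = 100, del3 = 900)
  expect_lt(global_category_test(b1, b2), 1e-6)
  # chi-square vs Monte-Carlo permutation within simulation error
  c1 <- c(canonical = 60, del3 = 40, add3 = 30)
  c2 <- c(canonical = 45, del3 = 50, add3 = 35)
  p_chi <- global_category_test(c1, c2)
  p_perm <- global_category_test(c1, c2, method = "permutation",
                                 n_perm = 20000L, seed = 4)
  expect_lt(abs(p_chi - p_perm), 0.03)
})

test_that("BH adjustment equals the textbook step-up procedure", {
  set.seed(11)
  for (i in 1:5) {
    p <- runif(sample(10:200, 1))
    expect_equal(p.adjust(p, method = "BH"), brute_bh(p), tolerance = 1e-12)
  }
})

test_that("QC reports unit self-correlation and ordered variance fractions", {
  set.seed(12)
  rpm <- matrix(rexp(300, 1 / 50), ncol = 6,
                dimnames = list(NULL, paste0("s", 1:6)))
  rpm[, 6] <- rpm[, 5]                      # duplicated sample
  qc <- qc_summary(rpm)
  expect_equal(unname(qc$correlation["s5", "s6"]), 1)
  expect_true(all(diag(qc$correlation) == 1))
  expect_equal(qc$correlation, t(qc$correlation))
  expect_true(all(diff(qc$variance_fraction) < 1e-9))
  expect_lte(sum(qc$variance_fraction), 1 + 1e-9)
  # 2-sample case: one PC carries all variance
  qc2 <- qc_summary(rpm[, 1:2])
  expect_equal(qc2$variance_fraction[1], 1)
})
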