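mk_iso <- function(categories, counts_by_sample, uridylated = NULL,
                   accession = "MIMAT0001", name = "miR-x") {
  n <- length(categories)
  if (is.null(uridylated)) uridylated <- rep(FALSE, n)
  df <- data.frame(accession = accession, name = name,
                   label = sprintf("0|%d", seq_len(n) - 1L),
                   start_offset = 0L, end_offset = seq_len(n) - 1L,
                   nta = "", category = categories,
                   uridylated = uridylated, stringsAsFactors = FALSE)
  for (s in names(counts_by_sample)) df[[s]] <- counts_by_sample[[s]]
  df
}

test_that("RPM arithmetic, conservation and scale invariance hold", {
  iso <- mk_iso(c("canonical", "3' deletion"),
                list(s1 = c(5L, 15L), s2 = c(10L, 30L)))
  cm <- rpm_normalize(iso, denominators = c(s1 = 2e6, s2 = 4e6))
  expect_equal(unname(cm$rpm[1, "s1"]), 2.5)
  # default denominator = column sums -> RPM sums to 1e6 per sample
  cm2 <- rpm_normalize(iso)
  expect_equal(unname(colSums(cm2$rpm)), c(1e6, 1e6))
  # doubling all raw counts and denominators leaves RPM unchanged
  iso2 <- iso; iso2$s1 <- iso$s1 * 2L; iso2$s2 <- iso$s2 * 2L
  cm3 <- rpm_normalize(iso2)
  expect_equal(cm3$rpm, cm2$rpm, ignore_attr = TRUE)
  expect_error(rpm_normalize(iso, denominators = c(s1 = 0, s2 = 1)),
               "zero RPM denominator.*s1")
  # invariant: rpm == raw / denom * 1e6 on random matrices
  set.seed(1)
  for (i in 1:5) {
    r <- matrix(rpois(20, 50), 5)
    iso_r <- mk_iso(rep("canonical", 5),
                    setNames(lapply(1:4, function(j) r[, j]),
                             paste0("s", 1:4)))
    cmr <- rpm_normalize(iso_r)
    expect_equal(cmr$rpm, sweep(cmr$raw, 2, colSums(cmr$raw), "/") * 1e6,
                 tolerance = 1e-12)
  }
})

test_that("arm abundance is the sum of member isomiR abundances", {
  iso <- rbind(mk_iso(c("canonical", "3' deletion"),
                      list(s1 = c(10L, 15L))),
               mk_iso("canonical", list(s1 = 8L),
                      accession = "MIMAT0002", name = "miR-y"))
  cm <- rpm_normalize(iso, denominators = c(s1 = 1e6))
  arm <- arm_abundance(cm)
  expect_equal(unname(arm$rpm["miR-x", "s1"]), 25)
  expect_equal(unname(arm$rpm["miR-y", "s1"]), 8)   # single isomiR: identity
  expect_equal(sum(arm$rpm), sum(cm$rpm))           # conservation
  expect_equal(sum(arm$raw), sum(cm$raw))
})

test_that("proportion tables reproduce printed senescence rows exactly", {
  conds <- c(a1 = "SEN", a2 = "SEN+M")
  # arm with only archetype reads: canonical 100
  iso0 <- mk_iso("canonical", list(a1 = 500L, a2 = 700L))
  pt0 <- proportion_table(iso0, conds)
  expect_equal(pt0$canonical, c(100, 100))
  expect_equal(pt0$uridylation, c(0, 0))

  # the five-category split 7127/563/2221/63/26 -> 71.27/5.63/22.21/0.63/0.26
  iso1 <- mk_iso(c("canonical", "3' addition", "3' deletion",
                   "5' deletion", "mixed"),
                 list(a1 = c(7127L, 563L, 2221L, 63L, 26L),
                      a2 = rep(0L, 5)))
  pt1 <- proportion_table(iso1, conds)
  sen <- pt1[pt1$condition == "SEN", ]
  expect_equal(round(sen$canonical, 2), 71.27)
  expect_equal(round(sen$`3' addition`, 2), 5.63)
  expect_equal(round(sen$`3' deletion`, 2), 22.21)
  expect_equal(round(sen$`5' deletion`, 2), 0.63)
  expect_equal(round(sen$mixed, 2), 0.26)
  # zero-read condition: NA percentages, row still emitted
  senm <- pt1[pt1$condition == "SEN+M", ]
  expect_true(all(is.na(senm$canonical)))

  # two-category split 4429/5571 -> 44.29/55.71
  iso2 <- mk_iso(c("canonical", "3' deletion"),
                 list(a1 = c(4429L, 5571L), a2 = c(5505L, 4495L)))
  pt2 <- proportion_table(iso2, conds)
  expect_equal(round(pt2$canonical[pt2$condition == "SEN"], 2), 44.29)
  expect_equal(round(pt2$`3' deletion`[pt2$condition == "SEN"], 2), 55.71)
  # exclusive columns always sum to 100
  cats <- c("canonical", "3' addition", "3' deletion", "5' addition",
            "5' deletion", "mixed")
  for (pt in list(pt0, pt2))
    expect_equal(rowSums(pt[, cats]), rep(100, nrow(pt)),
                 tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("uridylation is cross-cutting over the same denominator", {
  conds <- c(a1 = "SEN")
  iso <- mk_iso(c("canonical", "3' addition", "mixed"),
                list(a1 = c(800L, 120L, 80L)),
                uridylated = c(FALSE, TRUE, TRUE))
  pt <- proportion_table(iso, conds)
  expect_equal(pt$uridylation, 20)   # (120+80)/1000
  cats <- c("canonical", "3' addition", "3' deletion", "5' addition",
            "5' deletion", "mixed")
  expect_equal(sum(pt[, cats]), 100)
})

test_that("replicate pooling matches summed counts; averaging differs", {
  conds <- c(r1 = "SEN", r2 = "SEN")
  iso <- mk_iso(c("canonical", "mixed"),
                list(r1 = c(90L, 10L), r2 = c(100L, 900L)))
  pool <- proportion_table(iso, conds)
  expect_equal(pool$canonical, 100 * 190 / 1100)
  avg <- proportion_table(iso, conds, pooling = "average")
  expect_equal(avg$canonical, mean(c(90, 10)))
})

test_that("proportion z-tests flag redistributed categories", {
  conds <- c(a1 = "SEN", a2 = "SEN+M")
  iso <- mk_iso(c("canonical", "3' deletion"),
                list(a1 = c(4429L, 5571L), a2 = c(5505L, 4495L)))
  zt <- proportion_ztests(iso, conds, "SEN", "SEN+M")
  expect_lt(zt$p[zt$category == "canonical"], 0.001)
  iso_same <- mk_iso("canonical", list(a1 = 50L, a2 = 50L))
  zt0 <- proportion_ztests(iso_same, conds, "SEN", "SEN+M")
  expect_equal(zt0$p[1], 1)
})

test_that("population doubling formula and accumulation", {
  expect_equal(population_doublings(40000, 5000), 3)
  expect_equal(population_doublings(5000, 5000), 0)
  expect_equal(population_doublings(10000, 5000), 1)
  expect_error(population_doublings(0, 5000), "positive")
  expect_equal(cumulative_pd(c(10000, 20000), c(5000, 5000)),
               c(1, 3))
})

test_that("recovered proportions equal configured fractions exactly", {
  ref <- make_ref(1, seed = 61)
  acc <- ref$arms$accession[1]
  sp <- stats::setNames(list(data.frame(
    start_offset = c(0L, 0L, 1L), end_offset = c(0L, -2L, 0L),
    nta = "", fraction = c(0.7127, 0.2221, 0.0652))), acc)
  cfg <- spectrum_config(sp, reads_per_sample = 10000L)
  td <- tempfile()
  sim <- simulate_reads(cfg, ref$hairpins, ref$arms, "s1", td, seed = 3)
  ra <- run_assign(sim$fastq, cfg$adapter, ref$hairpins, ref$arms)
  iso <- build_isomir_table(ra$assigned, ref$hairpins, ref$arms)$isomirs
  pt <- proportion_table(iso, c(s1 = "SEN"))
  expect_equal(round(pt$canonical, 2), 71.27)
  expect_equal(round(pt$`3' deletion`, 2), 22.21)
  expect_equal(round(pt$`5' deletion`, 2), 6.52)
})
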