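test_that("seed extraction windows positions 2-8 of the shifted sequence", {
  m <- "TAGCTTATCAGACTGATGTTGA"
  expect_equal(seed_of(m, 0), "AGCTTAT")
  expect_equal(seed_of(m, 1), "GCTTATC")
  expect_equal(seed_of(m, 0), seed_of(m, 0))             # idempotent
  # negative offset prepends templated upstream sequence: the new seed is
  # positions 2-8 of the extended mature, i.e. old positions 1-7
  expect_equal(seed_of(m, -1, upstream = "GG"), "TAGCTTA")
  expect_equal(seed_of(m, -2, upstream = "CG"), "GTAGCTT")
  expect_error(seed_of(m, -1), "upstream")
  expect_error(seed_of("ACGT", 0), "escapes")
  # RNA input is handled
  expect_equal(seed_of("UAGCUUAUCAGACUGAUGUUGA", 0), "AGCTTAT")
})

test_that("seed collisions exclude self-pairs and find planted matches", {
  canon <- data.frame(accession = c("M1", "M2", "M3"),
                      name = c("a", "b", "c"),
                      seed = c("AGCTTAT", "GCTTATC", "TTTTTTT"),
                      stringsAsFactors = FALSE)
  iso <- data.frame(accession = c("M1", "M1"), label = c("+1|0", "+2|0"),
                    seed = c("GCTTATC", "AGCTTAT"), stringsAsFactors = FALSE)
  cl <- seed_collisions(iso, canon)
  # +1 isomiR of M1 hits canonical M2; the self-match to M1 is excluded
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$accession_isomir, "M1")
  expect_equal(cl$accession_canonical, "M2")
  expect_equal(nrow(seed_collisions(iso[0, ], canon)), 0L)
})

test_that("site scanning matches construction and the brute-force oracle", {
  s <- "AGCTTAT"
  rc7 <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  utr_8mer <- paste0("CCCCC", rc7, "A", "CCCCC")
  for (ty in c("8mer", "7mer-m8", "7mer-A1")) {
    ts <- predict_targets(s, c(g = utr_8mer), site_types = ty)
    expect_equal(ts$gene, "g")
  }
  # no complementary core anywhere
  expect_equal(nrow(predict_targets(s, c(g = strrep("C", 50)))), 0L)
  # 7mer-m8 without the A is not a 7mer-A1
  utr_m8 <- paste0("GGGGG", rc7, "G", "GGGGG")
  expect_equal(nrow(predict_targets(s, c(g = utr_m8),
                                    site_types = "7mer-A1")), 0L)
  expect_equal(predict_targets(s, c(g = utr_m8),
                               site_types = "7mer-m8")$gene, "g")
  # random-sequence equivalence with the naive scanner
  set.seed(20)
  for (i in 1:30) {
    utr <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
                 collapse = "")
    seed7 <- paste(sample(c("A", "C", "G", "T"), 7, replace = TRUE),
                   collapse = "")
    types <- sample(c("8mer", "7mer-m8", "7mer-A1"),
                    sample(1:3, 1))
    got <- predict_targets(seed7, c(g = utr), site_types = types)
    want <- brute_site_scan(seed7, utr, types)
    expect_equal(if (nrow(got)) got$sites else 0L, want)
  }
})

test_that("Venn region counts are exact set algebra", {
  A <- letters[1:10]; B <- letters[6:12]; C <- letters[c(1, 6, 20)]
  ov2 <- target_overlap(list(A = A, B = B))
  expect_equal(unname(ov2["A&B"]), 5L)
  expect_equal(sum(ov2), length(union(A, B)))
  ov_same <- target_overlap(list(A = A, B = A))
  expect_equal(unname(ov_same["A&B"]), 10L)
  expect_false(any(grepl("^A$|^B$", names(ov_same))))
  ov_disj <- target_overlap(list(A = A, B = letters[20:22]))
  expect_false("A&B" %in% names(ov_disj))
  ov3 <- target_overlap(list(A = A, B = B, C = C))
  expect_equal(unname(ov3["A&B&C"]), 1L)    # "f"
  expect_equal(sum(ov3), length(union(union(A, B), C)))
  m <- target_overlap(list(A = A, B = B, C = C, D = letters[1:3]))
  expect_true(is.matrix(m))
  expect_equal(m["A", "D"], 3L)
})

test_that("enrichment p equals the hypergeometric tail and Fisher exact", {
  # 2x2 (10, 90, 10, 890): 20 targets in a universe of 1000, set of 100
  sets <- list(S = sprintf("g%03d", 1:100))
  universe <- sprintf("g%03d", 1:1000)
  targets <- sprintf("g%03d", c(1:10, 901:910))
  en <- enrich_targets(targets, sets, universe = universe)
  expect_equal(en$p, phyper(9, 100, 900, 20, lower.tail = FALSE),
               tolerance = 1e-15)
  ft <- fisher.test(matrix(c(10, 90, 10, 890), 2), alternative = "greater")
  expect_equal(en$p, ft$p.value, tolerance = 1e-12)
  expect_equal(en$ratio, 0.1)
  # ratio form: 34 of 47 genes targeted -> 72.3%
  sets2 <- list(P = sprintf("h%02d", 1:47))
  en2 <- enrich_targets(sprintf("h%02d", 1:34), sets2,
                        universe = c(sprintf("h%02d", 1:47),
                                     sprintf("x%02d", 1:53)))
  expect_equal(round(100 * en2$ratio, 1), 72.3)
  # random tables up to n = 10000: equality to 1e-12 relative
  set.seed(30)
  for (i in 1:10) {
    N <- sample(2000:10000, 1)
    K <- sample(50:500, 1)      # set size
    n <- sample(50:500, 1)      # targets
    k <- sample(0:min(K, n - 1), 1)
    u <- sprintf("u%05d", 1:N)
    gs <- list(S = u[1:K])
    tg <- c(u[seq_len(k)], u[(K + 1):(K + n - k)])
    p1 <- enrich_targets(tg, gs, universe = u)$p
    p2 <- fisher.test(matrix(c(k, K - k, n - k, N - K - (n - k)), 2),
                      alternative = "greater")$p.value
    expect_equal(p1, p2, tolerance = 1e-12)
  }
  expect_error(enrich_targets("zz", list(S = "aa"), universe = "aa"),
               "outside the universe")
})
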