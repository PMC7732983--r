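test_that("3' adapter trimming removes prefixes, flags failures", {
  ad <- "TGGAATTCTCGGGTGCCAAGG"
  tr <- trim_adapter(paste0("ACGTACGT", substr(ad, 1, 8)), ad)
  expect_equal(tr$sequence, "ACGTACGT")
  expect_true(tr$trimmed)
  # no adapter anywhere: unchanged, flagged
  tr2 <- trim_adapter("ACGTACGTACGTACGT", "CCCCCCCCCC")
  expect_equal(tr2$sequence, "ACGTACGTACGTACGT")
  expect_false(tr2$trimmed)
  # adapter at position 1: empty insert
  tr3 <- trim_adapter(substr(ad, 1, 12), ad)
  expect_equal(tr3$sequence, "")
  # full adapter with 2 mismatches (<=10% of 21) still found
  mm <- ad
  substr(mm, 3, 3) <- "A"; substr(mm, 10, 10) <- "C"
  tr4 <- trim_adapter(paste0("TTTTGGGGCCCCAAAA", mm), ad)
  expect_equal(tr4$sequence, "TTTTGGGGCCCCAAAA")
  # short exact overlap below min_overlap is not trimmed
  tr5 <- trim_adapter(paste0("ACGTACGTACGTAC", substr(ad, 1, 2)), ad)
  expect_false(tr5$trimmed)
})

test_that("collapsing merges identical reads and conserves counts", {
  seqs <- c(rep(strrep("AC", 11), 3), strrep("G", 10), strrep("AT", 10))
  res <- collapse_and_filter(seqs)
  expect_equal(res$reads$count[res$reads$sequence == strrep("AC", 11)], 3L)
  expect_false(strrep("G", 10) %in% res$reads$sequence)  # 10-mer filtered
  expect_equal(unname(res$tally["input"]),
               unname(res$tally["kept"] + res$tally["length_filtered"] +
                        res$tally["quality_filtered"]))
  # quality filter
  res2 <- collapse_and_filter(c(strrep("AC", 11), strrep("AG", 11)),
                              mean_quality = c(35, 10))
  expect_equal(sum(res2$reads$count), 1L)
  expect_equal(unname(res2$tally["quality_filtered"]), 1L)
})

test_that("ungapped alignment handles exact, mismatched and ambiguous reads", {
  ref <- make_ref(2, seed = 31)
  hp <- ref$hairpins
  read0 <- substr(hp$sequence[1], 10, 31)            # interior substring
  al <- align_ungapped(data.frame(sequence = read0, count = 1L), hp)
  expect_equal(nrow(al$alignments), 1L)
  expect_equal(al$alignments$start, 10L)
  expect_equal(al$alignments$mismatches, 0L)
  expect_equal(al$alignments$tail, "")

  read1 <- read0
  substr(read1, 8, 8) <- setdiff(c("A", "C", "G", "T"),
                                 substr(read1, 8, 8))[1]
  al1 <- align_ungapped(data.frame(sequence = read1, count = 1L), hp)
  expect_equal(al1$alignments$mismatches, 1L)
  expect_equal(al1$alignments$templated_len, 22L)

  # identical subsequence planted on both hairpins -> ambiguous, dropped
  hp2 <- hp
  sub <- substr(hp2$sequence[1], 5, 26)
  hp2$sequence[2] <- paste0(substr(hp2$sequence[2], 1, 4), sub,
                            substr(hp2$sequence[2], 27, nchar(hp2$sequence[2])))
  ala <- align_ungapped(data.frame(sequence = sub, count = 3L), hp2)
  expect_equal(unname(ala$tally["ambiguous"]), 3L)
  expect_equal(nrow(ala$alignments), 0L)

  # garbage read: unaligned
  alg <- align_ungapped(data.frame(sequence = strrep("AC", 11), count = 2L),
                        hp)
  expect_equal(unname(alg$tally["unaligned"]), 2L)
})

test_that("aligner agrees with the exhaustive sliding-window oracle", {
  set.seed(424)
  for (rep in 1:4) {
    ref <- make_ref(sample(2:5, 1), seed = 1000 + rep)
    hp <- ref$hairpins
    reads <- character(0)
    for (i in 1:40) {
      h <- sample(nrow(hp), 1)
      ext <- paste0(hp$sequence[h], hp$flank3[h])
      len <- sample(16:24, 1)
      s <- sample(nchar(ext) - len + 1L, 1)
      r <- substr(ext, s, s + len - 1L)
      if (runif(1) < 0.5) {           # plant a substitution
        p <- sample(len, 1)
        substr(r, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                          substr(r, p, p)), 1)
      }
      if (runif(1) < 0.3)             # plant a short tail
        r <- paste0(r, paste(sample(c("A", "C", "G", "T"),
                                    sample(1:3, 1), replace = TRUE),
                             collapse = ""))
      reads <- c(reads, r)
    }
    reads <- unique(reads)
    al <- align_ungapped(data.frame(sequence = reads,
                                    count = rep(1L, length(reads))), hp)
    for (r in reads) {
      mine <- al$alignments[al$alignments$sequence == r,
                            c("hairpin_id", "start", "templated_len",
                              "mismatches", "tail")]
      oracle <- brute_align_one(r, hp)
      if (is.null(oracle)) {
        expect_equal(nrow(mine), 0L)
      } else if (length(unique(oracle$hairpin_id)) > 1L) {
        expect_equal(nrow(mine), 0L)   # ambiguous, dropped
      } else {
        mine <- mine[order(mine$start, mine$templated_len), , drop = FALSE]
        rownames(mine) <- NULL
        expect_equal(mine, oracle[, names(mine)], ignore_attr = TRUE)
      }
    }
  }
})

test_that("arm assignment picks the nearest arm within offset caps", {
  ref <- make_ref(1, seed = 8)
  hp <- ref$hairpins; arms <- ref$arms
  mk <- function(seqs) {
    al <- align_ungapped(data.frame(sequence = seqs,
                                    count = rep(1L, length(seqs))), hp)
    assign_to_arm(al$alignments, arms, al$tally)
  }
  # read starting exactly at the 5p arm start
  r5 <- substr(hp$sequence, arms$arm_start[1], arms$arm_end[1])
  a5 <- mk(r5)
  expect_equal(a5$assigned$accession, arms$accession[1])
  expect_equal(a5$assigned$start_offset, 0L)
  # read in the 3p arm region resolves to the 3p arm
  i3 <- which(arms$arm_start > 30)
  r3 <- substr(hp$sequence, arms$arm_start[i3] + 1L, arms$arm_end[i3] + 1L)
  a3 <- mk(r3)
  expect_equal(a3$assigned$accession, arms$accession[i3])
  expect_equal(a3$assigned$start_offset, 1L)
  # loop read >= 5 nt from both arm starts: unassigned
  rl <- substr(hp$sequence, arms$arm_start[1] + 12L, arms$arm_start[1] + 33L)
  al <- mk(rl)
  expect_equal(nrow(al$assigned), 0L)
  expect_equal(unname(al$tally["unassigned"]), 1L)
})

test_that("read accounting is conserved through every stage", {
  ref <- make_ref(2, seed = 99)
  sp <- rich_spectrum(ref)
  cfg <- spectrum_config(sp, reads_per_sample = 500L, error_rate = 0.01,
                         uniform_errors = FALSE)
  td <- tempfile()
  sim <- simulate_reads(cfg, ref$hairpins, ref$arms, c("s1", "s2"), td,
                        seed = 17)
  ra <- run_assign(sim$fastq, cfg$adapter, ref$hairpins, ref$arms)
  for (s in names(ra$tallies)) {
    tl <- ra$tallies[[s]]
    expect_equal(unname(tl["input"]), 500)
    expect_equal(unname(tl["kept"]),
                 unname(tl["assigned"] + tl["unassigned"] +
                          tl["ambiguous"] + tl["unaligned"]))
    expect_equal(unname(tl["input"]),
                 unname(tl["kept"] + tl["length_filtered"] +
                          tl["quality_filtered"]))
    expect_equal(sum(ra$assigned[[s]]$count), unname(tl["assigned"]))
  }
})
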