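# Shared fixtures: tiny references and a one-call mini pipeline.

make_ref <- function(n = 2L, seed = 7L, ...) {
  simulate_reference(n, seed = seed, ...)
}

# Run FASTQ -> trim -> collapse -> align -> assign for each sample and
# return the per-sample assigned tables plus tallies.
run_assign <- function(fastq, adapter, hairpins, arms, ...) {
  assigned <- list()
  tallies <- list()
  for (s in names(fastq)) {
    pre <- suppressWarnings(read_fastq_collapsed(fastq[[s]], adapter))
    al <- align_ungapped(pre$reads, hairpins, ...)
    as1 <- assign_to_arm(al$alignments, arms, c(pre$tally, al$tally))
    assigned[[s]] <- as1$assigned
    tallies[[s]] <- as1$tally
  }
  list(assigned = assigned, tallies = tallies)
}

# A moderately rich spectrum exercising every category, for end-to-end
# truth-recovery tests.  Tail bases are chosen against the reference so
# the planted labels are unambiguous.
rich_spectrum <- function(ref, arm_idx = 1L) {
  acc <- ref$arms$accession[arm_idx]
  a <- ref$arms[arm_idx, ]
  hp <- ref$hairpins[ref$hairpins$id == a$hairpin_id, ]
  ext <- paste0(hp$sequence, hp$flank3)
  tail_base <- function(end_offset) {
    cont <- substr(ext, a$arm_end + end_offset + 1L,
                   a$arm_end + end_offset + 1L)
    if (cont == "T") "A" else "T"
  }
  sp <- data.frame(
    start_offset = c(0L, 0L, 0L, 1L, -1L, 1L, 0L),
    end_offset   = c(0L, -2L, 1L, 0L, 0L, -1L, 0L),
    nta          = c("", "", "", "", "", "", tail_base(0L)),
    fraction     = c(0.40, 0.15, 0.10, 0.08, 0.07, 0.05, 0.15),
    stringsAsFactors = FALSE)
  sp$nta[6] <- tail_base(-1L)
  stats::setNames(list(sp), acc)
}
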