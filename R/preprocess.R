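#' Adapter trimming, read collapsing and ungapped alignment
#'
#' Small-RNA reads are longer than the mature insert, so every read carries
#' a 3' sequencing adapter (or a prefix of it).  Trimming removes the
#' adapter, collapsing merges identical inserts, and alignment places each
#' insert on a hairpin precursor (+ its genomic 3' flank) as a contiguous
#' ungapped match of a read *prefix*; whatever 3' remainder the reference
#' cannot explain becomes the candidate non-templated tail.
#'
#' @name preprocess-align
NULL

#' Trim a 3' sequencing adapter
#'
#' Removes the suffix of each read that matches the start of the adapter:
#' either an exact match to an adapter prefix of at least `min_overlap`
#' bases, or a full-adapter occurrence with at most 10\% mismatches.  The
#' earliest (5'-most) qualifying adapter start is used.  Reads without a
#' recognizable adapter are passed through unchanged and flagged.
#'
#' @param reads character vector of read sequences.
#' @param adapter adapter sequence (non-empty).
#' @param min_overlap minimum exact overlap with the adapter start
#'   (default 3).
#' @return data.frame with columns `sequence` (trimmed insert) and
#'   `trimmed` (logical).
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 3L) {
  stopifnot(nzchar(adapter), min_overlap >= 1L)
  adapter <- .normalize_seq(adapter)
  reads <- .normalize_seq(reads)
  na <- nchar(adapter)
  nr <- nchar(reads)
  cut_at <- rep(NA_integer_, length(reads))   # adapter start, 1-based
  max_mm <- floor(0.1 * na)
  # position-outer scan, vectorized across reads: the earliest qualifying
  # adapter start wins, so still-unset reads are filled left to right
  for (pos in seq_len(max(nr, 0L))) {
    ov <- pmin(nr - pos + 1L, na)
    open <- which(is.na(cut_at) & ov >= min_overlap)
    if (!length(open)) next
    rseg <- substr(reads[open], pos, pos + ov[open] - 1L)
    hit <- rseg == substring(adapter, 1L, ov[open])
    full <- ov[open] == na & !hit
    if (any(full) && max_mm > 0L) {
      mm <- integer(sum(full))
      idx <- open[full]
      for (k in seq_len(na))
        mm <- mm + (substr(reads[idx], pos + k - 1L, pos + k - 1L) !=
                      substr(adapter, k, k))
      hit[full] <- mm <= max_mm
    }
    cut_at[open[hit]] <- pos
  }
  trimmed <- !is.na(cut_at)
  out_seq <- reads
  out_seq[trimmed] <- substr(reads[trimmed], 1L, cut_at[trimmed] - 1L)
  data.frame(sequence = out_seq, trimmed = trimmed, stringsAsFactors = FALSE)
}

#' Collapse identical reads and apply length/quality filters
#'
#' @param sequences trimmed insert sequences.
#' @param counts per-sequence multiplicities (default 1 each).
#' @param mean_quality optional per-read mean Phred quality; reads below
#'   `min_mean_quality` are excluded.
#' @param min_len,max_len length window, defaults 15 and 28 nt (brackets
#'   the mature-miRNA size range).
#' @param min_mean_quality quality threshold (default 20).
#' @return list with `reads` (data.frame sequence/count of kept reads,
#'   collapsed) and `tally` (named vector: input, kept, length_filtered,
#'   quality_filtered) satisfying input = kept + filtered.
#' @export
collapse_and_filter <- function(sequences, counts = NULL, mean_quality = NULL,
                                min_len = 15L, max_len = 28L,
                                min_mean_quality = 20) {
  if (is.null(counts)) counts <- rep(1L, length(sequences))
  stopifnot(length(counts) == length(sequences), all(counts >= 1L))
  n_in <- sum(counts)
  qual_ok <- if (is.null(mean_quality)) rep(TRUE, length(sequences))
             else mean_quality >= min_mean_quality
  len <- nchar(sequences)
  len_ok <- len >= min_len & len <= max_len
  keep <- qual_ok & len_ok
  n_qual <- sum(counts[!qual_ok])
  n_len <- sum(counts[qual_ok & !len_ok])
  kept <- sequences[keep]
  kc <- counts[keep]
  agg <- if (length(kept)) {
    tapply(kc, kept, sum)
  } else integer(0)
  reads <- data.frame(sequence = names(agg),
                      count = as.integer(unname(agg)),
                      stringsAsFactors = FALSE)
  reads <- reads[order(reads$sequence), , drop = FALSE]
  rownames(reads) <- NULL
  tally <- c(input = n_in, kept = sum(kc),
             length_filtered = n_len, quality_filtered = n_qual)
  stopifnot(tally["input"] ==
              tally["kept"] + tally["length_filtered"] + tally["quality_filtered"])
  list(reads = reads, tally = tally)
}

#' Read a FASTQ file into collapsed, filtered reads
#'
#' Convenience wrapper: FASTQ -> adapter trimming -> collapse/filter.
#' @param fastq_path input FASTQ (optionally gzipped).
#' @param adapter 3' adapter sequence; `NULL` skips trimming.
#' @param ... passed to [collapse_and_filter].
#' @inheritParams trim_adapter
#' @return as [collapse_and_filter], with an extra tally entry `untrimmed`
#'   counting reads in which no adapter was found (they are retained).
#' @export
read_fastq_collapsed <- function(fastq_path, adapter, min_overlap = 3L, ...) {
  fq <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(fastq_path))
  seqs <- as.character(fq)
  ql <- as(Biostrings::quality(fq), "IntegerList")
  qmean <- sum(ql) / pmax(lengths(ql), 1L)
  untrimmed <- 0L
  if (!is.null(adapter)) {
    tr <- trim_adapter(seqs, adapter, min_overlap)
    seqs <- tr$sequence
    untrimmed <- sum(!tr$trimmed)
  }
  res <- collapse_and_filter(seqs, mean_quality = qmean, ...)
  res$tally <- c(res$tally, untrimmed = untrimmed)
  res
}

# Align one read sequence against one extended reference (hairpin+flank).
# Returns a data.frame of candidate (start, templated_len, mismatches, tail)
# rows: for each start and mismatch budget, the maximal templated prefix
# whose final base matches the reference (a terminal mismatch is never the
# allowed substitution; it belongs to the tail).
.align_one_ref <- function(read, ext, max_mismatch = 1L, max_tail = 6L,
                           min_templated = 14L) {
  nr <- nchar(read)
  ne <- nchar(ext)
  rv <- utf8ToInt(read)
  ev <- utf8ToInt(ext)
  out <- vector("list", 0L)
  for (s in seq_len(ne)) {
    span <- min(nr, ne - s + 1L)
    if (span < min_templated) next
    mm <- rv[seq_len(span)] != ev[s:(s + span - 1L)]
    cum <- cumsum(mm)
    for (budget in 0:max_mismatch) {
      ok <- which(cum <= budget & !mm)    # positions usable as templated end
      if (!length(ok)) next
      k <- max(ok)
      nmm <- cum[k]
      if (nmm != budget && budget > 0L) next  # same candidate as lower budget
      if (k < min_templated) next
      tail_len <- nr - k
      if (tail_len > max_tail) next
      out[[length(out) + 1L]] <- list(start = s, templated_len = k,
                                      mismatches = as.integer(nmm),
                                      tail = substr(read, k + 1L, nr))
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, lapply(out, as.data.frame, stringsAsFactors = FALSE))
}

#' Ungapped alignment of reads to hairpins plus flanks
#'
#' Each read is placed as a contiguous, gap-free match of a read prefix to
#' a hairpin extended by its genomic 3' flank, allowing at most
#' `max_mismatch` internal substitutions.  The unexplained 3' remainder is
#' the candidate non-templated tail (at most `max_tail` bases).  A 3'-
#' terminal mismatching base is never counted as the allowed substitution:
#' it is shunted into the tail, since it is indistinguishable from a
#' non-templated addition.  Candidates are ranked by (fewest mismatches,
#' shortest tail); a read whose best rank is achieved on two different
#' hairpins is ambiguous and excluded from quantification.
#'
#' @param reads data.frame with `sequence` and `count` (from
#'   [collapse_and_filter]).
#' @param hairpins a [hairpin_set].
#' @param max_mismatch maximum internal substitutions (default 1).
#' @param max_tail maximum unexplained 3' tail length (default 6).
#' @param min_templated minimum templated prefix length (default 14).
#' @return list with `alignments` (data.frame: sequence, count, hairpin_id,
#'   start, templated_len, mismatches, tail; one row per surviving
#'   candidate, possibly several per read on one hairpin) and `tally`
#'   (aligned / ambiguous / unaligned read counts).
#' @export
align_ungapped <- function(reads, hairpins, max_mismatch = 1L,
                           max_tail = 6L, min_templated = 14L) {
  ext <- .extended_seq(hairpins)
  ord <- order(hairpins$id)               # deterministic hairpin ordering
  res <- vector("list", nrow(reads))
  tally <- c(aligned = 0L, ambiguous = 0L, unaligned = 0L)
  for (i in seq_len(nrow(reads))) {
    cand <- NULL
    for (j in ord) {
      hits <- .align_one_ref(reads$sequence[i], ext[j], max_mismatch,
                             max_tail, min_templated)
      if (!is.null(hits)) {
        hits$hairpin_id <- hairpins$id[j]
        cand <- rbind(cand, hits)
      }
    }
    if (is.null(cand)) {
      tally["unaligned"] <- tally["unaligned"] + reads$count[i]
      next
    }
    rank <- cand$mismatches * (max_tail + 1L) + nchar(cand$tail)
    best <- cand[rank == min(rank), , drop = FALSE]
    if (length(unique(best$hairpin_id)) > 1L) {
      tally["ambiguous"] <- tally["ambiguous"] + reads$count[i]
      next
    }
    best <- best[order(best$start), , drop = FALSE]
    best$sequence <- reads$sequence[i]
    best$count <- reads$count[i]
    res[[i]] <- best
    tally["aligned"] <- tally["aligned"] + reads$count[i]
  }
  alignments <- do.call(rbind, res)
  if (is.null(alignments))
    alignments <- data.frame(start = integer(), templated_len = integer(),
                             mismatches = integer(), tail = character(),
                             hairpin_id = character(), sequence = character(),
                             count = integer(), stringsAsFactors = FALSE)
  rownames(alignments) <- NULL
  list(alignments = alignments, tally = tally)
}

#' Assign alignments to mature arms
#'
#' Among a read's equal-rank candidate placements on its (single) hairpin,
#' the one whose templated 5' end is nearest an annotated arm start wins;
#' ties between placements break toward the smaller |5' offset| and then
#' the smaller start.  The assignment stands only if both the 5' offset
#' and the templated 3' offset are within the caps.
#'
#' @param alignments,tally output of [align_ungapped].
#' @param arms an [arm_set].
#' @param max_start_offset cap on |5' offset| (default 4).
#' @param max_end_offset cap on |templated 3' offset| (default 6).
#' @return list with `assigned` (data.frame: sequence, count, hairpin_id,
#'   accession, name, start, templated_len, mismatches, tail, start_offset,
#'   end_offset) and `tally` extended with `assigned` / `unassigned`.
#' @export
assign_to_arm <- function(alignments, arms, tally = NULL,
                          max_start_offset = 4L, max_end_offset = 6L) {
  key <- paste(alignments$sequence, alignments$hairpin_id, sep = "\r")
  groups <- split(seq_len(nrow(alignments)), key)
  rows <- vector("list", length(groups))
  n_assigned <- 0L; n_unassigned <- 0L
  for (g in groups) {
    al <- alignments[g, , drop = FALSE]
    hp_arms <- arms[arms$hairpin_id == al$hairpin_id[1L], , drop = FALSE]
    best <- NULL
    if (nrow(hp_arms)) {
      for (r in seq_len(nrow(al))) {
        d <- abs(al$start[r] - hp_arms$arm_start)
        a <- which.min(d)                 # nearest arm start
        so <- al$start[r] - hp_arms$arm_start[a]
        eo <- (al$start[r] + al$templated_len[r] - 1L) - hp_arms$arm_end[a]
        if (abs(so) > max_start_offset || abs(eo) > max_end_offset) next
        cand <- cbind(al[r, , drop = FALSE],
                      data.frame(accession = hp_arms$accession[a],
                                 name = hp_arms$name[a],
                                 start_offset = so, end_offset = eo,
                                 stringsAsFactors = FALSE))
        if (is.null(best) ||
            abs(cand$start_offset) < abs(best$start_offset) ||
            (abs(cand$start_offset) == abs(best$start_offset) &&
             cand$start < best$start))
          best <- cand
      }
    }
    if (is.null(best)) n_unassigned <- n_unassigned + al$count[1L]
    else { rows[[length(rows) + 1L]] <- best; n_assigned <- n_assigned + best$count }
  }
  rows <- Filter(Negate(is.null), rows)
  assigned <- if (length(rows)) do.call(rbind, rows)
              else data.frame(sequence = character(), count = integer(),
                              hairpin_id = character(), accession = character(),
                              name = character(), start = integer(),
                              templated_len = integer(), mismatches = integer(),
                              tail = character(), start_offset = integer(),
                              end_offset = integer(), stringsAsFactors = FALSE)
  assigned <- assigned[order(assigned$accession, assigned$start,
                             assigned$sequence), , drop = FALSE]
  rownames(assigned) <- NULL
  if (!is.null(tally)) {
    tally["assigned"] <- n_assigned
    tally["unassigned"] <- n_unassigned
    tally["aligned"] <- unname(tally["aligned"])
  } else tally <- c(assigned = n_assigned, unassigned = n_unassigned)
  list(assigned = assigned, tally = tally)
}
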