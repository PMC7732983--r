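# Independent brute-force oracles.  These deliberately reimplement the
# checked operations with naive character-level loops, sharing no code
# with the package internals.

# Exhaustive sliding-window aligner: enumerate every (hairpin, start,
# templated_len) placement, score it, keep the best-rank set.
brute_align_one <- function(read, hairpins, max_mismatch = 1L,
                            max_tail = 6L, min_templated = 14L) {
  cand <- list()
  rch <- strsplit(read, "")[[1L]]
  L <- length(rch)
  for (h in seq_len(nrow(hairpins))) {
    ext <- paste0(hairpins$sequence[h], hairpins$flank3[h])
    ech <- strsplit(ext, "")[[1L]]
    M <- length(ech)
    for (s in seq_len(M)) {
      kmax <- min(L, M - s + 1L)
      if (kmax < min_templated) next
      for (k in min_templated:kmax) {
        mm <- 0L
        for (p in seq_len(k)) if (rch[p] != ech[s + p - 1L]) mm <- mm + 1L
        if (mm > max_mismatch) next
        if (rch[k] != ech[s + k - 1L]) next        # terminal must match
        tail_len <- L - k
        if (tail_len > max_tail) next
        cand[[length(cand) + 1L]] <- data.frame(
          hairpin_id = hairpins$id[h], start = s, templated_len = k,
          mismatches = mm,
          tail = if (tail_len) paste(rch[(k + 1L):L], collapse = "") else "",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(cand)) return(NULL)
  cand <- do.call(rbind, cand)
  rank <- cand$mismatches * (max_tail + 1L) + nchar(cand$tail)
  best <- cand[rank == min(rank), , drop = FALSE]
  best <- best[order(best$hairpin_id, best$start, best$templated_len), ,
               drop = FALSE]
  rownames(best) <- NULL
  best
}

# Textbook Benjamini-Hochberg step-up adjusted p-values.
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- 1
  for (i in n:1) {
    running <- min(running, p[o[i]] * n / i)
    adj[o[i]] <- running
  }
  adj
}

# Naive site scan: slide a window over the UTR and compare substrings.
brute_site_scan <- function(seed, utr, site_types) {
  rc <- function(x) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste(rev(comp[strsplit(x, "")[[1L]]]), collapse = "")
  }
  pats <- character(0)
  if ("7mer-m8" %in% site_types) pats <- c(pats, rc(seed))
  if ("7mer-A1" %in% site_types)
    pats <- c(pats, paste0(rc(substr(seed, 1, 6)), "A"))
  if ("8mer" %in% site_types) pats <- c(pats, paste0(rc(seed), "A"))
  pos <- integer(0)
  for (p in pats) {
    w <- nchar(p)
    for (i in seq_len(max(nchar(utr) - w + 1L, 0L)))
      if (substr(utr, i, i + w - 1L) == p) pos <- c(pos, i)
  }
  length(unique(pos))
}

# Median-of-ratios size factors, computed the long way.
brute_size_factors <- function(m) {
  keep <- apply(m, 1L, function(r) all(r > 0))
  mm <- m[keep, , drop = FALSE]
  geo <- apply(mm, 1L, function(r) exp(mean(log(r))))
  sf <- apply(mm, 2L, function(col) median(col / geo))
  sf / exp(mean(log(sf)))
}

# Expected six-way category, written as a plain decision list.
brute_category <- function(s, e, nta, nta_mode = "3p_addition") {
  has_nta <- nchar(nta) > 0
  if (s == 0 && e == 0 && !has_nta) return("canonical")
  if (s != 0 && (e != 0 || has_nta)) return("mixed")
  if (e != 0 && has_nta) return("mixed")
  if (s > 0) return("5' deletion")
  if (s < 0) return("5' addition")
  if (e > 0) return("3' addition")
  if (e < 0) return("3' deletion")
  if (nta_mode == "own") "nta" else "3' addition"
}
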