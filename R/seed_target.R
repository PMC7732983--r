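#' Seed extraction, seed-shifted target prediction and enrichment
#'
#' A 5'-shifted isomiR carries a different seed (mature positions 2-8)
#' than its archetype, and therefore a different target repertoire.  This
#' module extracts seeds for arbitrary 5' offsets, detects collisions with
#' the canonical seeds of other arms, scans 3'UTRs for the canonical
#' TargetScan-style site classes (8mer, 7mer-m8, 7mer-A1), compares target
#' sets, and tests gene-set enrichment of targets with the one-sided
#' Fisher exact (hypergeometric) test with BH correction.
#'
#' @name seed-target
NULL

#' Seed of a (possibly 5'-shifted) mature sequence
#'
#' Returns mature positions 2-8 (a 7-mer) of the 5'-adjusted sequence.
#' For a positive 5' offset the window slides toward the 3' end of the
#' archetype; for a negative offset the templated hairpin bases upstream
#' of the archetype must be supplied via `upstream` (they are prepended).
#'
#' @param mature_sequence archetype mature sequence (DNA or RNA).
#' @param start_offset signed 5' offset (0 = canonical seed).
#' @param upstream templated hairpin sequence immediately 5' of the
#'   archetype (needed only for negative offsets).
#' @return 7-mer seed in DNA alphabet.
#' @export
seed_of <- function(mature_sequence, start_offset = 0L, upstream = "") {
  seqd <- .normalize_seq(mature_sequence)
  up <- .normalize_seq(upstream)
  if (start_offset < 0L) {
    need <- -start_offset
    if (nchar(up) < need)
      stop("need ", need, " upstream base(s) for offset ", start_offset)
    seqd <- paste0(substr(up, nchar(up) - need + 1L, nchar(up)), seqd)
    start_offset <- 0L
  }
  first <- start_offset + 2L              # mature position 2 of shifted seq
  last <- start_offset + 8L
  if (last > nchar(seqd))
    stop("seed window escapes the available sequence")
  substr(seqd, first, last)
}

#' Seed collisions between isomiR seeds and canonical seeds
#'
#' @param isomir_seeds data.frame with columns `accession`, `label`,
#'   `seed`.
#' @param canonical_index data.frame with columns `accession`, `name`,
#'   `seed` (one canonical seed per annotated arm).
#' @return data.frame of exact 7-mer matches (isomiR x canonical arm),
#'   self-pairs (same accession) excluded.
#' @export
seed_collisions <- function(isomir_seeds, canonical_index) {
  m <- merge(isomir_seeds, canonical_index, by = "seed",
             suffixes = c("_isomir", "_canonical"))
  m <- m[m$accession_isomir != m$accession_canonical, , drop = FALSE]
  m <- m[order(m$accession_isomir, m$label, m$accession_canonical), ,
         drop = FALSE]
  rownames(m) <- NULL
  m
}

.site_patterns <- function(seed) {
  seed <- .normalize_seq(seed)
  stopifnot(nchar(seed) == 7L)
  rc <- function(x)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  list(`7mer-m8` = rc(seed),                                # rc(pos 2-8)
       `7mer-A1` = paste0(rc(substr(seed, 1L, 6L)), "A"),   # rc(pos 2-7)+A
       `8mer` = paste0(rc(seed), "A"))                      # both
}

#' Predict targets of a seed on a set of 3'UTRs
#'
#' Scans each UTR (given strand only) for the site classes enabled:
#' `7mer-m8` (reverse complement of seed positions 2-8), `7mer-A1`
#' (reverse complement of positions 2-7 followed by A) and `8mer` (both).
#' A gene qualifies with at least one site of an enabled type.  An 8mer
#' occurrence also counts as one 7mer-m8 and one 7mer-A1 occurrence; per
#' gene, the reported `sites` count is the number of distinct qualifying
#' site positions.
#'
#' @param seed 7-mer seed.
#' @param utrs named character vector or DNAStringSet of 3'UTR sequences.
#' @param site_types subset of c("8mer", "7mer-m8", "7mer-A1").
#' @return data.frame `gene`, `sites` (class `target_set`); attribute
#'   `seed` records the query.
#' @export
predict_targets <- function(seed, utrs,
                            site_types = c("8mer", "7mer-m8", "7mer-A1")) {
  site_types <- match.arg(site_types, several.ok = TRUE)
  if (inherits(utrs, "XStringSet")) utrs <- as.character(utrs)
  utrs <- vapply(utrs, .normalize_seq, character(1))
  pats <- .site_patterns(seed)[site_types]
  genes <- names(utrs)
  stopifnot(!is.null(genes))
  sites <- vapply(utrs, function(u) {
    pos <- integer(0)
    for (p in pats) {
      hits <- gregexpr(p, u, fixed = TRUE)[[1L]]
      if (hits[1L] != -1L) pos <- c(pos, as.integer(hits))
    }
    length(unique(pos))
  }, integer(1))
  out <- data.frame(gene = genes[sites > 0], sites = sites[sites > 0],
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "seed") <- .normalize_seq(seed)
  class(out) <- c("target_set", "data.frame")
  out
}

#' Venn region counts for 2 or 3 target sets
#'
#' Exact set-algebra counts for every region of the Venn partition; for
#' more than 3 sets a pairwise intersection matrix is returned instead.
#'
#' @param sets named list of gene-id vectors (or `target_set` objects).
#' @return for 2-3 sets, a named integer vector of region counts (names
#'   like "A_only", "A&B", summing to the union size); for >3 sets, a
#'   matrix of pairwise intersection sizes.
#' @export
target_overlap <- function(sets) {
  sets <- lapply(sets, function(s) {
    if (is.data.frame(s)) unique(s$gene) else unique(as.character(s))
  })
  nm <- names(sets)
  stopifnot(!is.null(nm), length(sets) >= 2L)
  if (length(sets) > 3L) {
    m <- outer(seq_along(sets), seq_along(sets),
               Vectorize(function(i, j) length(intersect(sets[[i]], sets[[j]]))))
    dimnames(m) <- list(nm, nm)
    return(m)
  }
  all_genes <- unique(unlist(sets))
  member <- vapply(sets, function(s) all_genes %in% s,
                   logical(length(all_genes)))
  member <- matrix(member, ncol = length(sets),
                   dimnames = list(NULL, nm))
  key <- apply(member, 1L, function(r)
    paste(nm[r], collapse = "&"))
  regions <- table(key)
  out <- stats::setNames(as.integer(regions), names(regions))
  stopifnot(sum(out) == length(all_genes))
  out
}

#' Read a GMT gene-set file
#' @param path tab-separated GMT (set name, description, member genes).
#' @return named list of gene-id vectors; descriptions in attribute
#'   `description`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) stop("malformed GMT line(s): ", which(bad)[1L])
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, "", 1L)
  attr(sets, "description") <- vapply(parts, `[`, "", 2L)
  sets
}

#' Write gene sets to GMT
#' @param sets named list of gene vectors.
#' @param path output path.
#' @param description per-set description (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Fisher gene-set enrichment of a target list
#'
#' One-sided Fisher exact test (hypergeometric upper tail) of the 2x2
#' table {in set, not in set} x {target, not target} for every gene set,
#' BH correction across sets, significance at `p_threshold` (default
#' 0.01).  The reported ratio is the fraction of the set's genes that are
#' targeted.  The universe defaults to the union of all gene-set members.
#'
#' @param targets character vector of target gene ids (or `target_set`).
#' @param gene_sets named list of gene-id vectors (e.g. from [read_gmt]).
#' @param universe background gene ids; must contain all set members and
#'   targets.
#' @param p_threshold significance threshold on the raw p (default 0.01).
#' @return data.frame: set, set_size, overlap, ratio, p, fdr, significant;
#'   ordered by p.
#' @export
enrich_targets <- function(targets, gene_sets, universe = NULL,
                           p_threshold = 0.01) {
  if (is.data.frame(targets)) targets <- targets$gene
  targets <- unique(as.character(targets))
  stopifnot(length(gene_sets) > 0, !is.null(names(gene_sets)))
  if (is.null(universe)) universe <- unique(unlist(gene_sets))
  if (!length(universe)) stop("empty universe")
  miss <- setdiff(targets, universe)
  if (length(miss))
    stop("targets outside the universe: ", paste(utils::head(miss, 5),
                                                 collapse = ", "))
  n_univ <- length(universe)
  n_tar <- length(targets)
  rows <- lapply(names(gene_sets), function(nm) {
    gs <- intersect(unique(gene_sets[[nm]]), universe)
    if (!length(gs)) stop("empty gene set: ", nm)
    k <- length(intersect(gs, targets))
    # P(X >= k), X ~ Hypergeom(drawing n_tar from n_univ with |gs| marked)
    p <- stats::phyper(k - 1L, length(gs), n_univ - length(gs), n_tar,
                       lower.tail = FALSE)
    data.frame(set = nm, set_size = length(gs), overlap = k,
               ratio = k / length(gs), p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$fdr <- stats::p.adjust(res$p, method = "BH")
  res$significant <- res$p < p_threshold
  res <- res[order(res$p, res$set), , drop = FALSE]
  rownames(res) <- NULL
  res
}
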