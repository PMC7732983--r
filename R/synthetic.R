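#' Synthetic small RNA-seq data with full ground truth
#'
#' Generators for every input the pipeline consumes: hairpin/arm
#' references, FASTQ reads with a configured isomiR spectrum (templated 5'
#' and 3' shifts, non-templated tails, sequencing errors, 3' adapter),
#' negative-binomial count matrices with planted linear or U-shaped
#' condition effects, and 3'UTR/gene-set inputs with planted seed-match
#' sites.  Every generator is deterministic given its seed and returns the
#' ground truth alongside the artifact, so pipeline output can be checked
#' exactly.
#'
#' @name synthetic-data
NULL

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# Derive a per-stream 31-bit seed from a master seed, reproducibly.
# Double-precision arithmetic: the products stay well below 2^53.
.derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(stream) * 104729) %%
               2147483629)
}

.BASES <- c("A", "C", "G", "T")

.random_dna <- function(n_len) {
  paste(sample(.BASES, n_len, replace = TRUE), collapse = "")
}

#' Generate a random hairpin reference with annotated arms
#'
#' Random precursor sequences with a 5p arm and a 3p arm, plus genomic 3'
#' flanks; a ready-made small reference for simulations and tests.
#'
#' @param n_hairpins number of precursors.
#' @param hairpin_len precursor length (default 70).
#' @param arm_len mature arm length (default 22).
#' @param flank_len genomic flank length (default 10).
#' @param seed RNG seed.
#' @return list with `hairpins` ([hairpin_set]) and `arms` ([arm_set]);
#'   arms are named `syn-miR-<i>-5p/-3p`.
#' @export
simulate_reference <- function(n_hairpins = 3L, hairpin_len = 70L,
                               arm_len = 22L, flank_len = 10L, seed = 1L) {
  stopifnot(hairpin_len >= 2L * arm_len + 6L)
  .with_seed(seed, {
    ids <- sprintf("syn-mir-%d", seq_len(n_hairpins))
    seqs <- vapply(ids, function(i) .random_dna(hairpin_len), character(1))
    flanks <- vapply(ids, function(i) .random_dna(flank_len), character(1))
    hp <- hairpin_set(ids, seqs, flanks, flank_len = flank_len)
    s5 <- 5L
    s3 <- hairpin_len - arm_len - 2L
    arms <- arm_set(
      name = c(sprintf("syn-miR-%d-5p", seq_len(n_hairpins)),
               sprintf("syn-miR-%d-3p", seq_len(n_hairpins))),
      accession = c(sprintf("SYNMAT%04d", seq_len(n_hairpins) * 2L - 1L),
                    sprintf("SYNMAT%04d", seq_len(n_hairpins) * 2L)),
      hairpin_id = rep(ids, 2L),
      arm_start = rep(c(s5, s3), each = n_hairpins),
      arm_end = rep(c(s5 + arm_len - 1L, s3 + arm_len - 1L),
                    each = n_hairpins),
      hairpins = hp)
    list(hairpins = hp, arms = arms)
  })
}

#' Specify an isomiR spectrum for read simulation
#'
#' @param spectra named list (arm accession -> data.frame with columns
#'   `start_offset`, `end_offset`, `nta`, `fraction`).  Fractions per arm
#'   must sum to 1 (tolerance 1e-9); offsets within the caps.
#' @param adapter 3' sequencing adapter appended to every read.
#' @param reads_per_sample reads generated per configured arm in each
#'   sample (the spectrum fractions are per arm, so each arm's spectrum
#'   is sampled independently at this depth).
#' @param error_rate per-base substitution probability (default 0).
#' @param allocation `"largest_remainder"` (deterministic counts per
#'   isoform; exact proportion recovery) or `"multinomial"`.
#' @param uniform_errors if FALSE (default), substitution errors are never
#'   placed on the first or last base of the templated region, keeping
#'   truth labels unambiguous; TRUE allows errors anywhere in the read.
#' @param read_length if non-NULL, reads are truncated to this many bases
#'   (insert + adapter prefix), emulating a fixed sequencing cycle count.
#' @param max_start_offset,max_end_offset offset caps (defaults 4, 6).
#' @return validated config list of class `spectrum_config`.
#' @export
spectrum_config <- function(spectra, adapter = "TGGAATTCTCGGGTGCCAAGG",
                            reads_per_sample = 1000L, error_rate = 0,
                            allocation = c("largest_remainder", "multinomial"),
                            uniform_errors = FALSE, read_length = NULL,
                            max_start_offset = 4L, max_end_offset = 6L) {
  allocation <- match.arg(allocation)
  stopifnot(is.list(spectra), !is.null(names(spectra)),
            reads_per_sample >= 1L, error_rate >= 0, error_rate < 1)
  for (acc in names(spectra)) {
    sp <- spectra[[acc]]
    stopifnot(all(c("start_offset", "end_offset", "nta", "fraction") %in%
                    names(sp)))
    if (abs(sum(sp$fraction) - 1) > 1e-9)
      stop("fractions for arm ", acc, " do not sum to 1")
    if (any(abs(sp$start_offset) > max_start_offset))
      stop("5' offset beyond cap for arm ", acc)
    if (any(abs(sp$end_offset) > max_end_offset))
      stop("3' offset beyond cap for arm ", acc)
    if (any(!grepl("^[ACGTUacgtu]*$", sp$nta)))
      stop("NTA tail outside ACGTU alphabet for arm ", acc)
  }
  structure(list(spectra = spectra, adapter = .normalize_seq(adapter),
                 reads_per_sample = as.integer(reads_per_sample),
                 error_rate = error_rate, allocation = allocation,
                 uniform_errors = uniform_errors, read_length = read_length,
                 max_start_offset = max_start_offset,
                 max_end_offset = max_end_offset),
            class = "spectrum_config")
}

# Largest-remainder apportionment of n among fractions (deterministic).
.largest_remainder <- function(fractions, n) {
  raw <- fractions * n
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    rem <- raw - base
    give <- order(rem, decreasing = TRUE)[seq_len(left)]
    base[give] <- base[give] + 1
  }
  as.integer(base)
}

# Templated isoform sequence for an arm at (start_offset, end_offset);
# errors if the span escapes hairpin+flank bounds or uses upstream bases
# that do not exist.
.isoform_seq <- function(hairpins, arms, accession, start_offset,
                         end_offset) {
  a <- arms[arms$accession == accession, , drop = FALSE]
  if (!nrow(a)) stop("unknown arm accession: ", accession)
  hp <- hairpins[hairpins$id == a$hairpin_id, , drop = FALSE]
  ext <- .extended_seq(hp)
  s <- a$arm_start + start_offset
  e <- a$arm_end + end_offset
  if (s < 1L || e > nchar(ext) || s >= e)
    stop("isoform (", start_offset, ",", end_offset, ") of ", accession,
         " escapes hairpin+flank bounds")
  substr(ext, s, e)
}

#' Simulate small-RNA FASTQ reads with a planted isomiR spectrum
#'
#' Every read is (templated isoform sequence) + (non-templated tail) +
#' (adapter), with substitution errors at the configured rate.  One FASTQ
#' per sample is written; the returned truth table gives the planted
#' isomiR label, category and count per sample.  The generator validates
#' (before writing anything) that each planted tail's first base differs
#' from the genomic continuation — otherwise the tail base would in truth
#' be a templated extension and the configured label would be wrong.
#'
#' @param config a [spectrum_config].
#' @param hairpins a [hairpin_set].
#' @param arms an [arm_set].
#' @param samples character vector of sample names.
#' @param out_dir directory for the FASTQ files (created).
#' @param seed master RNG seed; per-sample streams are derived from it.
#' @return list: `fastq` (named paths), `truth` (data.frame sample,
#'   accession, name, start_offset, end_offset, nta, label, category,
#'   uridylated, count).
#' @export
simulate_reads <- function(config, hairpins, arms, samples, out_dir,
                           seed = 1L) {
  stopifnot(inherits(config, "spectrum_config"), length(samples) >= 1L)
  # validate everything before any file is written
  iso <- list()
  for (acc in names(config$spectra)) {
    sp <- config$spectra[[acc]]
    for (r in seq_len(nrow(sp))) {
      tmpl <- .isoform_seq(hairpins, arms, acc, sp$start_offset[r],
                           sp$end_offset[r])
      nta <- .normalize_seq(sp$nta[r])
      if (nzchar(nta)) {
        a <- arms[arms$accession == acc, ]
        hp <- hairpins[hairpins$id == a$hairpin_id, ]
        ext <- .extended_seq(hp)
        nxt_pos <- a$arm_end + sp$end_offset[r] + 1L
        nxt <- if (nxt_pos <= nchar(ext)) substr(ext, nxt_pos, nxt_pos) else ""
        if (nzchar(nxt) && substr(nta, 1L, 1L) == nxt)
          stop("planted NTA for ", acc, " (", sp$start_offset[r], ",",
               sp$end_offset[r], ") starts with the templated continuation '",
               nxt, "'; its true label would differ from the configured one")
      }
      iso[[length(iso) + 1L]] <- list(accession = acc,
                                      name = a_name <- arms$name[arms$accession == acc],
                                      start_offset = sp$start_offset[r],
                                      end_offset = sp$end_offset[r],
                                      nta = nta, fraction = sp$fraction[r],
                                      templated = tmpl)
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fastq <- character(0)
  truth <- list()
  for (si in seq_along(samples)) {
    smp <- samples[si]
    sseed <- .derive_seed(seed, si)
    per_arm <- split(iso, vapply(iso, `[[`, "", "accession"))
    recs <- .with_seed(sseed, {
      out <- list()
      for (acc in names(per_arm)) {
        entries <- per_arm[[acc]]
        fr <- vapply(entries, `[[`, 0, "fraction")
        counts <- if (config$allocation == "largest_remainder")
          .largest_remainder(fr, config$reads_per_sample)
        else as.integer(stats::rmultinom(1L, config$reads_per_sample, fr))
        for (k in seq_along(entries)) {
          e <- entries[[k]]
          e$count <- counts[k]
          out[[length(out) + 1L]] <- e
        }
      }
      out
    })
    seqs <- character(0)
    for (e in recs) {
      if (e$count == 0L) next
      insert <- paste0(e$templated, e$nta)
      read <- paste0(insert, config$adapter)
      if (!is.null(config$read_length))
        read <- substr(read, 1L, config$read_length)
      reads <- rep(read, e$count)
      seqs <- c(seqs, reads)
      truth[[length(truth) + 1L]] <- data.frame(
        sample = smp, accession = e$accession, name = e$name,
        start_offset = e$start_offset, end_offset = e$end_offset,
        nta = e$nta, label = isomir_label(e$start_offset, e$end_offset),
        category = classify_isomir(e$start_offset, e$end_offset, e$nta),
        uridylated = is_uridylated(e$nta), count = e$count,
        stringsAsFactors = FALSE)
    }
    if (config$error_rate > 0) {
      tlens <- unlist(lapply(recs, function(e)
        rep(nchar(e$templated), e$count)))
      seqs <- .with_seed(.derive_seed(sseed, 1L),
                         .apply_errors(seqs, tlens, config$error_rate,
                                       config$uniform_errors))
    }
    path <- file.path(out_dir, paste0(smp, ".fastq"))
    .write_fastq(seqs, sprintf("%s_r%06d", smp, seq_along(seqs)), path)
    fastq[smp] <- path
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(fastq = fastq, truth = truth)
}

# Substitution errors; protected positions are the first and last base of
# the templated region unless uniform = TRUE (then all bases are fair
# game, including tail and adapter).
.apply_errors <- function(seqs, templated_lens, rate, uniform) {
  vapply(seq_along(seqs), function(i) {
    s <- strsplit(seqs[i], "")[[1L]]
    tl <- templated_lens[i]
    allowed <- if (uniform) seq_along(s)
               else setdiff(seq_len(length(s)), c(1L, tl, length(s)))
    hit <- allowed[stats::runif(length(allowed)) < rate]
    for (p in hit) s[p] <- sample(setdiff(.BASES, s[p]), 1L)
    paste(s, collapse = "")
  }, character(1))
}

.write_fastq <- function(seqs, ids, path) {
  qual <- strrep("I", nchar(seqs))
  con <- file(path, "wb")  # binary mode: byte-identical across platforms
  on.exit(close(con))
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n", qual), con, sep = "\n")
  invisible(path)
}

#' Configure a negative-binomial count simulation
#'
#' @param n_features number of features.
#' @param conditions ordered condition labels (default Young, SEN, SEN+M).
#' @param n_replicates replicates per condition (default 3).
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   per-feature baseline mean (defaults log(200) and 1).
#' @param dispersion per-feature NB dispersion: scalar, vector of length
#'   `n_features`, or function(mean) -> dispersion (default 0.05).
#' @param effects NULL or data.frame with columns `feature` (index),
#'   `pattern` (one of linear-up, linear-down, U, inverted-U) and `fc1`,
#'   `fc2` (strictly positive per-transition fold changes).
#' @param seed RNG seed.
#' @return config list of class `count_sim_config`.
#' @export
count_sim_config <- function(n_features = 2000L,
                             conditions = c("Young", "SEN", "SEN+M"),
                             n_replicates = 3L,
                             baseline_meanlog = log(200),
                             baseline_sdlog = 1,
                             dispersion = 0.05,
                             effects = NULL, seed = 1L) {
  stopifnot(n_features >= 1L, n_replicates >= 2L, length(conditions) >= 2L)
  if (!is.null(effects)) {
    stopifnot(all(c("feature", "pattern", "fc1", "fc2") %in% names(effects)),
              all(effects$fc1 > 0), all(effects$fc2 > 0),
              all(effects$pattern %in%
                    c("linear-up", "linear-down", "U", "inverted-U")),
              all(effects$feature >= 1L), all(effects$feature <= n_features))
  }
  structure(list(n_features = as.integer(n_features),
                 conditions = conditions,
                 n_replicates = as.integer(n_replicates),
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 dispersion = dispersion, effects = effects,
                 seed = as.integer(seed)),
            class = "count_sim_config")
}

#' Simulate a negative-binomial count matrix with planted condition effects
#'
#' Per-feature baseline means are log-normal; condition means follow the
#' configured per-transition fold changes (`mean_k = baseline *
#' cumprod(fc)`); counts are NB(mean, dispersion) draws (Poisson when the
#' dispersion is 0).
#'
#' @param config a [count_sim_config].
#' @return list: `counts` (features x samples integer matrix, columns
#'   `<condition>_<rep>`), `conditions` (named sample -> condition),
#'   `truth` (data.frame feature, pattern ("flat" for nulls), fc1, fc2,
#'   baseline_mean).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "count_sim_config"))
  nc <- length(config$conditions)
  samples <- paste(rep(config$conditions, each = config$n_replicates),
                   rep(seq_len(config$n_replicates), nc), sep = "_")
  cond_of <- stats::setNames(rep(config$conditions,
                                 each = config$n_replicates), samples)
  .with_seed(config$seed, {
    base <- stats::rlnorm(config$n_features, config$baseline_meanlog,
                          config$baseline_sdlog)
    disp <- config$dispersion
    if (is.function(disp)) disp <- disp(base)
    disp <- rep_len(disp, config$n_features)
    fc <- matrix(1, config$n_features, nc)
    truth <- data.frame(feature = seq_len(config$n_features),
                        pattern = "flat", fc1 = 1, fc2 = 1,
                        baseline_mean = base, stringsAsFactors = FALSE)
    if (!is.null(config$effects)) {
      ef <- config$effects
      fc[ef$feature, 2L] <- ef$fc1
      if (nc >= 3L) fc[ef$feature, 3L] <- ef$fc1 * ef$fc2
      truth$pattern[ef$feature] <- ef$pattern
      truth$fc1[ef$feature] <- ef$fc1
      truth$fc2[ef$feature] <- ef$fc2
    }
    counts <- matrix(0L, config$n_features, length(samples),
                     dimnames = list(sprintf("f%05d",
                                             seq_len(config$n_features)),
                                     samples))
    for (j in seq_along(samples)) {
      k <- match(cond_of[j], config$conditions)
      mu <- base * fc[, k]
      counts[, j] <- ifelse(disp <= 0,
                            stats::rpois(config$n_features, mu),
                            stats::rnbinom(config$n_features,
                                           size = 1 / pmax(disp, 1e-12),
                                           mu = mu))
    }
    truth$feature <- rownames(counts)
    list(counts = counts, conditions = cond_of, truth = truth)
  })
}

#' Simulate 3'UTRs with planted seed sites, plus gene sets
#'
#' Designated genes receive `sites_per_gene` 8mer match sites (reverse
#' complement of the seed followed by A) of their assigned seed at random
#' positions; all other UTR sequence is rejection-sampled so that no UTR
#' contains an accidental 7mer-m8 or 7mer-A1 site of any planted seed.
#' Gene sets returned: one set per planted seed holding exactly its
#' target genes, plus background sets of random non-target genes.
#'
#' @param n_genes total genes (named g0001...).
#' @param planted named list: 7-mer seed -> character vector of gene ids
#'   to receive sites (ids must be among the generated gene names).
#' @param sites_per_gene planted sites per designated gene (default 1).
#' @param utr_length UTR length in nt (default 300).
#' @param n_background_sets,background_set_size random gene sets added to
#'   the GMT (defaults 5 and 20).
#' @param max_tries rejection-sampling bound per UTR (default 200).
#' @param seed RNG seed.
#' @return list: `utrs` (named character), `gene_sets` (named list),
#'   `truth` (data.frame gene, seed, n_sites for planted genes).
#' @export
simulate_utrs_genesets <- function(n_genes = 100L, planted = list(),
                                   sites_per_gene = 1L, utr_length = 300L,
                                   n_background_sets = 5L,
                                   background_set_size = 20L,
                                   max_tries = 200L, seed = 1L) {
  stopifnot(all(nchar(names(planted)) == 7L))
  genes <- sprintf("g%04d", seq_len(n_genes))
  for (sd in names(planted))
    stopifnot(all(planted[[sd]] %in% genes))
  all_pats <- unlist(lapply(names(planted), function(sd)
    .site_patterns(sd)[c("7mer-m8", "7mer-A1")]))
  clean <- function(u, except = character(0)) {
    pats <- setdiff(all_pats, except)
    !any(vapply(pats, function(p) grepl(p, u, fixed = TRUE), logical(1)))
  }
  .with_seed(seed, {
    utrs <- stats::setNames(character(n_genes), genes)
    gene_seed <- stats::setNames(rep(NA_character_, n_genes), genes)
    for (sd in names(planted)) gene_seed[planted[[sd]]] <- sd
    for (g in genes) {
      sd <- gene_seed[[g]]
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        u <- .random_dna(utr_length)
        if (!clean(u)) next
        if (!is.na(sd)) {
          site <- .site_patterns(sd)[["8mer"]]
          w <- nchar(site)
          # non-overlapping slots for the planted sites
          slots <- seq(1L, utr_length - w + 1L, by = w + 2L)
          pos <- sort(sample(slots, sites_per_gene))
          for (p in pos) substr(u, p, p + w - 1L) <- site
          own <- unlist(.site_patterns(sd)[c("7mer-m8", "7mer-A1")])
          if (!clean(u, except = own)) next
        }
        ok <- TRUE
        break
      }
      if (!ok) stop("rejection sampling failed for UTR of ", g,
                    " after ", max_tries, " tries")
      utrs[g] <- u
    }
    sets <- list()
    for (sd in names(planted))
      sets[[paste0("planted_", sd)]] <- planted[[sd]]
    non_targets <- setdiff(genes, unlist(planted))
    for (b in seq_len(n_background_sets)) {
      sz <- min(background_set_size, length(non_targets))
      sets[[sprintf("background_%02d", b)]] <- sort(sample(non_targets, sz))
    }
    truth <- do.call(rbind, c(
      list(data.frame(gene = character(), seed = character(),
                      n_sites = integer(), stringsAsFactors = FALSE)),
      lapply(names(planted), function(sd)
        if (length(planted[[sd]]))
          data.frame(gene = planted[[sd]], seed = sd,
                     n_sites = sites_per_gene, stringsAsFactors = FALSE))))
    list(utrs = utrs, gene_sets = sets, truth = truth)
  })
}
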