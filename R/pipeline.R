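#' Pipeline configuration, orchestration and reporting
#'
#' One configuration object drives the whole pipeline: paths to the
#' references, sample sheet, UTRs and gene sets, plus every module
#' parameter with its documented default.  `simulate_dataset()` writes a
#' complete synthetic input set with ground truth, `run_pipeline()`
#' executes preprocess -> align -> isomiR call -> quantify -> stats ->
#' targets -> enrichment, and `write_report()` assembles a markdown
#' summary.  All randomness flows from the single `seed` entry; stage
#' streams are derived from it deterministically.
#'
#' @name cli-report
NULL

.config_defaults <- function() list(
  hairpin_fasta = NULL, arm_gff3 = NULL, sample_sheet = NULL,
  utr_fasta = NULL, gmt = NULL, out_dir = NULL,
  adapter = "TGGAATTCTCGGGTGCCAAGG", min_overlap = 3L,
  min_len = 15L, max_len = 28L, min_mean_quality = 20,
  max_mismatch = 1L, max_tail = 6L, min_templated = 14L,
  max_start_offset = 4L, max_end_offset = 6L, flank_len = 10L,
  nta_mode = "3p_addition", strict_denominator = FALSE,
  pooling = "pool", fc_threshold = 1.5, alpha_fdr = 0.05,
  prior_df = 50, enrich_p_threshold = 0.01,
  de_condition_a = "SEN", de_condition_b = "SEN+M",
  condition_order = c("Young", "SEN", "SEN+M"),
  skip_targets = FALSE, seed = 1L)

#' Build a validated pipeline configuration
#'
#' @param ... configuration entries overriding the defaults (see
#'   `isomirseq:::.config_defaults()` for the full key list).  Unknown
#'   keys are rejected.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- .config_defaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$min_len >= 1L, cfg$max_len >= cfg$min_len,
            cfg$max_mismatch %in% 0:1, cfg$max_tail >= 0L,
            cfg$flank_len > cfg$max_end_offset,
            cfg$fc_threshold >= 1, cfg$alpha_fdr > 0, cfg$alpha_fdr < 1,
            cfg$enrich_p_threshold > 0, cfg$enrich_p_threshold < 1,
            cfg$nta_mode %in% c("3p_addition", "own"),
            cfg$pooling %in% c("pool", "average"))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from YAML
#' @param path YAML file whose keys match [pipeline_config] arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

.default_spectra <- function(arms, hairpins) {
  # emulates the observed composition: ~57% canonical, 3' deletion the
  # most frequent modification, ~3% 5'-shifted reads, uridylated tails.
  # The tail base prefers U but must differ from the genomic continuation
  # (otherwise it would in truth be a templated extension); arms whose
  # continuation is T get an A tail instead.
  template <- data.frame(
    start_offset = c(0L, 0L, 0L, 0L, 1L, -1L, 0L, 1L),
    end_offset   = c(0L, -1L, -2L, 1L, 0L, 0L, 0L, -1L),
    nta          = c("", "", "", "", "", "", "T", "T"),
    fraction     = c(0.57, 0.14, 0.06, 0.08, 0.02, 0.01, 0.07, 0.05),
    stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(arms)), function(i) {
    hp <- hairpins[hairpins$id == arms$hairpin_id[i], ]
    ext <- .extended_seq(hp)
    sp <- template
    for (r in which(nzchar(sp$nta))) {
      pos <- arms$arm_end[i] + sp$end_offset[r] + 1L
      cont <- if (pos <= nchar(ext)) substr(ext, pos, pos) else ""
      if (cont == substr(sp$nta[r], 1L, 1L))
        sp$nta[r] <- chartr("T", "A", sp$nta[r])
    }
    sp
  })
  stats::setNames(out, arms$accession)
}

#' Write a complete synthetic dataset to disk
#'
#' References (flank-extended FASTA + GFF3), per-sample FASTQ (3
#' conditions x 3 replicates by default), truth tables, 3'UTR FASTA, GMT
#' gene sets, a sample sheet, and a manifest recording seeds and file
#' checksums.
#'
#' @param out_dir output directory; must be empty unless `force`.
#' @param seed master seed.
#' @param n_hairpins precursors in the synthetic reference.
#' @param reads_per_sample reads per arm per FASTQ (default 100000).
#' @param error_rate per-base substitution probability (default 0).
#' @param conditions,n_replicates design (defaults Young/SEN/SEN+M x 3).
#' @param spectra optional named list of per-arm spectrum data.frames
#'   (see [spectrum_config]); by default every arm gets a realistic mix,
#'   identical across conditions.  To emulate condition-dependent
#'   redistribution, supply per-condition spectra as a named list
#'   condition -> spectra.
#' @param n_genes,utr_length UTR simulation size.
#' @param force overwrite a non-empty `out_dir`.
#' @return invisibly, the manifest list.
#' @export
simulate_dataset <- function(out_dir, seed = 1L, n_hairpins = 3L,
                             reads_per_sample = 100000L, error_rate = 0,
                             conditions = c("Young", "SEN", "SEN+M"),
                             n_replicates = 3L, spectra = NULL,
                             n_genes = 100L, utr_length = 300L,
                             force = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !force)
    stop("output directory not empty (use force = TRUE): ", out_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- simulate_reference(n_hairpins, seed = .derive_seed(seed, 101L))
  write_hairpins(ref$hairpins, file.path(out_dir, "hairpins.fa"))
  write_arm_annotations(ref$arms, file.path(out_dir, "arms.gff3"))
  per_cond <- !is.null(spectra) && all(names(spectra) %in% conditions)
  if (is.null(spectra)) spectra <- .default_spectra(ref$arms, ref$hairpins)
  fq_dir <- file.path(out_dir, "fastq")
  sheet <- list(); truth <- list()
  for (ci in seq_along(conditions)) {
    cn <- conditions[ci]
    sp <- if (per_cond) spectra[[cn]] else spectra
    cfg <- spectrum_config(sp, reads_per_sample = reads_per_sample,
                           error_rate = error_rate)
    smp <- paste0(gsub("[^A-Za-z0-9]", "", cn), "_", seq_len(n_replicates))
    sim <- simulate_reads(cfg, ref$hairpins, ref$arms, smp, fq_dir,
                          seed = .derive_seed(seed, 200L + ci))
    truth[[cn]] <- sim$truth
    # fastq paths are stored relative to the dataset directory so the
    # dataset (incl. its manifest) is location-independent
    sheet[[cn]] <- data.frame(sample = smp, condition = cn,
                              fastq = file.path("fastq",
                                                basename(unname(sim$fastq))),
                              stringsAsFactors = FALSE)
  }
  sheet <- do.call(rbind, sheet)
  utils::write.table(sheet, file.path(out_dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- do.call(rbind, truth)
  utils::write.table(truth, file.path(out_dir, "truth_isomirs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  # UTRs with planted sites for each arm's canonical seed
  seeds <- vapply(seq_len(nrow(ref$arms)), function(i)
    seed_of(ref$arms$archetype_seq[i]), character(1))
  seeds <- seeds[!duplicated(seeds)][seq_len(min(3L, nrow(ref$arms)))]
  genes <- sprintf("g%04d", seq_len(n_genes))
  planted <- stats::setNames(
    lapply(seq_along(seeds), function(i)
      genes[seq((i - 1L) * 10L + 1L, i * 10L)]), seeds)
  utr <- simulate_utrs_genesets(n_genes, planted, utr_length = utr_length,
                                seed = .derive_seed(seed, 301L))
  ss <- Biostrings::DNAStringSet(utr$utrs)
  Biostrings::writeXStringSet(ss, file.path(out_dir, "utrs.fa"))
  write_gmt(utr$gene_sets, file.path(out_dir, "genesets.gmt"))
  utils::write.table(utr$truth, file.path(out_dir, "truth_targets.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  files <- sort(list.files(out_dir, recursive = TRUE))
  manifest <- list(seed = seed,
                   files = stats::setNames(
                     vapply(file.path(out_dir, files), function(f)
                       unname(tools::md5sum(f)), character(1)), files))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}

#' Run the full isomiR pipeline
#'
#' Stages: FASTQ preprocessing (trim, filter, collapse), ungapped
#' alignment, arm assignment, isomiR calling, RPM quantification, arm
#' aggregation, proportion tables with z-tests, differential expression
#' (Wald), three-condition trend LRT with shape classification, global
#' category homogeneity test, QC, and (unless `skip_targets`) seed
#' extraction, target prediction, overlap and enrichment.  Every table is
#' written as TSV under `config$out_dir`; per-stage read tallies go to
#' the log file and the returned object.
#'
#' @param config a [pipeline_config] with at least `hairpin_fasta`,
#'   `arm_gff3`, `sample_sheet`, `out_dir` set.
#' @return invisibly, a list with all result tables.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (k in c("hairpin_fasta", "arm_gff3", "sample_sheet", "out_dir"))
    if (is.null(config[[k]])) stop("config entry required: ", k)
  for (k in c("hairpin_fasta", "arm_gff3", "sample_sheet"))
    if (!file.exists(config[[k]])) stop("missing input file: ", config[[k]])
  if (!config$skip_targets)
    for (k in c("utr_fasta", "gmt"))
      if (!is.null(config[[k]]) && !file.exists(config[[k]]))
        stop("missing input file: ", config[[k]])
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$out_dir, "pipeline.log")
  log <- function(...) cat(..., "\n", sep = "", file = logf, append = TRUE)
  cat("", file = logf)

  hairpins <- load_hairpins(config$hairpin_fasta,
                            flank_len = config$flank_len)
  arms <- load_arm_annotations(config$arm_gff3, hairpins)
  log("reference: ", nrow(hairpins), " hairpins, ", nrow(arms), " arms")
  sheet <- utils::read.delim(config$sample_sheet, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "condition", "fastq") %in% names(sheet)))
  rel <- !file.exists(sheet$fastq)
  sheet$fastq[rel] <- file.path(dirname(config$sample_sheet),
                                sheet$fastq[rel])
  if (!all(file.exists(sheet$fastq)))
    stop("missing input file: ",
         paste(sheet$fastq[!file.exists(sheet$fastq)], collapse = ", "))
  conditions <- stats::setNames(sheet$condition, sheet$sample)

  assigned <- list(); tallies <- list(); denominators <- numeric(0)
  for (i in seq_len(nrow(sheet))) {
    smp <- sheet$sample[i]
    pre <- read_fastq_collapsed(sheet$fastq[i], config$adapter,
                                min_overlap = config$min_overlap,
                                min_len = config$min_len,
                                max_len = config$max_len,
                                min_mean_quality = config$min_mean_quality)
    al <- align_ungapped(pre$reads, hairpins,
                         max_mismatch = config$max_mismatch,
                         max_tail = config$max_tail,
                         min_templated = config$min_templated)
    as <- assign_to_arm(al$alignments, arms, al$tally,
                        max_start_offset = config$max_start_offset,
                        max_end_offset = config$max_end_offset)
    assigned[[smp]] <- as$assigned
    tally <- c(pre$tally, as$tally)
    tallies[[smp]] <- tally
    denominators[smp] <- if (isTRUE(config$strict_denominator))
      sum(as$assigned$count[as$assigned$mismatches == 0L])
    else sum(as$assigned$count)
    log("sample ", smp, ": ", paste(names(tally), tally, sep = "=",
                                    collapse = " "))
  }

  iso <- build_isomir_table(assigned, hairpins, arms,
                            max_end_offset = config$max_end_offset,
                            nta_mode = config$nta_mode)
  isomirs <- iso$isomirs
  write_isomir_table(isomirs, file.path(config$out_dir, "isomirs.tsv"))
  counts <- rpm_normalize(isomirs, samples = sheet$sample,
                          conditions = conditions,
                          denominators = denominators,
                          policy = if (isTRUE(config$strict_denominator))
                            "mismatch==0" else "mismatch<=1")
  arm_counts <- arm_abundance(counts)
  .write_matrix(counts$rpm, file.path(config$out_dir, "isomir_rpm.tsv"))
  .write_matrix(arm_counts$rpm, file.path(config$out_dir, "arm_rpm.tsv"))

  props <- proportion_table(isomirs, conditions, pooling = config$pooling)
  utils::write.table(props, file.path(config$out_dir, "proportions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  have_ab <- all(c(config$de_condition_a, config$de_condition_b) %in%
                   conditions)
  ztests <- if (have_ab)
    proportion_ztests(isomirs, conditions, config$de_condition_a,
                      config$de_condition_b)
  if (!is.null(ztests))
    utils::write.table(ztests, file.path(config$out_dir,
                                         "proportion_ztests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  de <- trend <- global_p <- NULL
  min_reps <- min(table(conditions))
  if (have_ab && min_reps >= 2 && nrow(isomirs) > 0) {
    de <- de_test(counts$raw, conditions, config$de_condition_a,
                  config$de_condition_b,
                  fc_threshold = config$fc_threshold,
                  alpha_fdr = config$alpha_fdr,
                  prior_df = config$prior_df)
    utils::write.table(de, file.path(config$out_dir, "de_isomirs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    de_arm <- de_test(arm_counts$raw, conditions, config$de_condition_a,
                      config$de_condition_b,
                      fc_threshold = config$fc_threshold,
                      alpha_fdr = config$alpha_fdr,
                      prior_df = config$prior_df)
    utils::write.table(de_arm, file.path(config$out_dir, "de_arms.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ord <- intersect(config$condition_order, unique(conditions))
    if (length(ord) == 3L) {
      trend <- lrt_trend(arm_counts$raw, conditions, cond_order = ord,
                         alpha_fdr = config$alpha_fdr,
                         prior_df = config$prior_df)
      utils::write.table(trend, file.path(config$out_dir, "trend_arms.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    ca <- .category_counts(isomirs, conditions, config$de_condition_a)
    cb <- .category_counts(isomirs, conditions, config$de_condition_b)
    global_p <- global_category_test(ca, cb)
    writeLines(paste0("global_category_p\t", format(global_p)),
               file.path(config$out_dir, "global_category_test.tsv"))
  }
  qc <- if (ncol(counts$rpm) >= 2) qc_summary(counts$rpm)
  if (!is.null(qc))
    .write_matrix(qc$correlation, file.path(config$out_dir,
                                            "qc_correlation.tsv"))

  targets <- NULL
  if (!config$skip_targets && !is.null(config$utr_fasta) &&
      !is.null(config$gmt)) {
    targets <- .target_stage(config, hairpins, arms, isomirs)
  }

  res <- list(isomirs = isomirs, out_of_range = iso$out_of_range,
              counts = counts, arm_counts = arm_counts,
              proportions = props, ztests = ztests, de = de,
              trend = trend, global_category_p = global_p, qc = qc,
              targets = targets, tallies = tallies,
              denominators = denominators, config = config)
  class(res) <- "isomirseq_results"
  invisible(res)
}

.write_matrix <- function(m, path) {
  df <- data.frame(feature = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.category_counts <- function(isomirs, conditions, cond) {
  cs <- names(conditions)[conditions == cond]
  cnts <- rowSums(as.matrix(isomirs[, cs, drop = FALSE]))
  tapply(cnts, factor(isomirs$category, levels = .categories), sum,
         default = 0)
}

.target_stage <- function(config, hairpins, arms, isomirs) {
  utrs <- Biostrings::readDNAStringSet(config$utr_fasta)
  names(utrs) <- sub("\\s.*$", "", names(utrs))
  gene_sets <- read_gmt(config$gmt)
  canon <- data.frame(accession = arms$accession, name = arms$name,
                      seed = vapply(arms$archetype_seq, seed_of,
                                    character(1)),
                      stringsAsFactors = FALSE)
  shifted <- unique(isomirs[isomirs$start_offset != 0L,
                            c("accession", "name", "label", "start_offset"),
                            drop = FALSE])
  iso_seeds <- NULL
  if (nrow(shifted)) {
    sd <- vapply(seq_len(nrow(shifted)), function(i) {
      a <- arms[arms$accession == shifted$accession[i], ]
      hp <- hairpins[hairpins$id == a$hairpin_id, ]
      up <- substr(hp$sequence, 1L, a$arm_start - 1L)
      seed_of(a$archetype_seq, shifted$start_offset[i], upstream = up)
    }, character(1))
    iso_seeds <- cbind(shifted, seed = sd, stringsAsFactors = FALSE)
  }
  collisions <- if (!is.null(iso_seeds))
    seed_collisions(iso_seeds, canon)
  query <- unique(rbind(
    data.frame(source = canon$name, seed = canon$seed,
               stringsAsFactors = FALSE),
    if (!is.null(iso_seeds))
      data.frame(source = paste(iso_seeds$name, iso_seeds$label, sep = "|"),
                 seed = iso_seeds$seed, stringsAsFactors = FALSE)))
  target_sets <- lapply(stats::setNames(query$seed, query$source),
                        predict_targets, utrs = utrs)
  overlap <- if (length(target_sets) >= 2L)
    target_overlap(target_sets[seq_len(min(3L, length(target_sets)))])
  pooled <- unique(unlist(lapply(target_sets, `[[`, "gene")))
  universe <- unique(c(unlist(gene_sets), names(utrs)))
  enr <- enrich_targets(pooled, gene_sets, universe = universe,
                        p_threshold = config$enrich_p_threshold)
  utils::write.table(enr, file.path(config$out_dir, "enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tl <- do.call(rbind, lapply(names(target_sets), function(nm)
    if (nrow(target_sets[[nm]]))
      data.frame(source = nm, target_sets[[nm]], stringsAsFactors = FALSE)))
  if (!is.null(tl))
    utils::write.table(tl, file.path(config$out_dir, "target_sets.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(collisions) && nrow(collisions))
    utils::write.table(collisions,
                       file.path(config$out_dir, "seed_collisions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  list(canonical_seeds = canon, isomir_seeds = iso_seeds,
       collisions = collisions, target_sets = target_sets,
       overlap = overlap, enrichment = enr)
}

#' @export
print.isomirseq_results <- function(x, ...) {
  cat("isomirseq pipeline results\n")
  cat("  isomiRs: ", nrow(x$isomirs), " records, ",
      length(unique(x$isomirs$accession)), " arms\n", sep = "")
  if (!is.null(x$de))
    cat("  DE isomiRs called: ", sum(x$de$called), "\n", sep = "")
  if (!is.null(x$trend))
    cat("  trend shapes: ",
        paste(names(table(x$trend$shape)), table(x$trend$shape),
              sep = "=", collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Assemble a markdown report from a pipeline output directory
#'
#' Sections: global category composition, the Table-1-style proportion
#' block with z-test p-values, DE summary, trend groups, and the
#' enrichment table.  Missing result files are noted, not fatal.
#'
#' @param results_dir directory written by [run_pipeline].
#' @param path output file (default `report.md` inside `results_dir`).
#' @return the report path, invisibly.
#' @export
write_report <- function(results_dir, path = file.path(results_dir,
                                                       "report.md")) {
  rd <- function(f) {
    fp <- file.path(results_dir, f)
    if (file.exists(fp)) utils::read.delim(fp, stringsAsFactors = FALSE,
                                           check.names = FALSE)
  }
  lines <- c("# isomiR pipeline report", "")
  iso <- rd("isomirs.tsv")
  if (is.null(iso)) {
    lines <- c(lines, "Missing artifact: isomirs.tsv")
  } else {
    smp <- setdiff(names(iso), c("accession", "name", "label",
                                 "start_offset", "end_offset", "nta",
                                 "category", "uridylated"))
    tot <- sum(iso[, smp])
    bycat <- sort(tapply(rowSums(iso[, smp, drop = FALSE]), iso$category,
                         sum), decreasing = TRUE)
    lines <- c(lines, "## IsomiR category composition (all samples)", "",
               sprintf("Total assigned reads: %d; non-canonical: %.1f%%",
                       tot, 100 * (1 - (bycat["canonical"] %||% 0) / tot)),
               "",
               sprintf("- %s: %.2f%%", names(bycat), 100 * bycat / tot), "")
  }
  props <- rd("proportions.tsv")
  if (!is.null(props)) {
    lines <- c(lines, "## Per-arm category proportions (%)", "",
               paste(names(props), collapse = " | "),
               paste(rep("---", ncol(props)), collapse = " | "),
               apply(props, 1L, function(r)
                 paste(vapply(r, function(v) {
                   vn <- suppressWarnings(as.numeric(v))
                   if (!is.na(vn) && vn != round(vn)) sprintf("%.2f", vn)
                   else as.character(v)
                 }, character(1)), collapse = " | ")), "")
  } else lines <- c(lines, "Missing artifact: proportions.tsv", "")
  de <- rd("de_isomirs.tsv")
  if (!is.null(de))
    lines <- c(lines, "## Differential expression (isomiRs)", "",
               sprintf("%d of %d isomiRs called (FDR < 0.05, FC >= 1.5): %d up, %d down",
                       sum(de$called), nrow(de),
                       sum(de$called & de$log2fc > 0),
                       sum(de$called & de$log2fc < 0)), "")
  else lines <- c(lines, "Section skipped: no DE table", "")
  trend <- rd("trend_arms.tsv")
  if (!is.null(trend)) {
    tb <- table(trend$shape)
    lines <- c(lines, "## Trend shapes (arms, Young -> SEN -> SEN+M)", "",
               sprintf("- %s: %d", names(tb), as.integer(tb)), "")
  } else lines <- c(lines, "Section skipped: no trend table", "")
  enr <- rd("enrichment.tsv")
  if (!is.null(enr)) {
    lines <- c(lines, "## Gene-set enrichment of predicted targets", "",
               paste(names(enr), collapse = " | "),
               paste(rep("---", ncol(enr)), collapse = " | "),
               apply(utils::head(enr, 15L), 1L, paste, collapse = " | "),
               "")
  } else lines <- c(lines, "Section skipped: no enrichment table", "")
  con <- file(path, "wb")
  writeLines(lines, con)
  close(con)
  invisible(path)
}
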