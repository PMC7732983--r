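#' RPM normalization, arm aggregation and category proportion tables
#'
#' IsomiR abundances are expressed in reads per million (RPM).  The
#' denominator for a sample is the number of reads that passed trimming
#' and filtering and were assigned to a miRNA arm — by default under the
#' aligner's at-most-one-mismatch policy; a strict mode restricts the
#' denominator to perfect (0-mismatch) assignments.  An arm's abundance is
#' the sum of the abundances of all its isomiRs.
#'
#' @name quantify
NULL

#' RPM-normalize an isomiR count table
#'
#' @param isomirs table from [build_isomir_table].
#' @param samples sample column names (default: all columns after the
#'   descriptor columns).
#' @param conditions optional named vector sample -> condition.
#' @param denominators per-sample totals of arm-assigned reads; default is
#'   the per-sample column sum of `isomirs` (correct when the table holds
#'   all isomiRs of all arms under the default denominator policy).
#' @param policy recorded denominator policy label.
#' @return object of class `isomir_counts`: list with `features`
#'   (descriptor columns), `raw` and `rpm` matrices, `denominators`,
#'   `conditions`, `policy`.
#' @export
rpm_normalize <- function(isomirs, samples = NULL, conditions = NULL,
                          denominators = NULL, policy = "mismatch<=1") {
  desc <- c("accession", "name", "label", "start_offset", "end_offset",
            "nta", "category", "uridylated")
  if (is.null(samples)) samples <- setdiff(names(isomirs), desc)
  raw <- as.matrix(isomirs[, samples, drop = FALSE])
  storage.mode(raw) <- "double"
  rownames(raw) <- paste(isomirs$name, isomirs$label,
                         ifelse(nzchar(isomirs$nta),
                                paste0("+", isomirs$nta), ""),
                         sep = "")
  if (is.null(denominators)) denominators <- colSums(raw)
  denominators <- denominators[samples]
  if (any(denominators <= 0))
    stop("zero RPM denominator for sample(s): ",
         paste(samples[denominators <= 0], collapse = ", "))
  rpm <- sweep(raw, 2L, denominators, "/") * 1e6
  structure(list(features = isomirs[, intersect(desc, names(isomirs)),
                                    drop = FALSE],
                 raw = raw, rpm = rpm,
                 denominators = denominators,
                 conditions = conditions, policy = policy),
            class = "isomir_counts")
}

#' @export
print.isomir_counts <- function(x, ...) {
  cat("isomir_counts: ", nrow(x$raw), " features x ", ncol(x$raw),
      " samples (denominator policy: ", x$policy, ")\n", sep = "")
  invisible(x)
}

#' Aggregate isomiR abundances to arm level
#'
#' @param counts an `isomir_counts` object from [rpm_normalize].
#' @return `isomir_counts` with one row per arm; RPM of an arm is the sum
#'   of member isomiR RPM (likewise raw counts).
#' @export
arm_abundance <- function(counts) {
  acc <- counts$features$accession
  nm <- counts$features$name[match(unique(acc), acc)]
  raw <- rowsum(counts$raw, acc, reorder = TRUE)
  rpm <- rowsum(counts$rpm, acc, reorder = TRUE)
  nm <- counts$features$name[match(rownames(raw), counts$features$accession)]
  rownames(raw) <- rownames(rpm) <- nm
  structure(list(features = data.frame(accession = sort(unique(acc)),
                                       name = nm, stringsAsFactors = FALSE),
                 raw = raw, rpm = rpm,
                 denominators = counts$denominators,
                 conditions = counts$conditions, policy = counts$policy),
            class = "isomir_counts")
}

.categories <- c("canonical", "3' addition", "3' deletion",
                 "5' addition", "5' deletion", "mixed")

#' Per-arm isomiR category proportion table
#'
#' For each arm and condition, the percentage of reads in each exclusive
#' isomiR category, plus a cross-cutting 3' uridylation percentage over
#' the same denominator.  Replicates within a condition are pooled
#' (counts summed) by default; `pooling = "average"` averages per-replicate
#' percentages instead.  Percentages are reported at full precision; round
#' to 2 decimals for display.
#'
#' @param isomirs table from [build_isomir_table].
#' @param conditions named vector sample -> condition.
#' @param pooling `"pool"` (default) or `"average"`.
#' @return object of class `proportion_table`: data.frame with columns
#'   accession, name, condition, total, one column per category, and
#'   `uridylation`; arms with zero reads in a condition carry NA
#'   percentages.
#' @export
proportion_table <- function(isomirs, conditions, pooling = c("pool", "average")) {
  pooling <- match.arg(pooling)
  samples <- names(conditions)
  stopifnot(all(samples %in% names(isomirs)))
  conds <- unique(unname(conditions))
  arms <- unique(isomirs[, c("accession", "name")])
  out <- list()
  for (i in seq_len(nrow(arms))) {
    sel <- isomirs$accession == arms$accession[i]
    for (cn in conds) {
      cs <- samples[conditions == cn]
      mat <- as.matrix(isomirs[sel, cs, drop = FALSE])
      catf <- factor(isomirs$category[sel], levels = .categories)
      urid <- isomirs$uridylated[sel]
      if (pooling == "pool") {
        cnts <- rowSums(mat)
        tot <- sum(cnts)
        pc <- if (tot > 0)
          100 * tapply(cnts, catf, sum, default = 0) / tot
        else stats::setNames(rep(NA_real_, length(.categories)), .categories)
        up <- if (tot > 0) 100 * sum(cnts[urid]) / tot else NA_real_
      } else {
        per <- apply(mat, 2L, function(v) {
          t1 <- sum(v)
          if (t1 == 0) rep(NA_real_, length(.categories) + 1L)
          else c(100 * tapply(v, catf, sum, default = 0) / t1,
                 100 * sum(v[urid]) / t1)
        })
        m <- rowMeans(per, na.rm = TRUE)
        pc <- m[seq_along(.categories)]
        up <- m[length(.categories) + 1L]
        tot <- sum(mat)
      }
      row <- data.frame(accession = arms$accession[i], name = arms$name[i],
                        condition = cn, total = tot,
                        stringsAsFactors = FALSE)
      for (k in seq_along(.categories)) row[[.categories[k]]] <- unname(pc[k])
      row$uridylation <- unname(up)
      out[[length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("proportion_table", "data.frame")
  res
}

#' Two-proportion z-tests on a proportion table
#'
#' For every arm and category (and uridylation), tests the difference in
#' category proportion between two conditions using the pooled
#' two-proportion z statistic on the underlying counts.  Reported
#' unadjusted, as is conventional for per-arm proportion comparisons.
#'
#' @param isomirs table from [build_isomir_table].
#' @param conditions named vector sample -> condition.
#' @param cond_a,cond_b the two conditions to compare.
#' @return data.frame: accession, name, category (incl. "uridylation"),
#'   proportions and p-value.
#' @export
proportion_ztests <- function(isomirs, conditions, cond_a, cond_b) {
  samples <- names(conditions)
  sa <- samples[conditions == cond_a]
  sb <- samples[conditions == cond_b]
  arms <- unique(isomirs[, c("accession", "name")])
  out <- list()
  for (i in seq_len(nrow(arms))) {
    sel <- isomirs$accession == arms$accession[i]
    ca <- rowSums(as.matrix(isomirs[sel, sa, drop = FALSE]))
    cb <- rowSums(as.matrix(isomirs[sel, sb, drop = FALSE]))
    na <- sum(ca); nb <- sum(cb)
    if (na == 0 || nb == 0) next
    catf <- isomirs$category[sel]
    groups <- c(as.list(stats::setNames(.categories, .categories)),
                list(uridylation = NULL))
    for (g in names(groups)) {
      ing <- if (g == "uridylation") isomirs$uridylated[sel] else catf == g
      xa <- sum(ca[ing]); xb <- sum(cb[ing])
      if (xa + xb == 0) next
      out[[length(out) + 1L]] <- data.frame(
        accession = arms$accession[i], name = arms$name[i], category = g,
        prop_a = 100 * xa / na, prop_b = 100 * xb / nb,
        p = ztest_proportions(xa, na, xb, nb), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(accession = character(), name = character(),
                      category = character(), prop_a = numeric(),
                      prop_b = numeric(), p = numeric())
  rownames(res) <- NULL
  res
}

#' Population doublings
#'
#' PD for one passage from final (`final_count`) and seeded
#' (`initial_count`) cell numbers: `(log10(F) - log10(I)) / log10(2)`.
#' Cumulative PD is the running sum over passages.
#'
#' @param final_count,initial_count positive cell counts (vectorized).
#' @return PD values.
#' @export
population_doublings <- function(final_count, initial_count) {
  if (any(final_count <= 0) || any(initial_count <= 0))
    stop("cell counts must be positive")
  (log10(final_count) - log10(initial_count)) / log10(2)
}

#' Cumulative population doublings over passages
#' @param final_counts,initial_counts per-passage cell counts.
#' @return running cumulative PD.
#' @export
cumulative_pd <- function(final_counts, initial_counts) {
  cumsum(population_doublings(final_counts, initial_counts))
}
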