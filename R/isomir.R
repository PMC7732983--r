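#' IsomiR nomenclature, tail resolution and classification
#'
#' An isomiR is described relative to its arm's archetype (the database
#' sequence) by two signed offsets and a non-templated tail.  The label
#' "s|e" writes the 5' and templated-3' offsets with explicit signs
#' (positive = shifted toward the hairpin 3' end); the archetype is "0|0".
#' Categories follow the six-way scheme: canonical, 3' deletion,
#' 3' addition, 5' deletion, 5' addition, and mixed.  A tail consisting
#' only of uridines marks the record as uridylated.
#'
#' @name isomir-call
NULL

#' Format an offset pair as an isomiR label
#' @param start_offset,end_offset signed integer offsets.
#' @return character labels like `"0|0"`, `"+1|-2"`.
#' @export
isomir_label <- function(start_offset, end_offset) {
  f <- function(x) ifelse(x > 0, paste0("+", x), as.character(x))
  paste0(f(start_offset), "|", f(end_offset))
}

#' Parse an isomiR label back into offsets
#' @param label labels as produced by [isomir_label].
#' @return data.frame with `start_offset`, `end_offset`.
#' @export
parse_isomir_label <- function(label) {
  parts <- strsplit(label, "|", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) stop("malformed isomiR label: ", label[bad][1L])
  data.frame(start_offset = as.integer(vapply(parts, `[`, "", 1L)),
             end_offset = as.integer(vapply(parts, `[`, "", 2L)))
}

#' Split an aligned 3' tail into templated extension and non-templated tail
#'
#' Maximal-prefix rule: the longest prefix of the tail that continues the
#' reference sequence beyond the templated end is absorbed as additional
#' templated 3' extension; the remaining suffix is the non-templated
#' addition (NTA).  If the available reference continuation runs out, the
#' remainder is NTA by definition.
#'
#' @param tail candidate tail (DNA or RNA alphabet; U treated as T).
#' @param continuation reference bases immediately downstream of the
#'   templated 3' end (hairpin remainder + genomic flank).
#' @return list with `extra_templated` (integer) and `nta` (string, DNA
#'   alphabet).
#' @export
resolve_tail <- function(tail, continuation) {
  tail <- .normalize_seq(tail)
  continuation <- .normalize_seq(continuation)
  n <- min(nchar(tail), nchar(continuation))
  k <- 0L
  while (k < n &&
         substr(tail, k + 1L, k + 1L) == substr(continuation, k + 1L, k + 1L))
    k <- k + 1L
  list(extra_templated = k, nta = substr(tail, k + 1L, nchar(tail)))
}

#' Classify an isomiR by its offsets and non-templated tail
#'
#' Six exclusive categories: `canonical` (0, 0, no tail), `5' deletion`
#' (positive 5' offset only), `5' addition` (negative 5' offset only),
#' `3' deletion` (negative 3' offset only), `3' addition` (positive 3'
#' offset only), and `mixed` (both ends modified, or an NTA co-occurring
#' with a templated 3' change or any 5' change).  A pure-NTA record
#' (offsets 0|0, non-empty tail) is reported as `3' addition` by default
#' (`nta_mode = "3p_addition"`); `nta_mode = "own"` gives it its own
#' `nta` category instead.
#'
#' @param start_offset,end_offset signed offsets.
#' @param nta non-templated tail strings ("" for none).
#' @param nta_mode where pure-NTA records are counted.
#' @return character vector of categories.
#' @export
classify_isomir <- function(start_offset, end_offset, nta,
                            nta_mode = c("3p_addition", "own")) {
  nta_mode <- match.arg(nta_mode)
  has_nta <- nzchar(nta)
  n <- length(start_offset)
  cat <- character(n)
  five_mod <- start_offset != 0L
  three_templ <- end_offset != 0L
  mixed <- (five_mod & (three_templ | has_nta)) |
    (five_mod & three_templ) | (has_nta & three_templ)
  pure_nta <- !five_mod & !three_templ & has_nta
  cat[mixed] <- "mixed"
  cat[!mixed & five_mod & start_offset > 0L] <- "5' deletion"
  cat[!mixed & five_mod & start_offset < 0L] <- "5' addition"
  cat[!mixed & !five_mod & three_templ & end_offset < 0L] <- "3' deletion"
  cat[!mixed & !five_mod & three_templ & end_offset > 0L] <- "3' addition"
  cat[pure_nta] <- if (nta_mode == "own") "nta" else "3' addition"
  cat[!five_mod & !three_templ & !has_nta] <- "canonical"
  cat
}

#' Is a tail a uridylation?
#' @param nta non-templated tail strings.
#' @return logical: non-empty and composed only of U (T).
#' @export
is_uridylated <- function(nta) {
  nta <- .normalize_seq(nta)
  nzchar(nta) & grepl("^T+$", nta)
}

#' Build the per-sample isomiR table from arm-assigned alignments
#'
#' One record per distinct (arm, 5' offset, templated 3' offset, NTA),
#' with per-sample summed counts, label, category and uridylation flag.
#' The aligner's tail is re-resolved against the reference continuation so
#' templated 3' extensions are absorbed before NTA is called.
#'
#' @param assigned_by_sample named list (sample -> `assigned` data.frame
#'   from [assign_to_arm]).
#' @param hairpins a [hairpin_set] (for tail resolution context).
#' @param arms an [arm_set].
#' @param max_end_offset cap on the templated 3' offset after tail
#'   resolution (default 6); beyond-cap records go to the out-of-range
#'   bucket.
#' @param nta_mode passed to [classify_isomir].
#' @return list with `isomirs` (data.frame: accession, name, label,
#'   start_offset, end_offset, nta, category, uridylated, then one count
#'   column per sample, ordered by accession then label) and
#'   `out_of_range` (same shape, records whose resolved 3' offset broke
#'   the cap).
#' @export
build_isomir_table <- function(assigned_by_sample, hairpins, arms,
                               max_end_offset = 6L,
                               nta_mode = "3p_addition") {
  samples <- names(assigned_by_sample)
  stopifnot(!is.null(samples), all(nzchar(samples)))
  ext <- stats::setNames(.extended_seq(hairpins), hairpins$id)
  recs <- list()
  for (s in samples) {
    a <- assigned_by_sample[[s]]
    if (!nrow(a)) next
    e <- ext[a$hairpin_id]
    tmpl_end <- a$start + a$templated_len - 1L
    for (r in seq_len(nrow(a))) {
      cont <- substr(e[r], tmpl_end[r] + 1L, nchar(e[r]))
      rt <- resolve_tail(a$tail[r], cont)
      so <- a$start_offset[r]
      eo <- a$end_offset[r] + rt$extra_templated
      key <- paste(a$accession[r], so, eo, rt$nta, sep = "\r")
      if (is.null(recs[[key]])) {
        recs[[key]] <- list(accession = a$accession[r], name = a$name[r],
                            start_offset = so, end_offset = eo,
                            nta = rt$nta,
                            counts = stats::setNames(rep(0L, length(samples)),
                                                     samples))
      }
      recs[[key]]$counts[s] <- recs[[key]]$counts[s] + a$count[r]
    }
  }
  if (!length(recs)) {
    empty <- data.frame(accession = character(), name = character(),
                        label = character(), start_offset = integer(),
                        end_offset = integer(), nta = character(),
                        category = character(), uridylated = logical(),
                        stringsAsFactors = FALSE)
    for (s in samples) empty[[s]] <- integer()
    return(list(isomirs = empty, out_of_range = empty))
  }
  tab <- data.frame(
    accession = vapply(recs, `[[`, "", "accession"),
    name = vapply(recs, `[[`, "", "name"),
    start_offset = vapply(recs, `[[`, 0L, "start_offset"),
    end_offset = vapply(recs, `[[`, 0L, "end_offset"),
    nta = vapply(recs, `[[`, "", "nta"),
    stringsAsFactors = FALSE)
  tab$label <- isomir_label(tab$start_offset, tab$end_offset)
  tab$category <- classify_isomir(tab$start_offset, tab$end_offset, tab$nta,
                                  nta_mode = nta_mode)
  tab$uridylated <- is_uridylated(tab$nta)
  cm <- do.call(rbind, lapply(recs, `[[`, "counts"))
  for (s in samples) tab[[s]] <- as.integer(cm[, s])
  tab <- tab[, c("accession", "name", "label", "start_offset", "end_offset",
                 "nta", "category", "uridylated", samples)]
  in_range <- abs(tab$end_offset) <= max_end_offset
  out <- tab[!in_range, , drop = FALSE]
  tab <- tab[in_range, , drop = FALSE]
  ord <- order(tab$accession, tab$label, tab$nta)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- rownames(out) <- NULL
  if (nrow(out))
    message(nrow(out), " isomiR record(s) beyond the 3' offset cap (",
            max_end_offset, ") routed out of range")
  list(isomirs = tab, out_of_range = out)
}

#' Write an isomiR table to TSV
#' @param isomirs table from [build_isomir_table].
#' @param path output path.
#' @export
write_isomir_table <- function(isomirs, path) {
  utils::write.table(isomirs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
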