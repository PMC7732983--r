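#' Hairpin precursor references and mature-arm annotations
#'
#' A hairpin reference ties a precursor sequence to its genomic origin and
#' carries a short stretch of downstream genomic sequence ("3' flank").  The
#' flank is what lets the isomiR caller distinguish a templated 3' extension
#' (the added bases continue the genome) from a non-templated addition (they
#' do not).  Sequences are stored uppercase with U normalized to T so that
#' all comparison logic runs in DNA space; the original alphabet (RNA or
#' DNA) is remembered so outputs can be reported as the input was given.
#'
#' @name reference-model
NULL

.normalize_seq <- function(x) {
  x <- toupper(x)
  chartr("U", "T", x)
}

#' Construct a set of hairpin references
#'
#' @param id character vector of hairpin identifiers (unique).
#' @param sequence precursor sequences, A/C/G/T/U any case.
#' @param flank3 downstream genomic sequence in mature (5'->3') orientation,
#'   one per hairpin; alphabet ACGTN after U->T normalization.
#' @param chrom,strand,start,end optional genomic coordinates (1-based
#'   inclusive, strand "+" or "-"); defaults describe an unplaced reference.
#' @param flank_len required flank length; every `flank3` must have exactly
#'   this many bases.  Must exceed the maximum 3' extension the isomiR
#'   caller will probe (default caps need at least 7).
#' @return data.frame of class `hairpin_set` with one row per hairpin.
#' @export
hairpin_set <- function(id, sequence, flank3,
                        chrom = NA_character_, strand = "+",
                        start = NA_integer_, end = NA_integer_,
                        flank_len = 10L) {
  id <- as.character(id)
  if (anyDuplicated(id))
    stop("duplicate hairpin IDs: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  alphabet <- ifelse(grepl("U", toupper(sequence), fixed = TRUE), "RNA", "DNA")
  sequence <- .normalize_seq(sequence)
  flank3 <- .normalize_seq(flank3)
  if (any(bad <- !grepl("^[ACGTN]*$", sequence)))
    stop("non-ACGTN characters in hairpin sequence: ",
         paste(id[bad], collapse = ", "))
  if (any(bad <- nchar(flank3) != flank_len))
    stop("flank3 length != ", flank_len, " for: ",
         paste(id[bad], collapse = ", "))
  if (any(bad <- !grepl("^[ACGTN]*$", flank3)))
    stop("non-ACGTN characters in flank3: ", paste(id[bad], collapse = ", "))
  start <- as.integer(start)
  end <- as.integer(end)
  placed <- !is.na(start) & !is.na(end)
  if (any(bad <- placed & (end - start + 1L) != nchar(sequence)))
    stop("genomic span does not match sequence length for: ",
         paste(id[bad], collapse = ", "))
  hp <- data.frame(id = id, sequence = sequence, flank3 = flank3,
                   chrom = chrom, strand = strand, start = start, end = end,
                   alphabet = alphabet, stringsAsFactors = FALSE)
  attr(hp, "flank_len") <- as.integer(flank_len)
  class(hp) <- c("hairpin_set", "data.frame")
  hp
}

#' Load hairpin references from FASTA
#'
#' Two flank sources are supported: pre-extended records (the last
#' `flank_len` bases of each FASTA record are the genomic flank and are
#' split off), or a genome FASTA plus a coordinate table from which the
#' downstream flank is extracted (reverse-complemented on the minus
#' strand so hairpin and flank are always stored in mature orientation).
#'
#' @param fasta_path path to hairpin FASTA (records may be RNA or DNA).
#' @param flank_source either `"extended"` (default) or a list
#'   `list(genome = <fasta path>, coords = <data.frame id/chrom/strand/start/end>)`.
#' @param flank_len flank length F (default 10).
#' @return a [hairpin_set].
#' @export
load_hairpins <- function(fasta_path, flank_source = "extended",
                          flank_len = 10L) {
  seqs <- tryCatch(Biostrings::readBStringSet(fasta_path),
                   error = function(e)
                     stop("malformed FASTA '", fasta_path, "': ",
                          conditionMessage(e)))
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicate hairpin IDs in ", fasta_path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  raw <- as.character(seqs)
  if (identical(flank_source, "extended")) {
    if (any(bad <- nchar(raw) <= flank_len))
      stop("records shorter than flank_len, cannot split flank: ",
           paste(ids[bad], collapse = ", "))
    body <- substr(raw, 1L, nchar(raw) - flank_len)
    flank <- substr(raw, nchar(raw) - flank_len + 1L, nchar(raw))
    hairpin_set(ids, body, flank, flank_len = flank_len)
  } else {
    genome <- Biostrings::readDNAStringSet(flank_source$genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
    co <- flank_source$coords
    miss <- setdiff(ids, co$id)
    if (length(miss))
      stop("missing flank coordinates for hairpins: ",
           paste(miss, collapse = ", "))
    co <- co[match(ids, co$id), ]
    flank <- vapply(seq_along(ids), function(i) {
      chr <- genome[[as.character(co$chrom[i])]]
      if (is.null(chr)) stop("chromosome not in genome FASTA: ", co$chrom[i])
      if (co$strand[i] == "+") {
        fl <- Biostrings::subseq(chr, co$end[i] + 1L, co$end[i] + flank_len)
        as.character(fl)
      } else {
        fl <- Biostrings::subseq(chr, co$start[i] - flank_len, co$start[i] - 1L)
        as.character(Biostrings::reverseComplement(fl))
      }
    }, character(1))
    hairpin_set(ids, raw, flank, chrom = co$chrom, strand = co$strand,
                start = co$start, end = co$end, flank_len = flank_len)
  }
}

#' Write hairpins back to (flank-extended) FASTA
#'
#' The inverse of [load_hairpins] with `flank_source = "extended"`: each
#' record is sequence + flank3, in the record's original alphabet.
#' @param hairpins a [hairpin_set].
#' @param path output FASTA path.
#' @export
write_hairpins <- function(hairpins, path) {
  x <- paste0(hairpins$sequence, hairpins$flank3)
  rna <- hairpins$alphabet == "RNA"
  x[rna] <- chartr("T", "U", x[rna])
  ss <- Biostrings::BStringSet(x)
  names(ss) <- hairpins$id
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Construct mature-arm annotations
#'
#' @param name mature arm names (e.g. "miR-217-5p").
#' @param accession MIMAT-style accession IDs, unique across the set.
#' @param hairpin_id parent hairpin id, present in `hairpins`.
#' @param arm_start,arm_end 1-based inclusive positions within the hairpin.
#' @param hairpins the [hairpin_set] the arms live on.
#' @return data.frame of class `arm_set`; `archetype_seq` is extracted from
#'   the hairpin sequence.
#' @export
arm_set <- function(name, accession, hairpin_id, arm_start, arm_end,
                    hairpins) {
  accession <- as.character(accession)
  if (anyDuplicated(accession))
    stop("duplicate arm accessions: ",
         paste(unique(accession[duplicated(accession)]), collapse = ", "))
  hairpin_id <- as.character(hairpin_id)
  miss <- setdiff(hairpin_id, hairpins$id)
  if (length(miss))
    stop("arms reference unknown hairpins: ", paste(miss, collapse = ", "))
  i <- match(hairpin_id, hairpins$id)
  arm_start <- as.integer(arm_start)
  arm_end <- as.integer(arm_end)
  hl <- nchar(hairpins$sequence)[i]
  bad <- arm_start < 1L | arm_start >= arm_end | arm_end > hl
  if (any(bad))
    stop("arm coordinates outside hairpin bounds (1-based inclusive): ",
         paste(name[bad], collapse = ", "))
  arms <- data.frame(
    name = as.character(name), accession = accession,
    hairpin_id = hairpin_id, arm_start = arm_start, arm_end = arm_end,
    archetype_seq = substr(hairpins$sequence[i], arm_start, arm_end),
    stringsAsFactors = FALSE)
  class(arms) <- c("arm_set", "data.frame")
  arms
}

#' Load mature-arm annotations from a miRBase-dialect GFF3
#'
#' Expects `miRNA` features whose seqid names a loaded hairpin and whose
#' coordinates are 1-based inclusive positions *within* that hairpin, with
#' `ID=` (accession) and `Name=` attributes.
#'
#' @param gff3_path path to the GFF3 file.
#' @param hairpins a [hairpin_set] providing the parent sequences.
#' @return an [arm_set].
#' @export
load_arm_annotations <- function(gff3_path, hairpins) {
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  gr <- gr[as.character(gr$type) == "miRNA"]
  if (!length(gr)) stop("no miRNA features in ", gff3_path)
  md <- S4Vectors::mcols(gr)
  if (is.null(md$ID) || is.null(md$Name))
    stop("miRNA features must carry ID and Name attributes")
  arms <- arm_set(name = as.character(md$Name),
                  accession = as.character(md$ID),
                  hairpin_id = as.character(GenomicRanges::seqnames(gr)),
                  arm_start = GenomicRanges::start(gr),
                  arm_end = GenomicRanges::end(gr),
                  hairpins = hairpins)
  message(nrow(arms), " mature arms loaded from ", gff3_path)
  arms
}

#' Write arm annotations to miRBase-dialect GFF3
#' @param arms an [arm_set].
#' @param path output path.
#' @export
write_arm_annotations <- function(arms, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = arms$hairpin_id,
    ranges = IRanges::IRanges(arms$arm_start, arms$arm_end),
    strand = "+")
  gr$type <- "miRNA"
  gr$source <- "isomirseq"
  gr$ID <- arms$accession
  gr$Name <- arms$name
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

.extended_seq <- function(hairpins) {
  paste0(hairpins$sequence, hairpins$flank3)
}
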