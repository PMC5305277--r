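#' Read aligned reads from a SAM file
#'
#' Reads primary, mapped alignments from a SAM file and lays each read's
#' sequence out in reference space (insertions removed, deletions gapped),
#' so that the base aligned to any reference position can be looked up
#' directly. Secondary, supplementary and unmapped records are dropped.
#'
#' @param path Path to a SAM file.
#' @return A data frame of class `aligned_reads` with columns `read_id`,
#'   `chrom`, `start`, `end` and `ref_seq` (reference-space sequence;
#'   `-` marks a deletion). Empty (with a warning) when the file contains
#'   no mapped primary alignments.
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop("SAM file not found: ", path)
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(what = c("qname", "seq"), flag = flag)
  ga <- GenomicAlignments::readGAlignments(bam, param = param)
  if (length(ga) == 0L) {
    warning("no mapped primary alignments in ", path)
    return(empty_aligned_reads())
  }
  laid <- GenomicAlignments::sequenceLayer(
    S4Vectors::mcols(ga)$seq, GenomicAlignments::cigar(ga),
    from = "query", to = "reference")
  out <- data.frame(
    read_id = S4Vectors::mcols(ga)$qname,
    chrom = as.character(GenomicAlignments::seqnames(ga)),
    start = GenomicAlignments::start(ga),
    end = GenomicAlignments::end(ga),
    ref_seq = as.character(laid),
    stringsAsFactors = FALSE)
  class(out) <- c("aligned_reads", "data.frame")
  out
}

empty_aligned_reads <- function() {
  out <- data.frame(read_id = character(0), chrom = character(0),
                    start = integer(0), end = integer(0),
                    ref_seq = character(0), stringsAsFactors = FALSE)
  class(out) <- c("aligned_reads", "data.frame")
  out
}

# base aligned at reference position `pos` for every read; NA when the
# read does not cover the position or a deletion spans it
base_at <- function(reads, chrom, pos) {
  b <- rep(NA_character_, nrow(reads))
  covered <- reads$chrom == chrom & reads$start <= pos & reads$end >= pos
  b[covered] <- substr(reads$ref_seq[covered],
                       pos - reads$start[covered] + 1L,
                       pos - reads$start[covered] + 1L)
  b[!is.na(b) & (b == "-" | b == "." | b == "")] <- NA_character_
  b
}
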