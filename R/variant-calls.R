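#' Variant-call tables
#'
#' Variant calls are held in a data frame of class `snv_calls`, one row per
#' called site, with list columns for the per-record vectors:
#' \describe{
#'   \item{chrom, pos}{1-based genomic position.}
#'   \item{ref}{Reference allele (uppercase).}
#'   \item{alt}{List column: character vector of alternate alleles (may be
#'     empty for confident homozygous-reference calls).}
#'   \item{gt}{Genotype string of allele indices, e.g. `"0/1"` (0 = ref).}
#'   \item{ad}{List column: integer allelic depths, reference first, one
#'     per allele.}
#'   \item{fs, qd}{Fisher strand (phred-scaled strand bias) and quality by
#'     depth; `NA` means the statistic was absent, never zero.}
#'   \item{filter}{Upstream filter field; `""` or `"PASS"` means passing.}
#'   \item{ann}{List column: annotation data frame from
#'     [parse_annotation()].}
#' }
#'
#' @param chrom,pos Position of the call.
#' @param ref Reference allele.
#' @param alt Character vector of alternate alleles (default none: a
#'   homozygous-reference call).
#' @param gt Genotype string (default `"0/0"`).
#' @param ad Integer allelic depths, reference first.
#' @param fs,qd Site statistics (`NA` = absent).
#' @param filter Filter field string.
#' @param ann Annotation data frame (see [parse_annotation()]).
#' @return A one-row `snv_calls` data frame.
#' @export
#' @examples
#' variant_call("chr12", 25398284, "C", "A", gt = "0/1", ad = c(12L, 8L),
#'              fs = 3, qd = 11.2)
variant_call <- function(chrom, pos, ref, alt = character(0), gt = "0/0",
                         ad = NULL, fs = NA_real_, qd = NA_real_,
                         filter = "PASS", ann = empty_annotation()) {
  if (is.null(ad)) ad <- rep(10L, 1L + length(alt))
  stopifnot(length(ad) == 1L + length(alt))
  new_snv_calls(data.frame(
    chrom = chrom, pos = as.integer(pos), ref = ref,
    alt = I(list(as.character(alt))), gt = gt,
    ad = I(list(as.integer(ad))), fs = as.numeric(fs), qd = as.numeric(qd),
    filter = filter, ann = I(list(ann)), stringsAsFactors = FALSE))
}

new_snv_calls <- function(df) {
  class(df) <- c("snv_calls", "data.frame")
  df
}

#' Combine variant-call tables
#'
#' @param ... `snv_calls` data frames (or a single list of them).
#' @return A single `snv_calls` data frame, rows in input order.
#' @export
bind_calls <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]]) && !is.data.frame(parts[[1]]))
    parts <- parts[[1]]
  new_snv_calls(do.call(rbind, c(parts, list(make.row.names = FALSE))))
}

empty_calls <- function() {
  new_snv_calls(data.frame(
    chrom = character(0), pos = integer(0), ref = character(0),
    alt = I(list()), gt = character(0), ad = I(list()),
    fs = numeric(0), qd = numeric(0), filter = character(0),
    ann = I(list()), stringsAsFactors = FALSE))
}

# indices (0-based) of the called alleles, e.g. "0/1" -> c(0L, 1L)
gt_indices <- function(gt) {
  idx <- suppressWarnings(as.integer(strsplit(gt, "[/|]")[[1]]))
  idx[!is.na(idx)]
}

# bases of the alleles called in row i (duplicates kept: "1/1" -> two copies)
called_alleles <- function(calls, i) {
  alleles <- c(calls$ref[i], calls$alt[[i]])
  idx <- gt_indices(calls$gt[i])
  idx <- idx[idx < length(alleles)]
  alleles[idx + 1L]
}

has_alt <- function(calls) lengths(calls$alt) > 0L

# SNV: single-base ACGT reference and every alternate allele single-base ACGT
is_snv_call <- function(calls) {
  ref_ok <- is_single_base(calls$ref)
  alt_ok <- vapply(calls$alt, function(a) all(is_single_base(a)), logical(1))
  ref_ok & alt_ok
}

total_depth <- function(calls) {
  vapply(calls$ad, function(d) sum(d, na.rm = TRUE), numeric(1))
}

#' @export
print.snv_calls <- function(x, ...) {
  cat("<snv_calls> ", nrow(x), " call(s)\n", sep = "")
  if (nrow(x) > 0) {
    show <- utils::head(data.frame(
      chrom = x$chrom, pos = x$pos, ref = x$ref,
      alt = vapply(x$alt, paste, character(1), collapse = ","),
      gt = x$gt,
      ad = vapply(x$ad, paste, character(1), collapse = ","),
      fs = x$fs, qd = x$qd, filter = x$filter,
      stringsAsFactors = FALSE), 10L)
    print(show, row.names = FALSE)
    if (nrow(x) > 10) cat("... and ", nrow(x) - 10L, " more\n", sep = "")
  }
  invisible(x)
}
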