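#' Read variant calls from a VCF file
#'
#' Reads a VCF 4.x file (as produced by a GATK HaplotypeCaller + SnpEff
#' style upstream) into an [`snv_calls`][variant_call] table. Per-sample
#' `GT` and `AD` fields are required per record; the `FS`, `QD` and `ANN`
#' INFO fields are optional and, when absent, are represented as `NA` /
#' empty annotation — never as numeric defaults.
#'
#' @param path Path to a VCF file (plain text).
#' @param include_hom_ref Keep records without alternate alleles (confident
#'   homozygous-reference calls)? Default `FALSE`.
#' @param sample Sample name to extract from a multi-sample VCF; default
#'   the first sample.
#' @param strict If `TRUE`, a record whose `AD` arity does not match its
#'   allele count is an error; if `FALSE` (default) such records are
#'   skipped with a warning and counted in the `"skipped"` attribute.
#' @return An `snv_calls` data frame in file order, with attribute
#'   `skipped` (number of records dropped for malformed per-record data).
#' @export
read_vcf <- function(path, include_hom_ref = FALSE, sample = NULL,
                     strict = FALSE) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  if (length(body)) {
    nfields <- vapply(strsplit(lines[body], "\t", fixed = TRUE),
                      length, integer(1))
    bad <- body[nfields < 8L]
    if (length(bad))
      stop("malformed VCF line ", bad[1], ": fewer than 8 tab-separated fields")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  n <- nrow(v@fix)
  if (is.null(n) || n == 0L) return(empty_calls())

  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))  # single-record files come back as a bare vector
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  samples <- colnames(v@gt)[-1]
  if (is.null(sample)) sample <- samples[1]
  if (!sample %in% samples) stop("sample '", sample, "' not present in VCF")

  gt <- vcfR::extract.gt(v, element = "GT", as.numeric = FALSE)[, sample]
  ad <- vcfR::extract.gt(v, element = "AD", as.numeric = FALSE)[, sample]
  fs <- suppressWarnings(vcfR::extract.info(v, element = "FS", as.numeric = TRUE))
  qd <- suppressWarnings(vcfR::extract.info(v, element = "QD", as.numeric = TRUE))
  ann <- vcfR::extract.info(v, element = "ANN")

  alt_list <- unname(lapply(fix[, "ALT"], function(a) {
    if (is.na(a) || a %in% c(".", "")) character(0)
    else strsplit(a, ",", fixed = TRUE)[[1]]
  }))
  ad_list <- unname(lapply(ad, function(a) {
    if (is.na(a)) integer(0) else as.integer(strsplit(a, ",", fixed = TRUE)[[1]])
  }))
  filt <- fix[, "FILTER"]
  filt[is.na(filt) | filt == "."] <- ""

  keep <- rep(TRUE, n)
  skipped <- 0L
  for (i in seq_len(n)) {
    if (length(ad_list[[i]]) != 1L + length(alt_list[[i]])) {
      msg <- sprintf(
        "record %d (%s:%s): AD arity %d inconsistent with %d allele(s)",
        i, fix[i, "CHROM"], fix[i, "POS"],
        length(ad_list[[i]]), 1L + length(alt_list[[i]]))
      if (strict) stop(msg)
      warning("skipping ", msg)
      keep[i] <- FALSE
      skipped <- skipped + 1L
    }
  }
  if (!include_hom_ref) keep <- keep & lengths(alt_list) > 0L

  out <- new_snv_calls(data.frame(
    chrom = unname(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]),
    ref = unname(fix[, "REF"]),
    alt = I(alt_list),
    gt = unname(ifelse(is.na(gt), "0/0", gt)),
    ad = I(ad_list),
    fs = as.numeric(fs),
    qd = as.numeric(qd),
    filter = unname(filt),
    ann = I(unname(lapply(ann, parse_annotation))),
    stringsAsFactors = FALSE))
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
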