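#' Two-site haplotype analysis of aligned reads
#'
#' Reads spanning two proximal single-base variant sites (e.g. KRAS
#' codons 12 and 13) are classified into joint-allele categories
#' (wild type / mutant at each site), giving a read-level view of which
#' allele combinations are expressed.
#'
#' @param label Site label (e.g. `"codon12"`).
#' @param chrom,pos Genomic position of the site.
#' @param wt,mut Wild-type and mutant base (single distinct ACGT bases).
#' @return An object of class `haplotype_site`.
#' @export
haplotype_site <- function(label, chrom, pos, wt, mut) {
  stopifnot(is_single_base(wt), is_single_base(mut), wt != mut, pos >= 1)
  structure(list(label = label, chrom = chrom, pos = as.integer(pos),
                 wt = wt, mut = mut),
            class = "haplotype_site")
}

HAP_CATEGORIES <- c("wt/wt", "wt/mut", "mut/wt", "mut/mut")

# state of base b at a site: "wt", "mut", "other", or NA (not covered)
site_state <- function(b, site) {
  s <- rep(NA_character_, length(b))
  s[!is.na(b) & b == site$wt] <- "wt"
  s[!is.na(b) & b == site$mut] <- "mut"
  s[!is.na(b) & b != site$wt & b != site$mut] <- "other"
  s
}

classify_reads <- function(reads, siteA, siteB) {
  if (siteA$chrom != siteB$chrom)
    stop("haplotype sites must lie on the same chromosome")
  if (siteA$pos == siteB$pos)
    stop("haplotype sites must have distinct positions")
  a <- site_state(base_at(reads, siteA$chrom, siteA$pos), siteA)
  b <- site_state(base_at(reads, siteB$chrom, siteB$pos), siteB)
  out <- rep("uninformative", nrow(reads))
  covered <- !is.na(a) & !is.na(b)
  other <- covered & (a == "other" | b == "other")
  out[other] <- "other"
  clean <- covered & !other
  out[clean] <- paste(a[clean], b[clean], sep = "/")
  out
}

#' Classify one aligned read at two variant sites
#'
#' A read is uninformative unless it covers both positions with an
#' aligned base; a base matching neither the wild-type nor the mutant
#' allele at either site (including `N`) makes the read `"other"`;
#' otherwise the category is the ordered pair of states, e.g.
#' `"wt/mut"`.
#'
#' @param read A one-row [`aligned_reads`][read_alignments] data frame.
#' @param siteA,siteB [haplotype_site()] objects on the same chromosome.
#' @return One of `"wt/wt"`, `"wt/mut"`, `"mut/wt"`, `"mut/mut"`,
#'   `"other"`, `"uninformative"`.
#' @export
classify_read <- function(read, siteA, siteB) {
  stopifnot(nrow(read) == 1L)
  classify_reads(read, siteA, siteB)
}

#' Construct a haplotype tally from counts
#'
#' @param replicate_id Replicate label.
#' @param wt_wt,wt_mut,mut_wt,mut_mut Read counts per joint-allele
#'   category.
#' @param other Reads carrying a third base at either site; tracked, but
#'   excluded from `total`, which counts informative reads over the four
#'   joint-allele categories only.
#' @return A one-row data frame of class `haplotype_tally`.
#' @export
haplotype_tally <- function(replicate_id, wt_wt, wt_mut, mut_wt,
                            mut_mut = 0L, other = 0L) {
  df <- data.frame(replicate_id = replicate_id,
                   wt_wt = as.integer(wt_wt), wt_mut = as.integer(wt_mut),
                   mut_wt = as.integer(mut_wt), mut_mut = as.integer(mut_mut),
                   other = as.integer(other), stringsAsFactors = FALSE)
  stopifnot(all(unlist(df[-1]) >= 0L))
  df$total <- df$wt_wt + df$wt_mut + df$mut_wt + df$mut_mut
  class(df) <- c("haplotype_tally", "data.frame")
  df
}

#' Tally reads over two-site joint-allele categories
#'
#' Classifies every read with [classify_read()]; uninformative reads are
#' excluded from all columns, `other` reads are tracked but excluded
#' from the total.
#'
#' @param reads An [`aligned_reads`][read_alignments] data frame.
#' @param siteA,siteB [haplotype_site()] objects.
#' @param replicate_id Replicate label for the tally row.
#' @return A [haplotype_tally()].
#' @export
tally_haplotypes <- function(reads, siteA, siteB, replicate_id = "rep1") {
  cats <- classify_reads(reads, siteA, siteB)
  haplotype_tally(replicate_id,
                  wt_wt = sum(cats == "wt/wt"),
                  wt_mut = sum(cats == "wt/mut"),
                  mut_wt = sum(cats == "mut/wt"),
                  mut_mut = sum(cats == "mut/mut"),
                  other = sum(cats == "other"))
}

#' Pooled per-category proportions across replicates
#'
#' Proportions are computed from pooled counts (sum of each category's
#' counts divided by the sum of totals), not as the mean of
#' per-replicate proportions: the two conventions differ whenever
#' replicate totals differ.
#'
#' @param tallies One or more [haplotype_tally()] rows (a single data
#'   frame or a list of them).
#' @return An object of class `haplotype_pooled` with elements `counts`
#'   (pooled), `total`, `proportions` (full-precision fractions, `NA`
#'   when the pooled total is 0) and `pct` (rounded to one decimal).
#' @export
pooled_proportions <- function(tallies) {
  if (is.list(tallies) && !is.data.frame(tallies))
    tallies <- do.call(rbind, tallies)
  stopifnot(nrow(tallies) >= 1L)
  counts <- c(wt_wt = sum(tallies$wt_wt), wt_mut = sum(tallies$wt_mut),
              mut_wt = sum(tallies$mut_wt), mut_mut = sum(tallies$mut_mut))
  total <- sum(counts)
  props <- if (total > 0) counts / total else counts * NA_real_
  structure(list(counts = counts, total = total, proportions = props,
                 pct = pct(props)),
            class = "haplotype_pooled")
}

#' @export
print.haplotype_pooled <- function(x, ...) {
  cat("<haplotype_pooled> ", x$total, " informative reads\n", sep = "")
  lab <- gsub("_", "/", names(x$counts), fixed = TRUE)
  for (i in seq_along(x$counts))
    cat(sprintf("  %-8s %6d  %s%%\n", lab[i], x$counts[i],
                format(x$pct[i], nsmall = 1)))
  invisible(x)
}
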