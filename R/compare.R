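#' Genotype match between a call and a reference variant
#'
#' In `allele` mode (default) a call matches a reference variant when the
#' reference mutant allele is among the call's called alleles; a
#' homozygous-reference call at a reference-mutation position is a
#' mismatch. In `strict` mode, zygosity agreement is additionally
#' required when the reference zygosity is known (`het`: both the
#' reference and the mutant allele called; `hom`: only the mutant
#' allele called).
#'
#' @param call A one-row `snv_calls` data frame.
#' @param ref A one-row reference variant (columns `chrom`, `pos`, `ref`,
#'   `mut`, optionally `zygosity`).
#' @param mode `"allele"` (default) or `"strict"`.
#' @return `"match"` or `"mismatch"`.
#' @export
match_genotype <- function(call, ref, mode = c("allele", "strict")) {
  mode <- match.arg(mode)
  stopifnot(nrow(call) == 1L)
  if (call$chrom[1] != ref$chrom[1] || call$pos[1] != ref$pos[1])
    stop("match_genotype: call and reference variant positions disagree")
  called <- called_alleles(call, 1L)
  m <- ref$mut[1] %in% called
  if (m && mode == "strict") {
    zyg <- ref$zygosity[1] %||% "unknown"
    if (!is.na(zyg) && zyg == "het")
      m <- ref$ref[1] %in% called
    else if (!is.na(zyg) && zyg == "hom")
      m <- all(called == ref$mut[1])
  }
  if (m) "match" else "mismatch"
}

new_comparison_result <- function(sample_id, reference_cell_line,
                                  n_reference, n_overlap, n_match,
                                  mode, type = "reference",
                                  detail = NULL) {
  structure(list(
    sample_id = sample_id,
    reference_cell_line = reference_cell_line,
    n_reference = n_reference,
    n_overlap = n_overlap,
    n_match = n_match,
    n_mismatch = n_overlap - n_match,
    coverage = if (n_reference > 0) n_overlap / n_reference else NA_real_,
    concordance = if (n_overlap > 0) n_match / n_overlap else NA_real_,
    mode = mode, type = type, detail = detail),
    class = "comparison_result")
}

#' Compare an SNV profile to a reference cell-line profile
#'
#' The authentication statistic: every profile position present among the
#' reference profile's unique positions counts toward the overlap, and
#' each overlapping call is scored by [match_genotype()] against the
#' reference variant(s) at that position (several mutant alleles at one
#' position: a match if any matches). Coverage is overlap / unique
#' reference variants; concordance is matches / overlap (undefined, `NA`,
#' at zero overlap). Fractions are kept at full precision; percentages
#' are rounded half-up to one decimal only when printed or reported.
#'
#' @param profile An [`snv_profile`][build_profile].
#' @param ref A [reference_profile()]; an empty one is an error of class
#'   `snvauth_no_profile`.
#' @param mode Match mode passed to [match_genotype()].
#' @return An object of class `comparison_result` with fields
#'   `n_reference`, `n_overlap`, `n_match`, `n_mismatch`, `coverage`,
#'   `concordance` and a per-position `detail` data frame.
#' @export
compare_to_reference <- function(profile, ref, mode = c("allele", "strict")) {
  mode <- match.arg(mode)
  stopifnot(inherits(profile, "snv_profile"), inherits(ref, "reference_profile"))
  if (nrow(ref$variants) == 0L)
    no_profile_error(paste0("no profile: reference for '", ref$cell_line,
                            "' is empty"))
  refv <- ref$variants
  rkey <- pos_key(refv$chrom, refv$pos)
  calls <- profile$calls
  if (nrow(calls) == 0L) {
    return(new_comparison_result(profile$sample_id, ref$cell_line,
                                 nrow(refv), 0L, 0L, mode))
  }
  ckey <- pos_key(calls$chrom, calls$pos)
  ref_by_pos <- split(seq_len(nrow(refv)), rkey)
  overlap_idx <- which(ckey %in% names(ref_by_pos))
  matched <- logical(length(overlap_idx))
  for (j in seq_along(overlap_idx)) {
    i <- overlap_idx[j]
    for (r in ref_by_pos[[ckey[i]]]) {
      if (match_genotype(calls[i, , drop = FALSE],
                         refv[r, , drop = FALSE], mode) == "match") {
        matched[j] <- TRUE
        break
      }
    }
  }
  detail <- data.frame(chrom = calls$chrom[overlap_idx],
                       pos = calls$pos[overlap_idx],
                       call = overlap_idx, matched = matched,
                       stringsAsFactors = FALSE)
  new_comparison_result(profile$sample_id, ref$cell_line, nrow(refv),
                        length(overlap_idx), sum(matched), mode,
                        detail = detail)
}

#' @export
print.comparison_result <- function(x, ...) {
  fmt1 <- function(v) if (is.na(v)) "NA"
                      else paste0(formatC(pct(v), format = "f", digits = 1), "%")
  conc <- fmt1(x$concordance)
  cov <- fmt1(x$coverage)
  cat("<comparison_result", if (x$type != "reference") paste0(" (", x$type, ")"),
      "> ", x$sample_id, " vs ", x$reference_cell_line, "\n", sep = "")
  cat("  reference SNVs: ", x$n_reference,
      " | overlap: ", x$n_overlap,
      " | match/mismatch: ", x$n_match, "/", x$n_mismatch, "\n", sep = "")
  cat("  coverage: ", cov, " | concordance: ", conc, "\n", sep = "")
  if (!is.null(x$contamination)) {
    cat("  contamination screen: ", x$n_match, "/", x$n_overlap,
        " (", x$status, ")\n", sep = "")
  }
  invisible(x)
}

#' Screen a profile against a contaminant reference profile
#'
#' Identical computation to [compare_to_reference()], but reported as a
#' contamination screen (`n_match / n_overlap`, e.g. `0/2`). A screen
#' with at least one matching SNV and an overlap of at least
#' `min_overlap_alarm` raises a contamination warning; zero overlap is
#' labelled indeterminate (insufficient evidence), never clean.
#'
#' @inheritParams compare_to_reference
#' @param contaminant_ref The contaminant's [reference_profile()] (e.g.
#'   HeLa).
#' @param min_overlap_alarm Minimum overlap for the alarm (default 2).
#' @return A `comparison_result` with extra fields `contamination`
#'   (logical) and `status` (`"warning"`, `"clean"` or
#'   `"indeterminate"`).
#' @export
screen_contaminant <- function(profile, contaminant_ref,
                               mode = c("allele", "strict"),
                               min_overlap_alarm = 2L) {
  res <- compare_to_reference(profile, contaminant_ref, mode)
  res$type <- "screen"
  res$contamination <- res$n_match >= 1L && res$n_overlap >= min_overlap_alarm
  res$status <- if (res$contamination) "warning"
                else if (res$n_overlap == 0L) "indeterminate"
                else "clean"
  res
}

#' Compare a profile to a SNP genotyping panel
#'
#' Panel loci with a profile call count toward the overlap; a locus
#' matches when the called genotype (as an unordered base pair) equals
#' the panel's expected genotype for the cell line.
#'
#' @param profile An `snv_profile`.
#' @param panel An [`snp_panel`][read_panel].
#' @param cell_line Cell line whose expected genotypes to use.
#' @return An object of class `panel_result` with `n_panel`, `n_overlap`,
#'   `n_match` and a per-locus `detail` data frame.
#' @export
compare_to_panel <- function(profile, panel, cell_line) {
  rows <- panel[panel$cell_line == cell_line, , drop = FALSE]
  if (nrow(rows) == 0L)
    no_profile_error(paste0("no panel genotypes for cell line '",
                            cell_line, "'"))
  calls <- profile$calls
  ckey <- if (nrow(calls)) pos_key(calls$chrom, calls$pos) else character(0)
  lkey <- pos_key(rows$chrom, rows$pos)
  hit <- match(lkey, ckey)
  covered <- which(!is.na(hit))
  matched <- logical(length(covered))
  for (j in seq_along(covered)) {
    i <- hit[covered[j]]
    called <- called_alleles(calls, i)
    if (length(called) == 1L) called <- rep(called, 2L)  # haploid notation
    matched[j] <- identical(sort(called), genotype_pair(rows$genotype[covered[j]]))
  }
  structure(list(cell_line = cell_line, n_panel = nrow(rows),
                 n_overlap = length(covered), n_match = sum(matched),
                 detail = data.frame(locus_id = rows$locus_id[covered],
                                     chrom = rows$chrom[covered],
                                     pos = rows$pos[covered],
                                     matched = matched,
                                     stringsAsFactors = FALSE)),
            class = "panel_result")
}

#' @export
print.panel_result <- function(x, ...) {
  cat("<panel_result> ", x$cell_line, ": ", x$n_match, "/", x$n_overlap,
      " matching loci (", x$n_panel, " panel loci)\n", sep = "")
  invisible(x)
}

#' Pairwise transcriptome-scale concordance matrix
#'
#' For each ordered pair of profiles, the overlap is the set of positions
#' called in both and a position matches when the two calls carry the
#' identical set of called alleles (`allele_set` mode) or the identical
#' genotype string over the same alleles (`genotype` mode). The diagonal
#' is exactly 1 (a profile against itself). Values are full-precision
#' fractions (`NA` at zero overlap); printing rounds to one decimal.
#'
#' @param profiles A (preferably named) list of `snv_profile` objects.
#' @param mode `"allele_set"` (default) or `"genotype"`.
#' @return A square numeric matrix of class `concordance_matrix`.
#' @export
pairwise_concordance <- function(profiles, mode = c("allele_set", "genotype")) {
  mode <- match.arg(mode)
  nm <- names(profiles) %||% vapply(profiles, `[[`, character(1), "sample_id")
  if (is.null(names(profiles))) names(profiles) <- nm
  n <- length(profiles)
  keysets <- lapply(profiles, function(p) {
    calls <- p$calls
    if (nrow(calls) == 0L) return(list(keys = character(0)))
    keys <- pos_key(calls$chrom, calls$pos)
    sig <- vapply(seq_len(nrow(calls)), function(i) {
      if (mode == "allele_set")
        paste(sort(unique(called_alleles(calls, i))), collapse = "/")
      else
        paste(calls$gt[i], paste(c(calls$ref[i], calls$alt[[i]]),
                                 collapse = ","), sep = "|")
    }, character(1))
    list(keys = keys, sig = sig)
  })
  m <- matrix(NA_real_, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) { m[i, j] <- 1; next }
      a <- keysets[[i]]; b <- keysets[[j]]
      hit <- match(a$keys, b$keys)
      ov <- which(!is.na(hit))
      if (length(ov) == 0L) next
      m[i, j] <- mean(a$sig[ov] == b$sig[hit[ov]])
    }
  }
  class(m) <- c("concordance_matrix", class(m))
  m
}

#' @export
print.concordance_matrix <- function(x, ...) {
  y <- unclass(x)
  print(round_half_up(100 * y, 1))
  invisible(x)
}

#' SNVs per million reads
#'
#' @param n_snvs Number of filtered SNVs.
#' @param n_reads Total number of sequenced reads (> 0).
#' @return `n_snvs / n_reads * 1e6`, rounded half-up to the nearest
#'   integer.
#' @export
#' @examples
#' snvs_per_million(72203, 37087864)  # 1947
snvs_per_million <- function(n_snvs, n_reads) {
  stopifnot(all(n_reads > 0), all(n_snvs >= 0))
  as.integer(round_half_up(n_snvs / n_reads * 1e6, 0))
}

#' Authentication verdict
#'
#' A sample is authenticated when its concordance against the expected
#' reference profile reaches the threshold (default 90%, the level
#' proposed for SNP-panel authentication) *and* the comparison rests on
#' enough overlapping positions (default 25): tiny overlaps can yield
#' spurious 100% concordances.
#'
#' @param result A [`comparison_result`][compare_to_reference].
#' @param concordance_threshold Minimum concordance (fraction, default
#'   0.90).
#' @param min_overlap Minimum overlapping positions (default 25).
#' @return An object of class `verdict` with fields `authenticated`,
#'   `status` (`"authenticated"`, `"not_authenticated"` or
#'   `"indeterminate"`) and `notes`.
#' @export
verdict <- function(result, concordance_threshold = 0.90, min_overlap = 25L) {
  stopifnot(concordance_threshold > 0, min_overlap > 0)
  notes <- character(0)
  if (is.na(result$concordance)) {
    status <- "indeterminate"
    notes <- c(notes, "no overlapping positions: authenticity indeterminate")
  } else {
    conc_ok <- result$concordance >= concordance_threshold
    ov_ok <- result$n_overlap >= min_overlap
    if (!ov_ok)
      notes <- c(notes, sprintf(
        "insufficient overlap (%d < %d): evidence too thin for authentication",
        result$n_overlap, min_overlap))
    if (conc_ok && !ov_ok) status <- "not_authenticated"
    else if (conc_ok) status <- "authenticated"
    else status <- "not_authenticated"
    if (conc_ok && ov_ok &&
        result$concordance < concordance_threshold + 0.02)
      notes <- c(notes, "concordance within 2 points of the threshold")
  }
  structure(list(authenticated = identical(status, "authenticated"),
                 status = status,
                 concordance_threshold = concordance_threshold,
                 min_overlap = as.integer(min_overlap),
                 notes = notes),
            class = "verdict")
}

#' @export
print.verdict <- function(x, ...) {
  cat("<verdict> ", x$status, "\n", sep = "")
  for (n in x$notes) cat("  note: ", n, "\n", sep = "")
  invisible(x)
}
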