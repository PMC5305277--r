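#' Filtering configuration
#'
#' Thresholds for the filtering stack that turns raw variant calls into a
#' filtered expressed-SNV profile. Defaults follow the GATK RNA-seq
#' best-practice convention: a call fails when its phred-scaled strand
#' bias exceeds `fs_fail_threshold` (FS > 30) or its quality by depth
#' falls below `qd_fail_threshold` (QD < 2); SNVs forming clusters of at
#' least `cluster_min_snvs` within a `cluster_window`-bp window are
#' removed, as are calls with total allelic depth below
#' `min_total_depth`.
#'
#' @param fs_fail_threshold Fail calls with Fisher strand above this
#'   (default 30).
#' @param qd_fail_threshold Fail calls with quality by depth below this
#'   (default 2).
#' @param cluster_window Window size in bases for cluster detection
#'   (default 35; inclusive span, i.e. positions p and q are
#'   cluster-compatible iff |p - q| <= window - 1).
#' @param cluster_min_snvs Minimum SNVs within a window that form a
#'   cluster (default 3; must be >= 2).
#' @param min_total_depth Minimum total allelic depth (default 10,
#'   inclusive: a call with summed depth exactly 10 is kept).
#' @param keep_hom_ref Keep confident homozygous-reference calls in the
#'   profile (default `TRUE`). Hom-ref calls bypass the quality, cluster
#'   and impact stages but are subject to the depth filter.
#' @param impact_selection Apply highest-impact-per-transcript selection
#'   (default `TRUE`).
#' @param missing_stats Policy for calls whose FS or QD statistic is
#'   absent: `"fail"` (default, strict — absent evidence does not pass a
#'   quality gate) or `"pass"` (lenient).
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(fs_fail_threshold = 30, qd_fail_threshold = 2,
                          cluster_window = 35L, cluster_min_snvs = 3L,
                          min_total_depth = 10L, keep_hom_ref = TRUE,
                          impact_selection = TRUE,
                          missing_stats = c("fail", "pass")) {
  missing_stats <- match.arg(missing_stats)
  stopifnot(fs_fail_threshold > 0, qd_fail_threshold > 0,
            cluster_window >= 1, cluster_min_snvs >= 2, min_total_depth > 0)
  structure(list(fs_fail_threshold = fs_fail_threshold,
                 qd_fail_threshold = qd_fail_threshold,
                 cluster_window = as.integer(cluster_window),
                 cluster_min_snvs = as.integer(cluster_min_snvs),
                 min_total_depth = as.integer(min_total_depth),
                 keep_hom_ref = isTRUE(keep_hom_ref),
                 impact_selection = isTRUE(impact_selection),
                 missing_stats = missing_stats),
            class = "filter_config")
}

#' Site-quality filter (strand bias, quality by depth, upstream flags)
#'
#' Removes calls flagged failed by the upstream caller (`filter` neither
#' empty nor `PASS`) and alt-carrying calls with FS above or QD below the
#' configured thresholds. Homozygous-reference calls carry no variant
#' quality statistics and bypass the FS/QD gates (upstream flags still
#' apply). Absent FS/QD fails the gate under `missing_stats = "fail"`.
#'
#' @param calls An `snv_calls` data frame.
#' @param config A [filter_config()].
#' @return `list(calls = passing calls in input order, removed = count)`.
#' @export
apply_site_quality_filters <- function(calls, config = filter_config()) {
  if (nrow(calls) == 0L) return(list(calls = calls, removed = 0L))
  flagged <- !(calls$filter %in% c("", ".", "PASS"))
  absent_fails <- config$missing_stats == "fail"
  fs_bad <- if (absent_fails) is.na(calls$fs) | calls$fs > config$fs_fail_threshold
            else !is.na(calls$fs) & calls$fs > config$fs_fail_threshold
  qd_bad <- if (absent_fails) is.na(calls$qd) | calls$qd < config$qd_fail_threshold
            else !is.na(calls$qd) & calls$qd < config$qd_fail_threshold
  fail <- flagged | (has_alt(calls) & (fs_bad | qd_bad))
  out <- calls[!fail, , drop = FALSE]
  rownames(out) <- NULL
  list(calls = out, removed = sum(fail))
}

# drop records that are not single-base substitutions (indels, MNVs,
# symbolic alleles); single-base hom-ref records pass
remove_non_snv <- function(calls) {
  if (nrow(calls) == 0L) return(list(calls = calls, removed = 0L))
  keep <- is_snv_call(calls)
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(calls = out, removed = sum(!keep))
}

#' Remove clustered SNVs
#'
#' Removes every SNV lying in any window of `cluster_window` bases
#' (inclusive span) that contains at least `cluster_min_snvs` SNVs on the
#' same chromosome. Only alt-carrying SNVs count toward, and are removed
#' by, the window scan; homozygous-reference and non-SNV records are
#' transparent to it. Unsorted input is sorted internally; output
#' preserves input order.
#'
#' @inheritParams apply_site_quality_filters
#' @return `list(calls = passing calls, removed = count)`.
#' @export
remove_snv_clusters <- function(calls, config = filter_config()) {
  if (nrow(calls) == 0L) return(list(calls = calls, removed = 0L))
  window <- config$cluster_window
  k <- config$cluster_min_snvs
  snv_idx <- which(has_alt(calls) & is_snv_call(calls))
  drop <- logical(nrow(calls))
  for (chr in unique(calls$chrom[snv_idx])) {
    idx <- snv_idx[calls$chrom[snv_idx] == chr]
    ord <- idx[order(calls$pos[idx])]
    p <- calls$pos[ord]
    n <- length(p)
    if (n < k) next
    marked <- logical(n)
    for (i in seq_len(n - k + 1L)) {
      if (p[i + k - 1L] - p[i] <= window - 1L)
        marked[i:(i + k - 1L)] <- TRUE
    }
    drop[ord[marked]] <- TRUE
  }
  out <- calls[!drop, , drop = FALSE]
  rownames(out) <- NULL
  list(calls = out, removed = sum(drop))
}

#' Total allelic depth filter
#'
#' Removes calls whose summed allelic depths fall below
#' `min_total_depth` (the boundary is inclusive: a total of exactly
#' `min_total_depth` is kept). Applies to all calls, including
#' homozygous-reference ones.
#'
#' @inheritParams apply_site_quality_filters
#' @return `list(calls = passing calls, removed = count)`.
#' @export
depth_filter <- function(calls, config = filter_config()) {
  if (nrow(calls) == 0L) return(list(calls = calls, removed = 0L))
  keep <- total_depth(calls) >= config$min_total_depth
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(calls = out, removed = sum(!keep))
}

#' Highest-impact-per-transcript selection
#'
#' For each annotated transcript, computes the maximum impact level among
#' that transcript's variants; a variant is retained iff, for at least one
#' of its annotated transcripts, its impact equals that transcript's
#' maximum. Unannotated calls (including homozygous-reference records)
#' are retained unconditionally.
#'
#' @param calls An `snv_calls` data frame.
#' @return The passing calls, in input order.
#' @export
highest_impact_selection <- function(calls) {
  if (nrow(calls) == 0L) return(calls)
  long <- lapply(seq_len(nrow(calls)), function(i) {
    a <- calls$ann[[i]]
    if (is.null(a) || nrow(a) == 0L || !has_alt(calls)[i]) return(NULL)
    data.frame(call = i, transcript = a$transcript,
               rank = impact_rank(a$impact), stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, long[!vapply(long, is.null, logical(1))])
  if (is.null(long) || nrow(long) == 0L) return(calls)
  tx_max <- tapply(long$rank, long$transcript, max)
  long$is_max <- long$rank == tx_max[long$transcript]
  keep_annot <- tapply(long$is_max, long$call, any)
  keep <- rep(TRUE, nrow(calls))
  keep[as.integer(names(keep_annot))] <- as.logical(keep_annot)
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a filtered expressed-SNV profile
#'
#' Applies the full filtering stack, in order: upstream-flag + site
#' quality (FS/QD) filters, non-SNV removal, SNV-cluster removal, total
#' allelic depth filter, and highest-impact-per-transcript selection.
#' The result is keyed by unique genomic position; when two passing SNVs
#' share a position the one with greater total depth wins (ties: greater
#' quality by depth, then first in input order), and the collision is
#' counted in the filter log.
#'
#' @param calls Raw `snv_calls` from [read_vcf()].
#' @param config A [filter_config()].
#' @param sample_id Sample identifier stored in the profile.
#' @return An object of class `snv_profile`: fields `sample_id`, `calls`
#'   (position-unique, sorted), `n_input_calls` and `filter_log` (named
#'   integer vector of per-stage removal counts).
#' @export
build_profile <- function(calls, config = filter_config(),
                          sample_id = "sample") {
  n_input <- nrow(calls)
  log <- c(hom_ref_dropped = 0L, site_quality = 0L, non_snv = 0L,
           cluster = 0L, depth = 0L, impact = 0L, duplicate_position = 0L)

  if (!config$keep_hom_ref && n_input > 0L) {
    hr <- !has_alt(calls)
    log["hom_ref_dropped"] <- sum(hr)
    calls <- calls[!hr, , drop = FALSE]
  }
  st <- apply_site_quality_filters(calls, config)
  log["site_quality"] <- st$removed
  st <- remove_non_snv(st$calls)
  log["non_snv"] <- st$removed
  st2 <- remove_snv_clusters(st$calls, config)
  log["cluster"] <- st2$removed
  st3 <- depth_filter(st2$calls, config)
  log["depth"] <- st3$removed
  kept <- st3$calls
  if (config$impact_selection) {
    before <- nrow(kept)
    kept <- highest_impact_selection(kept)
    log["impact"] <- before - nrow(kept)
  }

  if (nrow(kept) > 0L) {
    key <- pos_key(kept$chrom, kept$pos)
    if (anyDuplicated(key)) {
      pref <- order(key, -total_depth(kept),
                    -ifelse(is.na(kept$qd), -Inf, kept$qd),
                    seq_len(nrow(kept)), method = "radix")
      dup <- duplicated(key[pref])
      log["duplicate_position"] <- sum(dup)
      kept <- kept[sort(pref[!dup]), , drop = FALSE]
    }
    kept <- kept[order_positions(kept$chrom, kept$pos), , drop = FALSE]
    rownames(kept) <- NULL
  }

  structure(list(sample_id = sample_id, calls = kept,
                 n_input_calls = n_input, filter_log = log),
            class = "snv_profile")
}

#' @export
print.snv_profile <- function(x, ...) {
  cat("<snv_profile> ", x$sample_id, ": ", nrow(x$calls),
      " filtered SNV position(s) from ", x$n_input_calls,
      " input call(s)\n", sep = "")
  removed <- x$filter_log[x$filter_log > 0]
  if (length(removed))
    cat("  removed:", paste(names(removed), removed, sep = "=",
                            collapse = ", "), "\n")
  invisible(x)
}
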