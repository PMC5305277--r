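#' Characterisation table of matching vs mismatched SNVs
#'
#' Builds the per-impact-level and per-effect-class count table for
#' matching and mismatched SNVs, with proportions computed per column
#' (so the proportions within each column sum to 1, up to rounding).
#'
#' @param impact_match,impact_mismatch Named integer vectors of counts
#'   over the impact levels (MODIFIER, LOW, MODERATE, HIGH); missing
#'   levels count 0.
#' @param effect_match,effect_mismatch Named integer vectors of counts
#'   over the effect classes (missense, nonsense, synonymous, other).
#' @return An object of class `characterization_table` with elements
#'   `impact` and `effect`, each a data frame of counts and
#'   full-precision per-column proportions.
#' @export
characterization_table <- function(impact_match, impact_mismatch,
                                   effect_match, effect_mismatch) {
  fill <- function(x, levels) {
    out <- stats::setNames(rep(0L, length(levels)), levels)
    x <- x[names(x) %in% levels]
    out[names(x)] <- as.integer(x)
    out
  }
  block <- function(match, mismatch, levels) {
    m <- fill(match, levels)
    mm <- fill(mismatch, levels)
    data.frame(category = levels, match = unname(m), mismatch = unname(mm),
               match_prop = if (sum(m) > 0) unname(m) / sum(m) else NA_real_,
               mismatch_prop = if (sum(mm) > 0) unname(mm) / sum(mm)
                               else NA_real_,
               stringsAsFactors = FALSE)
  }
  structure(list(impact = block(impact_match, impact_mismatch,
                                rev(IMPACT_LEVELS)),
                 effect = block(effect_match, effect_mismatch,
                                EFFECT_CLASSES)),
            class = "characterization_table")
}

# the single highest-impact annotation row of call i (ties: first)
top_annotation <- function(calls, i) {
  a <- calls$ann[[i]]
  if (is.null(a) || nrow(a) == 0L) return(NULL)
  a[which.max(impact_rank(a$impact)), , drop = FALSE]
}

#' Characterise matching and mismatched SNVs by annotation
#'
#' Each call contributes its single highest-impact annotation to exactly
#' one impact row and one effect row; unannotated calls (e.g.
#' homozygous-reference records) contribute nothing.
#'
#' @param match_calls,mismatch_calls `snv_calls` data frames of the
#'   matching and mismatched SNVs of a comparison (see the `detail`
#'   field of [compare_to_reference()]).
#' @return A [characterization_table()].
#' @export
characterize <- function(match_calls, mismatch_calls) {
  tops <- function(calls) {
    rows <- lapply(seq_len(nrow(calls)), function(i) top_annotation(calls, i))
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows) == 0L) return(empty_annotation())
    do.call(rbind, rows)
  }
  tm <- tops(match_calls)
  tmm <- tops(mismatch_calls)
  characterization_table(
    impact_match = table(tm$impact), impact_mismatch = table(tmm$impact),
    effect_match = table(tm$effect), effect_mismatch = table(tmm$effect))
}

#' @export
print.characterization_table <- function(x, ...) {
  fmt <- function(df) {
    df$match_pct <- pct(df$match_prop)
    df$mismatch_pct <- pct(df$mismatch_prop)
    df[, c("category", "match", "mismatch", "match_pct", "mismatch_pct")]
  }
  cat("<characterization_table>\nImpact:\n")
  print(fmt(x$impact), row.names = FALSE)
  cat("Effect:\n")
  print(fmt(x$effect), row.names = FALSE)
  invisible(x)
}
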