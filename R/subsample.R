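#' Binomially thin allelic depths
#'
#' Desk-scale surrogate for sequencing-depth subsampling: every allelic
#' depth is replaced by a binomial draw with the original depth as count
#' and `fraction` as success probability. Alternate alleles whose
#' thinned depth reaches 0 are dropped from the allele list, and
#' genotype entries pointing at dropped alleles collapse to the
#' reference allele (e.g. `AD = [8, 6]` thinned to `[3, 0]` becomes a
#' homozygous-reference call of depth 3). Deterministic for a fixed
#' seed; `fraction = 1` returns the input unchanged.
#'
#' @param calls An `snv_calls` data frame.
#' @param fraction Thinning fraction in (0, 1].
#' @param seed Integer RNG seed.
#' @return The thinned `snv_calls`.
#' @export
thin_depths <- function(calls, fraction, seed = 1L) {
  if (!(is.numeric(fraction) && length(fraction) == 1L &&
        fraction > 0 && fraction <= 1))
    stop("fraction must be a single number in (0, 1]")
  if (fraction == 1 || nrow(calls) == 0L) return(calls)
  flat <- unlist(calls$ad, use.names = FALSE)
  thinned <- with_seed(seed,
                       stats::rbinom(length(flat), size = flat, prob = fraction))
  lens <- lengths(calls$ad)
  ad_new <- unname(split(as.integer(thinned),
                         rep(seq_len(nrow(calls)), lens)))
  out <- calls
  for (i in seq_len(nrow(out))) {
    ad <- ad_new[[i]]
    alt <- out$alt[[i]]
    if (length(alt) == 0L) {
      out$ad[[i]] <- ad
      next
    }
    keep_alt <- ad[-1] > 0L
    new_alt <- alt[keep_alt]
    # old allele index -> new index; dropped alt alleles collapse to ref (0)
    remap <- c(0L, ifelse(keep_alt, cumsum(keep_alt), 0L))
    idx <- gt_indices(out$gt[i])
    idx <- sort(remap[idx + 1L])
    out$gt[i] <- paste(idx, collapse = "/")
    out$alt[[i]] <- new_alt
    out$ad[[i]] <- c(ad[1], ad[-1][keep_alt])
  }
  out
}

#' Subsampling robustness curve
#'
#' Re-runs the filter + comparison stack at each depth fraction: thin
#' the allelic depths, rebuild the filtered SNV profile, and compare it
#' to the reference profile. At fraction 1 the result equals the
#' unthinned pipeline output exactly. Each fraction uses a substream
#' seed derived from `seed` by a fixed offset, so curves are
#' reproducible.
#'
#' @param calls Raw `snv_calls` (as from [read_vcf()]).
#' @param ref_profile A [reference_profile()].
#' @param fractions Vector of depth fractions in (0, 1]; sorted
#'   decreasing.
#' @param seed Integer base seed.
#' @param config A [filter_config()].
#' @param sample_id Sample identifier.
#' @param mode Match mode for [compare_to_reference()].
#' @return A data frame of class `subsample_curve` with columns
#'   `fraction`, `n_snvs`, `concordance` (fraction, `NA` at zero
#'   overlap) and `seed`.
#' @export
subsample_curve <- function(calls, ref_profile,
                            fractions = c(1, 0.5, 0.25, 0.1, 0.02, 0.01),
                            seed = 1L, config = filter_config(),
                            sample_id = "sample",
                            mode = c("allele", "strict")) {
  mode <- match.arg(mode)
  fractions <- sort(unique(fractions), decreasing = TRUE)
  rows <- vector("list", length(fractions))
  for (i in seq_along(fractions)) {
    sub_seed <- as.integer((seed + 7919 * i) %% 2147483646L) + 1L
    thinned <- thin_depths(calls, fractions[i], seed = sub_seed)
    prof <- build_profile(thinned, config, sample_id)
    cmp <- compare_to_reference(prof, ref_profile, mode)
    rows[[i]] <- data.frame(fraction = fractions[i],
                            n_snvs = nrow(prof$calls),
                            concordance = cmp$concordance,
                            seed = sub_seed)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("subsample_curve", "data.frame")
  out
}
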