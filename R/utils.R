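# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Rounding used for all reported percentages: half-up to the requested
#' number of decimals (base `round()` rounds half to even, which does not
#' reproduce conventionally printed one-decimal percentages).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(98.45, 1)  # 98.5, where round() gives 98.4
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# fraction -> percentage at reporting precision; NA passes through
pct <- function(x, digits = 1) round_half_up(100 * x, digits)

pos_key <- function(chrom, pos) paste0(chrom, ":", pos)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

DNA_BASES <- c("A", "C", "G", "T")

complement_base <- function(x) chartr("ACGT", "TGCA", x)

is_single_base <- function(x) !is.na(x) & nchar(x) == 1L & x %in% DNA_BASES

# stable ordering: chromosome lexical, then position numeric
order_positions <- function(chrom, pos) order(chrom, pos, method = "radix")

no_profile_error <- function(msg) {
  stop(errorCondition(msg, class = c("snvauth_no_profile", "error", "condition")))
}
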