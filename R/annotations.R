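#' Functional annotation vocabulary
#'
#' Putative impact levels (ordered least to most severe) and effect classes
#' used throughout the package. Impacts follow the SnpEff ontology
#' (MODIFIER < LOW < MODERATE < HIGH); the rich SnpEff effect vocabulary is
#' collapsed onto four classes: missense, nonsense, synonymous and other.
#'
#' @name annotation-vocabulary
#' @keywords internal
NULL

IMPACT_LEVELS <- c("MODIFIER", "LOW", "MODERATE", "HIGH")
EFFECT_CLASSES <- c("missense", "nonsense", "synonymous", "other")

impact_rank <- function(impact) match(impact, IMPACT_LEVELS)

empty_annotation <- function() {
  data.frame(transcript = character(0), gene = character(0),
             effect = character(0), impact = character(0),
             stringsAsFactors = FALSE)
}

map_effect <- function(effect_field) {
  # SnpEff may join several terms with "&"; classify on the first known term
  terms <- strsplit(effect_field, "&", fixed = TRUE)
  vapply(terms, function(tt) {
    if ("missense_variant" %in% tt) "missense"
    else if ("stop_gained" %in% tt) "nonsense"
    else if ("synonymous_variant" %in% tt) "synonymous"
    else "other"
  }, character(1))
}

#' Parse a SnpEff-style ANN annotation field
#'
#' Parses the pipe-delimited `ANN` INFO field
#' (`allele|effect|impact|gene_name|gene_id|feature_type|feature_id|...`),
#' possibly containing several comma-separated entries, into one annotation
#' row per entry. Effects are mapped onto \{missense, nonsense, synonymous,
#' other\} and impacts must be one of MODIFIER/LOW/MODERATE/HIGH.
#'
#' @param ann_field A single `ANN` string, or `NA`/`""` for no annotation.
#' @return A data frame with columns `transcript`, `gene`, `effect`,
#'   `impact`, one row per entry, in input order.
#' @export
#' @examples
#' parse_annotation(
#'   "A|missense_variant|MODERATE|KRAS|KRAS|transcript|ENST00000311936|coding")
parse_annotation <- function(ann_field) {
  if (is.null(ann_field) || length(ann_field) == 0) return(empty_annotation())
  stopifnot(length(ann_field) == 1L)
  if (is.na(ann_field) || !nzchar(ann_field)) return(empty_annotation())
  entries <- strsplit(ann_field, ",", fixed = TRUE)[[1]]
  rows <- lapply(entries, function(e) {
    f <- strsplit(e, "|", fixed = TRUE)[[1]]
    if (length(f) < 7L)
      stop("malformed annotation entry (fewer than 7 fields): ", e)
    impact <- f[3]
    if (!impact %in% IMPACT_LEVELS)
      stop("unknown impact level '", impact, "' in annotation entry: ", e)
    data.frame(transcript = f[7], gene = f[4], effect = map_effect(f[2]),
               impact = impact, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
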