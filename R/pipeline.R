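#' Run the full authentication pipeline
#'
#' Wires the modules into the end-to-end pipeline: read the VCF, build
#' the filtered expressed-SNV profile, compare it to the expected
#' reference cell-line profile, optionally screen against a contaminant
#' profile and check a SNP genotyping panel, and issue a verdict.
#'
#' @param vcf Path to the single-sample VCF of variant calls.
#' @param profile_file Path to the reference (COSMIC-style) profile TSV.
#' @param cell_line Expected cell line (must be present in
#'   `profile_file`).
#' @param contaminant_file Optional path to a contaminant profile TSV.
#' @param contaminant_cell_line Contaminant profile name (default
#'   `"HeLa"`).
#' @param panel_file Optional path to a SNP genotyping panel TSV.
#' @param config A [filter_config()].
#' @param sample VCF sample name (default first sample).
#' @param sample_id Identifier for reports (default the VCF base name).
#' @param mode Match mode for the comparisons.
#' @param concordance_threshold,min_overlap Verdict thresholds (see
#'   [verdict()]).
#' @param out Optional report path (written via [write_report()]).
#' @param format Report format when `out` is given.
#' @return An object of class `run_report`: the profile filter log, all
#'   comparison results, the verdict, a `status` string
#'   (`"authenticated"`, `"not_authenticated"`, `"indeterminate"`), tool
#'   version, configuration echo and input checksums.
#' @export
run_authentication <- function(vcf, profile_file, cell_line,
                               contaminant_file = NULL,
                               contaminant_cell_line = "HeLa",
                               panel_file = NULL,
                               config = filter_config(),
                               sample = NULL, sample_id = NULL,
                               mode = c("allele", "strict"),
                               concordance_threshold = 0.90,
                               min_overlap = 25L,
                               out = NULL, format = c("tsv", "json")) {
  mode <- match.arg(mode)
  format <- match.arg(format)
  sample_id <- sample_id %||% sub("\\.vcf$", "", basename(vcf))

  calls <- read_vcf(vcf, include_hom_ref = config$keep_hom_ref,
                    sample = sample)
  ref <- read_reference_profile(profile_file, cell_line)
  profile <- build_profile(calls, config, sample_id)
  cmp <- compare_to_reference(profile, ref, mode)

  screen <- NULL
  if (!is.null(contaminant_file)) {
    cont <- read_reference_profile(contaminant_file, contaminant_cell_line)
    screen <- screen_contaminant(profile, cont, mode)
  }
  panel_res <- NULL
  if (!is.null(panel_file)) {
    panel <- read_panel(panel_file)
    panel_res <- compare_to_panel(profile, panel, cell_line)
  }
  vd <- verdict(cmp, concordance_threshold, min_overlap)

  inputs <- c(vcf = vcf, profile = profile_file,
              contaminant = contaminant_file %||% NA_character_,
              panel = panel_file %||% NA_character_)
  checksums <- vapply(inputs, function(p) {
    if (is.na(p)) NA_character_ else unname(tools::md5sum(p))
  }, character(1))

  report <- structure(list(
    tool = "snvauth",
    version = as.character(utils::packageVersion("snvauth")),
    sample_id = sample_id,
    cell_line = cell_line,
    status = vd$status,
    filter_log = profile$filter_log,
    n_input_calls = profile$n_input_calls,
    n_profile_snvs = nrow(profile$calls),
    comparison = cmp,
    screen = screen,
    panel = panel_res,
    verdict = vd,
    config = unclass(config),
    inputs = as.list(inputs[!is.na(inputs)]),
    checksums = as.list(checksums[!is.na(checksums)])),
    class = "run_report")
  if (!is.null(out)) write_report(report, out, format)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> ", x$sample_id, " vs ", x$cell_line,
      " [", x$status, "]\n", sep = "")
  cat("  profile: ", x$n_profile_snvs, " SNV position(s) from ",
      x$n_input_calls, " call(s)\n", sep = "")
  print(x$comparison)
  if (!is.null(x$screen)) print(x$screen)
  if (!is.null(x$panel)) print(x$panel)
  print(x$verdict)
  invisible(x)
}

# exit-code contract used by the command-line wrapper:
# 0 authenticated, 2 not authenticated, 3 indeterminate, 4 input error
exit_code_for_status <- function(status) {
  switch(status, authenticated = 0L, not_authenticated = 2L,
         indeterminate = 3L, 4L)
}
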