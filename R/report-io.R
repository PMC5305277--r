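#' Write a comparison result or run report to disk
#'
#' Serialisation is loss-free for all counts; percentages are reported
#' rounded half-up to one decimal alongside the counts they derive from
#' (an undefined concordance is written as `NA`, never 0).
#'
#' @param x A [`comparison_result`][compare_to_reference] or
#'   [`run_report`][run_authentication].
#' @param path Output path.
#' @param format `"tsv"` (key/value pairs) or `"json"`.
#' @return Invisibly, `path`.
#' @export
write_report <- function(x, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  UseMethod("write_report")
}

report_fields <- function(x) {
  list(sample_id = x$sample_id,
       reference_cell_line = x$reference_cell_line,
       type = x$type,
       n_reference = x$n_reference,
       n_overlap = x$n_overlap,
       n_match = x$n_match,
       n_mismatch = x$n_mismatch,
       coverage_pct = if (is.na(x$coverage)) NA else pct(x$coverage),
       concordance_pct = if (is.na(x$concordance)) NA else pct(x$concordance))
}

#' @export
write_report.comparison_result <- function(x, path,
                                           format = c("tsv", "json")) {
  format <- match.arg(format)
  fields <- report_fields(x)
  if (format == "json") {
    jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  } else {
    vals <- vapply(fields, function(v) {
      if (is.null(v) || (length(v) == 1 && is.na(v))) "NA" else as.character(v)
    }, character(1))
    utils::write.table(data.frame(key = names(fields), value = vals),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @export
write_report.run_report <- function(x, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    flat <- x
    flat$comparison <- report_fields(x$comparison)
    if (!is.null(x$screen))
      flat$screen <- c(report_fields(x$screen),
                       list(status = x$screen$status))
    if (!is.null(x$panel))
      flat$panel <- list(cell_line = x$panel$cell_line,
                         n_panel = x$panel$n_panel,
                         n_overlap = x$panel$n_overlap,
                         n_match = x$panel$n_match)
    flat$verdict <- unclass(x$verdict)
    flat$filter_log <- as.list(x$filter_log)
    class(flat) <- NULL
    jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  } else {
    kv <- c(list(tool = x$tool, version = x$version, status = x$status,
                 sample_id = x$sample_id, cell_line = x$cell_line),
            stats::setNames(as.list(x$filter_log),
                            paste0("removed_", names(x$filter_log))),
            list(n_profile_snvs = x$n_profile_snvs),
            report_fields(x$comparison))
    if (!is.null(x$screen))
      kv <- c(kv, list(screen = paste0(x$screen$n_match, "/",
                                       x$screen$n_overlap),
                       screen_status = x$screen$status))
    if (!is.null(x$panel))
      kv <- c(kv, list(panel = paste0(x$panel$n_match, "/",
                                      x$panel$n_overlap)))
    vals <- vapply(kv, function(v) {
      if (is.null(v) || (length(v) == 1 && is.na(v))) "NA" else as.character(v)
    }, character(1))
    utils::write.table(data.frame(key = names(kv), value = vals),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a written comparison report back
#'
#' Reconstructs the counts of a report written by [write_report()]
#' (comparison results only); derived fractions are recomputed from the
#' counts, so a write/read round trip preserves every number.
#'
#' @param path Path written by [write_report()].
#' @return A `comparison_result`.
#' @export
read_report <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (startsWith(trimws(first), "{")) {
    f <- jsonlite::read_json(path)
  } else {
    kv <- utils::read.delim(path, stringsAsFactors = FALSE)
    f <- stats::setNames(as.list(kv$value), kv$key)
  }
  num <- function(v) if (is.null(v) || identical(v, "NA")) NA_integer_
                     else as.integer(v)
  res <- new_comparison_result(
    sample_id = as.character(f$sample_id),
    reference_cell_line = as.character(f$reference_cell_line),
    n_reference = num(f$n_reference),
    n_overlap = num(f$n_overlap),
    n_match = num(f$n_match),
    mode = "allele",
    type = as.character(f$type %||% "reference"))
  res
}
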