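#' Read a SNP genotyping panel
#'
#' Reads a tab-delimited SNP genotyping panel (one row per locus and cell
#' line) with columns `locus_id` (e.g. a dbSNP rs identifier), `chrom`,
#' `pos`, `cell_line` and `genotype` (unordered base pair, e.g. `"A/G"`).
#'
#' @param path Path to the panel file.
#' @return A data frame of class `snp_panel`.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("locus_id", "chrom", "pos", "cell_line", "genotype")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("panel file lacks column(s): ", paste(missing_cols, collapse = ", "))
  df$pos <- as.integer(df$pos)
  bad <- !grepl("^[ACGT]/[ACGT]$", df$genotype)
  if (any(bad))
    stop("unparseable panel genotype '", df$genotype[which(bad)[1]],
         "' in row ", which(bad)[1])
  class(df) <- c("snp_panel", "data.frame")
  df
}

write_panel <- function(panel, path) {
  utils::write.table(panel, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# "G/C" -> sorted base pair
genotype_pair <- function(genotype) sort(strsplit(genotype, "/", fixed = TRUE)[[1]])
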