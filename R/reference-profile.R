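#' Reference cell-line mutation profiles
#'
#' A reference profile is the deduplicated set of known single-base
#' substitutions for one cell line, in the style of a COSMIC cell-line
#' export: one record per unique (position, mutant allele) pair.
#'
#' @param cell_line Cell line name.
#' @param variants Data frame with columns `chrom`, `pos`, `ref`, `mut`
#'   and optionally `gene`, `transcript`, `zygosity`; deduplicated on
#'   (position, mutant allele) by the constructor.
#' @return An object of class `reference_profile`.
#' @export
reference_profile <- function(cell_line, variants) {
  need <- c("chrom", "pos", "ref", "mut")
  stopifnot(all(need %in% names(variants)))
  n <- nrow(variants)
  if (is.null(variants$gene)) variants$gene <- rep(NA_character_, n)
  if (is.null(variants$transcript))
    variants$transcript <- rep(NA_character_, n)
  if (is.null(variants$zygosity)) variants$zygosity <- rep("unknown", n)
  variants$pos <- as.integer(variants$pos)
  dup <- duplicated(paste(variants$chrom, variants$pos, variants$mut))
  variants <- variants[!dup, , drop = FALSE]
  variants <- variants[order_positions(variants$chrom, variants$pos), ,
                       drop = FALSE]
  rownames(variants) <- NULL
  structure(list(cell_line = cell_line, variants = variants,
                 n_dropped = 0L),
            class = "reference_profile")
}

#' @export
print.reference_profile <- function(x, ...) {
  cat("<reference_profile> ", x$cell_line, ": ", nrow(x$variants),
      " unique SNV(s)\n", sep = "")
  invisible(x)
}

# first matching column name among aliases (case/sep-insensitive)
find_column <- function(df, aliases) {
  norm <- function(s) gsub("[ ._]", "", tolower(s))
  hit <- match(norm(aliases), norm(names(df)))
  hit <- hit[!is.na(hit)]
  if (length(hit)) names(df)[hit[1]] else NULL
}

#' Read a COSMIC-style reference profile from delimited text
#'
#' Reads a tab-delimited cell-line mutation export and returns the
#' deduplicated profile for one cell line. Only single-base substitutions
#' are retained; rows whose `chrom:start-end` coordinate spans more than
#' one base are rejected as non-SNV. Profiles reported on the reverse
#' strand (optional `strand` column, value `-`) are normalised to
#' forward-strand alleles.
#'
#' Recognised columns (several aliases each, case-insensitive): cell line
#' (`cell_line`/`sample_name`), `gene`, `transcript`/`accession`, either a
#' combined `position` (`chrom:start-end`) or separate `chrom` + `pos`,
#' `ref`/`ref_allele`, `mut`/`mut_allele`/`alt`, optional `zygosity` and
#' `strand`.
#'
#' @param path Path to the delimited text file.
#' @param cell_line Cell line to extract. An absent cell line is an error
#'   of class `snvauth_no_profile` (distinct from an empty profile).
#' @param sep Field separator (default tab).
#' @return A [reference_profile()].
#' @export
read_reference_profile <- function(path, cell_line, sep = "\t") {
  if (!file.exists(path)) stop("profile file not found: ", path)
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                          check.names = FALSE, quote = "")
  cl_col <- find_column(df, c("cell_line", "sample_name", "sample"))
  if (is.null(cl_col)) stop("no cell-line column found in ", path)
  rows <- df[df[[cl_col]] == cell_line, , drop = FALSE]
  if (nrow(rows) == 0L)
    no_profile_error(paste0("no profile for cell line '", cell_line,
                            "' in ", path))

  pos_col <- find_column(rows, c("position", "mutation_genome_position",
                                 "genome_position"))
  if (!is.null(pos_col)) {
    m <- regmatches(rows[[pos_col]],
                    regexec("^([^:]+):([0-9]+)-([0-9]+)$", rows[[pos_col]]))
    bad <- lengths(m) != 4L
    if (any(bad))
      stop("unparseable coordinate '", rows[[pos_col]][which(bad)[1]],
           "' in row ", which(bad)[1])
    chrom <- vapply(m, `[`, character(1), 2)
    start <- as.integer(vapply(m, `[`, character(1), 3))
    end <- as.integer(vapply(m, `[`, character(1), 4))
    span_ok <- start == end
    pos <- start
  } else {
    c_col <- find_column(rows, c("chrom", "chromosome", "chr"))
    p_col <- find_column(rows, c("pos", "start"))
    if (is.null(c_col) || is.null(p_col))
      stop("no coordinate columns found in ", path)
    chrom <- as.character(rows[[c_col]])
    pos <- as.integer(rows[[p_col]])
    span_ok <- rep(TRUE, nrow(rows))
  }

  ref_col <- find_column(rows, c("ref", "ref_allele", "reference_allele", "wt"))
  mut_col <- find_column(rows, c("mut", "mut_allele", "mutant_allele", "alt"))
  if (is.null(ref_col) || is.null(mut_col))
    stop("no allele columns found in ", path)
  ref <- toupper(as.character(rows[[ref_col]]))
  mut <- toupper(as.character(rows[[mut_col]]))

  strand_col <- find_column(rows, c("strand", "mutation_strand"))
  if (!is.null(strand_col)) {
    minus <- rows[[strand_col]] == "-"
    ref[minus] <- complement_base(ref[minus])
    mut[minus] <- complement_base(mut[minus])
  }

  zyg_col <- find_column(rows, c("zygosity"))
  zyg <- if (is.null(zyg_col)) rep("unknown", nrow(rows))
         else tolower(as.character(rows[[zyg_col]]))
  zyg[!zyg %in% c("het", "hom")] <- "unknown"

  gene_col <- find_column(rows, c("gene", "gene_name"))
  tx_col <- find_column(rows, c("transcript", "accession_number", "accession"))

  keep <- span_ok & is_single_base(ref) & is_single_base(mut) & ref != mut
  variants <- data.frame(
    chrom = chrom[keep], pos = pos[keep], ref = ref[keep], mut = mut[keep],
    gene = if (is.null(gene_col)) NA_character_ else rows[[gene_col]][keep],
    transcript = if (is.null(tx_col)) NA_character_ else rows[[tx_col]][keep],
    zygosity = zyg[keep], stringsAsFactors = FALSE)
  prof <- reference_profile(cell_line, variants)
  prof$n_dropped <- sum(!keep)
  prof
}

#' Derive a reference profile from a filtered SNV profile
#'
#' Turns the alternate alleles called in an [`snv_profile`][build_profile]
#' into a reference profile (one variant per called non-reference allele).
#' Useful for transcriptome-scale profile building and for
#' self-consistency checks, where a profile compared against a reference
#' built from its own calls must be 100% concordant.
#'
#' @param profile An `snv_profile`.
#' @param cell_line Name to give the derived profile (default the
#'   profile's sample id).
#' @return A [reference_profile()].
#' @export
profile_as_reference <- function(profile, cell_line = profile$sample_id) {
  calls <- profile$calls
  rows <- lapply(seq_len(nrow(calls)), function(i) {
    muts <- setdiff(unique(called_alleles(calls, i)), calls$ref[i])
    if (length(muts) == 0L) return(NULL)
    data.frame(chrom = calls$chrom[i], pos = calls$pos[i], ref = calls$ref[i],
               mut = muts, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  variants <- if (length(rows)) do.call(rbind, rows)
              else data.frame(chrom = character(0), pos = integer(0),
                              ref = character(0), mut = character(0))
  reference_profile(cell_line, variants)
}
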