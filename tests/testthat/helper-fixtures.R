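# Fixture builders and independent brute-force oracles used across tests.

vcf_fixture_header <- function(sample = "S1") {
  c("##fileformat=VCFv4.2",
    "##contig=<ID=chrS,length=1000000>",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"fs\">",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"qd\">",
    "##INFO=<ID=ANN,Number=.,Type=String,Description=\"ann\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"ad\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample))
}

write_vcf_fixture <- function(records, sample = "S1",
                              path = withr::local_tempfile(fileext = ".vcf",
                                .local_envir = parent.frame())) {
  writeLines(c(vcf_fixture_header(sample), records), path)
  path
}

write_sam_fixture <- function(records,
                              path = withr::local_tempfile(fileext = ".sam",
                                .local_envir = parent.frame())) {
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               "@SQ\tSN:chrS\tLN:1000000", records), path)
  path
}

sam_read <- function(id, pos, seq, cigar = paste0(nchar(seq), "M"),
                     flag = 0, chrom = "chrS") {
  sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
          id, flag, if (flag == 4) "*" else chrom,
          if (flag == 4) 0 else pos, if (flag == 4) "*" else cigar,
          seq, strrep("I", nchar(seq)))
}

# quick annotated ANN string
ann_str <- function(alt = "G", effect = "missense_variant",
                    impact = "MODERATE", gene = "G1", tx = "T1") {
  sprintf("%s|%s|%s|%s|%s|transcript|%s|protein_coding",
          alt, effect, impact, gene, gene, tx)
}

# snv_calls row annotated on (possibly several) transcripts
annotated_call <- function(pos, impact = "MODERATE", tx = "T1",
                           effect = "missense", ref = "A", alt = "G",
                           gt = "0/1", ad = c(10L, 10L), fs = 5, qd = 10) {
  ann <- data.frame(transcript = tx, gene = paste0("G_", tx),
                    effect = effect, impact = impact,
                    stringsAsFactors = FALSE)
  variant_call("chrS", pos, ref, alt, gt = gt, ad = ad, fs = fs, qd = qd,
               ann = ann)
}

# wrap a calls table in an snv_profile without running the filter stack
as_profile <- function(calls, sample_id = "test") {
  structure(list(sample_id = sample_id, calls = calls,
                 n_input_calls = nrow(calls),
                 filter_log = integer(0)),
            class = "snv_profile")
}

empty_calls_fixture <- function() variant_call("chrS", 1, "A", "G")[0, ]

# random SNV calls at distinct positions (pass all filters by default)
random_calls <- function(n, positions = sample.int(100000, n),
                         chrom = "chrS") {
  bases <- c("A", "C", "G", "T")
  rows <- lapply(seq_len(n), function(i) {
    ref <- sample(bases, 1)
    alt <- sample(setdiff(bases, ref), 1)
    gt <- sample(c("0/1", "1/1"), 1)
    variant_call(chrom, positions[i], ref, alt, gt = gt,
                 ad = c(10L, 10L), fs = 5, qd = 10)
  })
  bind_calls(rows)
}

# random reference profile over candidate positions
random_reference <- function(n, positions = sample.int(100000, n),
                             chrom = "chrS", cell_line = "REF") {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  mut <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  reference_profile(cell_line, data.frame(
    chrom = chrom, pos = positions, ref = ref, mut = mut,
    stringsAsFactors = FALSE))
}

# --- independent oracles ----------------------------------------------

# all-windows cluster scan: for every integer window start, count SNVs in
# [s, s + window - 1]; every SNV inside any window holding >= k is removed
oracle_cluster_removed <- function(positions, window = 35L, k = 3L) {
  if (length(positions) == 0L) return(integer(0))
  removed <- logical(length(positions))
  for (s in (min(positions) - window):(max(positions))) {
    inside <- positions >= s & positions <= s + window - 1L
    if (sum(inside) >= k) removed <- removed | inside
  }
  positions[removed]
}

# position-by-position comparison: for every profile call, look up all
# reference variants at that position and match allele-wise
oracle_compare <- function(calls, refv) {
  n_overlap <- 0L
  n_match <- 0L
  for (i in seq_len(nrow(calls))) {
    at <- which(refv$chrom == calls$chrom[i] & refv$pos == calls$pos[i])
    if (length(at) == 0L) next
    n_overlap <- n_overlap + 1L
    alleles <- c(calls$ref[i], calls$alt[[i]])
    idx <- as.integer(strsplit(calls$gt[i], "[/|]")[[1]])
    called <- alleles[idx + 1L]
    if (any(refv$mut[at] %in% called)) n_match <- n_match + 1L
  }
  list(n_overlap = n_overlap, n_match = n_match)
}

extdata <- function(name) {
  f <- system.file("extdata", name, package = "snvauth")
  stopifnot(nzchar(f))
  f
}
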