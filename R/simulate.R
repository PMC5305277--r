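#' Simulation configuration
#'
#' Parameters of the synthetic-data generator that emulates every input
#' the pipeline consumes, with controlled ground truth. Defaults emulate
#' the statistical structure of a well-behaved authentic RNA-seq
#' experiment: about 40% of the reference variants expressed, a 2%
#' genotype-discordance rate at covered positions, negative-binomial
#' per-site depths, and two-site haplotype read ratios near 1:1:1.
#'
#' @param n_reference_variants Unique reference SNVs (default 1000).
#' @param expressed_fraction Probability a reference position receives a
#'   call (default 0.4).
#' @param depth_mean,depth_dispersion Negative-binomial per-site depth
#'   model (default mean 60, dispersion 4).
#' @param discordance_rate Probability a covered reference position
#'   carries a non-matching genotype (default 0.02); planted half as a
#'   wrong alternate allele and half as a homozygous-reference call.
#' @param contaminant_fraction Admixture level of a contaminant profile
#'   (default 0).
#' @param cluster_injection Planted 3-SNVs-in-35-bp clusters (default 5).
#' @param indel_injection Planted indel records (default 20).
#' @param n_low_depth Planted calls with total depth below 10 (default
#'   10).
#' @param n_shadow_pairs Planted transcript pairs carrying one HIGH- and
#'   one LOW-impact variant, exercising highest-impact selection
#'   (default 5).
#' @param fs_fail_rate,qd_fail_rate Fractions of alt-carrying calls
#'   drawn with a failing strand-bias / quality-by-depth statistic
#'   (default 0.02 each).
#' @param n_background Calls planted at non-reference positions
#'   (default 500).
#' @param annotation_mix Proportions over impact levels (must sum to 1).
#' @param effect_mix Proportions over effect classes (must sum to 1).
#' @param haplotype_ratios Proportions over the four joint-allele
#'   categories for read generation (default 1:1:1:0).
#' @param n_reads Reads emitted by [generate_reads()] (default 300).
#' @param read_length Read length in bases (default 76).
#' @param uninformative_fraction Fraction of reads covering only one
#'   site (default 0.05).
#' @param other_base_fraction Fraction of two-site reads carrying a
#'   third base at a site (default 0.02).
#' @param genome_length Length of the single toy chromosome (default
#'   2e7).
#' @param chrom Toy chromosome name (default `"chrS"`).
#' @param grid_offset Offset (0-99) of the 100-bp position grid sites are
#'   drawn from. Profiles generated on different offsets occupy disjoint
#'   position sets, which gives contaminant screens an exact zero
#'   baseline; the same offset lets profiles share positions, as related
#'   cell lines do.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_reference_variants = 1000L,
                       expressed_fraction = 0.4,
                       depth_mean = 60, depth_dispersion = 4,
                       discordance_rate = 0.02,
                       contaminant_fraction = 0,
                       cluster_injection = 5L,
                       indel_injection = 20L,
                       n_low_depth = 10L,
                       n_shadow_pairs = 5L,
                       fs_fail_rate = 0.02, qd_fail_rate = 0.02,
                       n_background = 500L,
                       annotation_mix = c(HIGH = 0.027, MODERATE = 0.709,
                                          LOW = 0.259, MODIFIER = 0.005),
                       effect_mix = c(missense = 0.707, nonsense = 0.025,
                                      synonymous = 0.268),
                       haplotype_ratios = c(wt_wt = 1/3, wt_mut = 1/3,
                                            mut_wt = 1/3, mut_mut = 0),
                       n_reads = 300L, read_length = 76L,
                       uninformative_fraction = 0.05,
                       other_base_fraction = 0.02,
                       genome_length = 2e7, chrom = "chrS",
                       grid_offset = 0L) {
  probs <- c(expressed_fraction, discordance_rate, contaminant_fraction,
             fs_fail_rate, qd_fail_rate, uninformative_fraction,
             other_base_fraction)
  stopifnot(all(probs >= 0 & probs <= 1),
            abs(sum(annotation_mix) - 1) < 1e-8,
            abs(sum(effect_mix) - 1) < 1e-8,
            abs(sum(haplotype_ratios) - 1) < 1e-8,
            depth_mean > 0, depth_dispersion > 0,
            n_reference_variants >= 0,
            grid_offset >= 0, grid_offset <= 99)
  structure(as.list(environment()), class = "sim_config")
}

# Disjoint position pools on a 100-bp grid: with all planted sites at
# least 100 bp apart, SNV clusters exist only where explicitly planted.
allocate_positions <- function(config, n_needed) {
  slots <- seq(500L + as.integer(config$grid_offset),
               as.integer(config$genome_length) - 500L, by = 100L)
  if (n_needed > length(slots))
    stop("toy genome too short for the requested number of sites")
  sort(sample(slots, n_needed))
}

random_bases <- function(n) sample(DNA_BASES, n, replace = TRUE)

# uniform integer in [a, b] (safe for b == a, unlike sample(seq(a, b), 1))
sample_int_range <- function(a, b) {
  stopifnot(b >= a)
  a + sample.int(b - a + 1L, 1L) - 1L
}

other_base <- function(exclude) {
  vapply(exclude, function(e) sample(setdiff(DNA_BASES, strsplit(e, "")[[1]]), 1),
         character(1))
}

#' Generate a synthetic reference cell-line profile
#'
#' Emits `n_reference_variants` unique single-base substitutions at
#' distinct positions on the toy chromosome. When `path` is given, a
#' COSMIC-style TSV is written; `n_duplicate_rows` extra rows replicate
#' existing mutations on a second transcript (in the file only), so the
#' reader's deduplication can be exercised.
#'
#' @param config A [sim_config()].
#' @param cell_line Cell line name (default `"SYNTH1"`).
#' @param path Optional output TSV path.
#' @param seed Integer RNG seed; generation is deterministic given the
#'   seed.
#' @param n_duplicate_rows Duplicated-transcript rows to inject into the
#'   written file (default 0).
#' @return A [reference_profile()] (with the file path in attribute
#'   `path` when written).
#' @export
generate_reference_profile <- function(config = sim_config(),
                                       cell_line = "SYNTH1", path = NULL,
                                       seed = 1L, n_duplicate_rows = 0L) {
  n <- config$n_reference_variants
  prof <- with_seed(seed, {
    pos <- allocate_positions(config, n)
    ref <- random_bases(n)
    mut <- other_base(ref)
    variants <- data.frame(
      chrom = rep(config$chrom, n), pos = pos, ref = ref, mut = mut,
      gene = sprintf("GENE%05d", seq_len(n)),
      transcript = sprintf("TX%05d", seq_len(n)),
      zygosity = sample(c("het", "hom"), n, replace = TRUE,
                        prob = c(0.6, 0.4)),
      stringsAsFactors = FALSE)
    reference_profile(cell_line, variants)
  })
  if (!is.null(path)) {
    v <- prof$variants
    if (n_duplicate_rows > 0L && nrow(v) > 0L) {
      dup <- v[with_seed(seed + 1L,
                         sample(nrow(v), min(n_duplicate_rows, nrow(v)))), ,
               drop = FALSE]
      dup$transcript <- paste0(dup$transcript, "b")
      v <- rbind(v, dup)
      v <- v[order(v$pos), , drop = FALSE]
    }
    out <- data.frame(cell_line = rep(cell_line, nrow(v)), gene = v$gene,
                      transcript = v$transcript,
                      position = sprintf("%s:%d-%d", v$chrom, v$pos, v$pos),
                      ref = v$ref, mut = v$mut, zygosity = v$zygosity,
                      stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    attr(prof, "path") <- path
  }
  prof
}

vcf_header <- function(config, sample_id) {
  c("##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", config$chrom,
            as.integer(config$genome_length)),
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Phred-scaled p-value using Fisher's exact test to detect strand bias\">",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Variant Confidence/Quality by Depth\">",
    "##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional annotations: 'Allele | Annotation | Annotation_Impact | Gene_Name | Gene_ID | Feature_Type | Feature_ID | Transcript_BioType'\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths for the ref and alt alleles\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           sample_id))
}

EFFECT_TERMS <- c(missense = "missense_variant", nonsense = "stop_gained",
                  synonymous = "synonymous_variant",
                  other = "upstream_gene_variant")

ann_string <- function(alt, effect, impact, gene, transcript) {
  sprintf("%s|%s|%s|%s|%s|transcript|%s|protein_coding",
          alt, EFFECT_TERMS[[effect]], impact, gene, gene, transcript)
}

passing_fs <- function(n) round(stats::runif(n, 0, 25), 3)
failing_fs <- function(n) round(stats::runif(n, 30.5, 80), 3)
passing_qd <- function(n) round(stats::runif(n, 2.5, 35), 2)
failing_qd <- function(n) round(stats::runif(n, 0.1, 1.9), 2)

#' Generate a synthetic VCF with known ground truth
#'
#' Emits a single-sample VCF realising the configured study conditions:
#' an `expressed_fraction` of the reference profile's positions receive
#' calls with negative-binomial depths; a `discordance_rate` of covered
#' positions get a wrong alternate allele or a homozygous-reference
#' genotype (half/half); a `contaminant_fraction` of an optional second
#' profile's variants are admixed; and failing-quality, clustered,
#' indel, low-depth and impact-shadowed calls are planted per the
#' configuration. Each variant is annotated on its own transcript
#' (planted shadow pairs excepted), so downstream filter fates are
#' exactly determined by the plant.
#'
#' @param config A [sim_config()].
#' @param reference A [reference_profile()] from
#'   [generate_reference_profile()].
#' @param path Output VCF path.
#' @param seed Integer RNG seed.
#' @param contaminant Optional contaminant [reference_profile()].
#' @param sample_id Sample column name (default the reference cell
#'   line).
#' @return Invisibly, a list with `path` and `truth` (a data frame with
#'   one row per emitted record: position, `origin`, `expressed`,
#'   `discordant`, `discord_mode`, written genotype and alleles).
#' @export
generate_vcf <- function(config, reference, path, seed = 1L,
                         contaminant = NULL,
                         sample_id = reference$cell_line) {
  refv <- reference$variants
  recs <- with_seed(seed, {
    rows <- list()
    used <- pos_key(refv$chrom, refv$pos)

    add <- function(rows, chrom, pos, ref, alt, gt, ad, fs, qd, ann,
                    origin, discordant = FALSE, discord_mode = "") {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, pos = pos, ref = ref,
        alt = if (length(alt)) paste(alt, collapse = ",") else ".",
        gt = gt, ad = paste(ad, collapse = ","),
        fs = fs, qd = qd, ann = ann, origin = origin,
        discordant = discordant, discord_mode = discord_mode,
        stringsAsFactors = FALSE)
      rows
    }

    # --- calls at reference-profile positions -------------------------
    n <- nrow(refv)
    expressed <- stats::runif(n) < config$expressed_fraction
    for (i in which(expressed)) {
      depth <- stats::rnbinom(1, size = config$depth_dispersion,
                              mu = config$depth_mean)
      discordant <- stats::runif(1) < config$discordance_rate
      dmode <- if (discordant) sample(c("hom_ref", "wrong_allele"), 1) else ""
      fs <- if (stats::runif(1) < config$fs_fail_rate) failing_fs(1)
            else passing_fs(1)
      qd <- if (stats::runif(1) < config$qd_fail_rate) failing_qd(1)
            else passing_qd(1)
      if (discordant && dmode == "hom_ref") {
        rows <- add(rows, refv$chrom[i], refv$pos[i], refv$ref[i],
                    character(0), "0/0", depth, NA, NA, NA,
                    origin = "reference", discordant = TRUE,
                    discord_mode = dmode)
        next
      }
      alt <- if (discordant) other_base(paste0(refv$ref[i], refv$mut[i]))
             else refv$mut[i]
      if (!discordant && refv$zygosity[i] == "hom") {
        ad <- c(0L, depth)
        gt <- "1/1"
      } else {
        ad_alt <- stats::rbinom(1, depth, 0.5)
        ad <- c(depth - ad_alt, ad_alt)
        gt <- "0/1"
      }
      ann <- ann_string(alt, sample(names(config$effect_mix), 1,
                                    prob = config$effect_mix),
                        sample(names(config$annotation_mix), 1,
                               prob = config$annotation_mix),
                        refv$gene[i], refv$transcript[i])
      rows <- add(rows, refv$chrom[i], refv$pos[i], refv$ref[i], alt, gt,
                  ad, fs, qd, ann, origin = "reference",
                  discordant = discordant, discord_mode = dmode)
    }

    # --- contaminant admixture ---------------------------------------
    if (!is.null(contaminant) && config$contaminant_fraction > 0) {
      cv <- contaminant$variants
      cv <- cv[!pos_key(cv$chrom, cv$pos) %in% used, , drop = FALSE]
      p_cont <- config$expressed_fraction * config$contaminant_fraction
      for (i in which(stats::runif(nrow(cv)) < p_cont)) {
        depth <- stats::rnbinom(1, size = config$depth_dispersion,
                                mu = config$depth_mean)
        ad_alt <- stats::rbinom(1, depth, 0.5)
        rows <- add(rows, cv$chrom[i], cv$pos[i], cv$ref[i], cv$mut[i],
                    "0/1", c(depth - ad_alt, ad_alt), passing_fs(1),
                    passing_qd(1),
                    ann_string(cv$mut[i], "missense", "MODERATE",
                               "CONTGENE", sprintf("CONTTX%05d", i)),
                    origin = "contaminant")
      }
    }

    # --- planted background / cluster / indel / low-depth / shadow ---
    n_extra <- config$n_background + config$cluster_injection +
      config$indel_injection + config$n_low_depth +
      2L * config$n_shadow_pairs
    avoid <- refv$pos
    if (!is.null(contaminant)) avoid <- c(avoid, contaminant$variants$pos)
    extra <- setdiff(allocate_positions(config, n_extra + length(avoid)),
                     avoid)[seq_len(n_extra)]
    extra <- sample(extra)  # decouple role from genomic order
    take <- function(k) {
      out <- extra[seq_len(k)]
      extra <<- extra[-seq_len(k)]
      out
    }

    bg <- take(config$n_background)
    for (j in seq_along(bg)) {
      ref <- random_bases(1)
      alt <- other_base(ref)
      depth <- stats::rnbinom(1, size = config$depth_dispersion,
                              mu = config$depth_mean)
      ad_alt <- stats::rbinom(1, depth, 0.5)
      rows <- add(rows, config$chrom, bg[j], ref, alt, "0/1",
                  c(depth - ad_alt, ad_alt), passing_fs(1), passing_qd(1),
                  ann_string(alt, sample(names(config$effect_mix), 1,
                                         prob = config$effect_mix),
                             sample(names(config$annotation_mix), 1,
                                    prob = config$annotation_mix),
                             sprintf("BGGENE%05d", j),
                             sprintf("BGTX%05d", j)),
                  origin = "background")
    }

    anchors <- take(config$cluster_injection)
    for (j in seq_along(anchors)) {
      for (off in c(0L, 12L, 24L)) {
        ref <- random_bases(1)
        alt <- other_base(ref)
        rows <- add(rows, config$chrom, anchors[j] + off, ref, alt, "0/1",
                    c(20L, 20L), passing_fs(1), passing_qd(1),
                    ann_string(alt, "missense", "MODERATE",
                               sprintf("CLGENE%03d", j),
                               sprintf("CLTX%03d_%d", j, off)),
                    origin = "cluster")
      }
    }

    ind <- take(config$indel_injection)
    for (j in seq_along(ind)) {
      b <- random_bases(1)
      rows <- add(rows, config$chrom, ind[j], paste0(b, "T"), b, "0/1",
                  c(15L, 15L), passing_fs(1), passing_qd(1), NA,
                  origin = "indel")
    }

    ld <- take(config$n_low_depth)
    for (j in seq_along(ld)) {
      ref <- random_bases(1)
      alt <- other_base(ref)
      depth <- sample(1:9, 1)
      ad_alt <- stats::rbinom(1, depth, 0.5)
      rows <- add(rows, config$chrom, ld[j], ref, alt, "0/1",
                  c(depth - ad_alt, ad_alt), passing_fs(1), passing_qd(1),
                  ann_string(alt, "missense", "MODERATE",
                             sprintf("LDGENE%03d", j),
                             sprintf("LDTX%03d", j)),
                  origin = "low_depth")
    }

    sh <- take(2L * config$n_shadow_pairs)
    for (j in seq_len(config$n_shadow_pairs)) {
      tx <- sprintf("SHTX%03d", j)
      gene <- sprintf("SHGENE%03d", j)
      for (k in 1:2) {
        ref <- random_bases(1)
        alt <- other_base(ref)
        impact <- if (k == 1) "HIGH" else "LOW"
        effect <- if (k == 1) "nonsense" else "synonymous"
        rows <- add(rows, config$chrom, sh[2L * (j - 1L) + k], ref, alt,
                    "0/1", c(20L, 20L), passing_fs(1), passing_qd(1),
                    ann_string(alt, effect, impact, gene, tx),
                    origin = if (k == 1) "shadow_high" else "shadow_low")
      }
    }

    do.call(rbind, rows)
  })

  recs <- recs[order(recs$chrom, recs$pos), , drop = FALSE]
  info <- ifelse(is.na(recs$fs), ".",
                 sprintf("FS=%s;QD=%s%s", recs$fs, recs$qd,
                         ifelse(is.na(recs$ann), "",
                                paste0(";ANN=", recs$ann))))
  lines <- sprintf("%s\t%d\t.\t%s\t%s\t100\tPASS\t%s\tGT:AD\t%s:%s",
                   recs$chrom, recs$pos, recs$ref, recs$alt, info,
                   recs$gt, recs$ad)
  writeLines(c(vcf_header(config, sample_id), lines), path)

  truth <- recs[, c("chrom", "pos", "ref", "alt", "gt", "ad", "origin",
                    "discordant", "discord_mode")]
  truth$expressed <- TRUE
  rownames(truth) <- NULL
  invisible(list(path = path, truth = truth))
}

#' Generate synthetic two-site reads in SAM layout
#'
#' Emits `n_reads` single-end alignments spanning the two haplotype
#' sites, with joint-allele categories drawn from
#' `config$haplotype_ratios`. A configurable fraction covers only the
#' first site (uninformative) and another carries a third base at the
#' first site (`other`). Bases away from the sites are the wild-type
#' backbone base `A`.
#'
#' @param config A [sim_config()].
#' @param siteA,siteB [haplotype_site()] objects on the same chromosome,
#'   within `read_length` of each other.
#' @param path Output SAM path.
#' @param seed Integer RNG seed.
#' @return Invisibly, a list with `path` and `truth` (per-read planted
#'   category).
#' @export
generate_reads <- function(config, siteA, siteB, path, seed = 1L) {
  stopifnot(siteA$chrom == siteB$chrom)
  lo <- min(siteA$pos, siteB$pos)
  hi <- max(siteA$pos, siteB$pos)
  span <- hi - lo + 1L
  L <- as.integer(config$read_length)
  if (span > L) stop("sites further apart than the read length")
  n <- as.integer(config$n_reads)

  out <- with_seed(seed, {
    category <- if (n > 0)
      sample(names(config$haplotype_ratios), n, replace = TRUE,
             prob = config$haplotype_ratios) else character(0)
    uninf <- stats::runif(n) < config$uninformative_fraction
    other <- !uninf & stats::runif(n) < config$other_base_fraction
    planted <- category
    planted[uninf] <- "uninformative"
    planted[other] <- "other"

    lines <- character(n)
    for (i in seq_len(n)) {
      if (uninf[i]) {
        # cover siteA only, leaving siteB outside the read
        if (siteA$pos < siteB$pos)
          start <- sample_int_range(max(1L, siteA$pos - L + 1L),
                                    min(siteA$pos, siteB$pos - L))
        else
          start <- sample_int_range(max(siteB$pos + 1L, siteA$pos - L + 1L),
                                    siteA$pos)
      } else {
        start <- hi - L + sample.int(L - span + 1L, 1)
      }
      seq_bases <- rep("A", L)
      put <- function(bases, site, state) {
        off <- site$pos - start + 1L
        if (off >= 1L && off <= L)
          bases[off] <- switch(state, wt = site$wt, mut = site$mut,
                               other = other_base(paste0(site$wt, site$mut)))
        bases
      }
      states <- strsplit(category[i], "_", fixed = TRUE)[[1]]
      stateA <- if (other[i]) "other" else states[1]
      seq_bases <- put(seq_bases, siteA, stateA)
      seq_bases <- put(seq_bases, siteB, states[2])
      lines[i] <- sprintf("read%05d\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
                          i, siteA$chrom, start, L,
                          paste(seq_bases, collapse = ""), strrep("I", L))
    }
    list(lines = lines, planted = planted)
  })

  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", siteA$chrom,
                      max(as.integer(config$genome_length), hi + 2L * L)))
  writeLines(c(header, out$lines), path)
  invisible(list(path = path,
                 truth = data.frame(read_id = sprintf("read%05d", seq_len(n)),
                                    category = out$planted,
                                    stringsAsFactors = FALSE)))
}

#' Generate a synthetic SNP genotyping panel
#'
#' Draws `n_loci` loci among the reference profile's positions and sets
#' the expected genotype to the simulated sample's true genotype there
#' (from the VCF ground truth when the position was expressed, from the
#' reference zygosity otherwise), emulating a panel a matching cell line
#' passes at 100% concordance.
#'
#' @param reference A [reference_profile()].
#' @param truth Ground-truth data frame from [generate_vcf()].
#' @param cell_line Cell line name for the panel rows.
#' @param n_loci Number of panel loci (default 48).
#' @param path Optional output TSV path.
#' @param seed Integer RNG seed.
#' @return An [`snp_panel`][read_panel] data frame.
#' @export
generate_panel <- function(reference, truth, cell_line = reference$cell_line,
                           n_loci = 48L, path = NULL, seed = 1L) {
  refv <- reference$variants
  stopifnot(n_loci <= nrow(refv))
  panel <- with_seed(seed, {
    pick <- sort(sample(nrow(refv), n_loci))
    v <- refv[pick, , drop = FALSE]
    g <- character(n_loci)
    tkey <- pos_key(truth$chrom, truth$pos)
    for (j in seq_len(n_loci)) {
      hit <- match(pos_key(v$chrom[j], v$pos[j]), tkey)
      if (!is.na(hit)) {
        alt <- if (truth$alt[hit] == ".") character(0)
               else strsplit(truth$alt[hit], ",", fixed = TRUE)[[1]]
        alleles <- c(truth$ref[hit], alt)
        idx <- gt_indices(truth$gt[hit])
        pair <- alleles[idx + 1L]
        if (length(pair) == 1L) pair <- rep(pair, 2L)
      } else {
        pair <- if (v$zygosity[j] == "hom") rep(v$mut[j], 2L)
                else c(v$ref[j], v$mut[j])
      }
      g[j] <- paste(sort(pair), collapse = "/")
    }
    df <- data.frame(locus_id = sprintf("rs9%06d", pick),
                     chrom = v$chrom, pos = v$pos,
                     cell_line = cell_line, genotype = g,
                     stringsAsFactors = FALSE)
    class(df) <- c("snp_panel", "data.frame")
    df
  })
  if (!is.null(path)) write_panel(panel, path)
  panel
}
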