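ref_var <- function(pos, ref = "C", mut = "A", zygosity = "unknown",
                    chrom = "chrS") {
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, mut = mut,
             zygosity = zygosity, stringsAsFactors = FALSE)
}

test_that("match_genotype scores alleles and hom-ref calls correctly", {
  het <- variant_call("chrS", 100, "C", "A", gt = "0/1")
  expect_equal(match_genotype(het, ref_var(100)), "match")
  # hom-ref at a reference-mutation position is a mismatch
  hr <- variant_call("chrS", 100, "C", gt = "0/0", ad = 25L)
  expect_equal(match_genotype(hr, ref_var(100)), "mismatch")
  # wrong alternate allele
  wrong <- variant_call("chrS", 100, "C", "T", gt = "0/1")
  expect_equal(match_genotype(wrong, ref_var(100)), "mismatch")
  # positions must agree
  expect_error(match_genotype(het, ref_var(101)), "positions disagree")
})

test_that("strict mode additionally requires zygosity agreement", {
  hom_alt <- variant_call("chrS", 100, "C", "A", gt = "1/1", ad = c(0L, 20L))
  het <- variant_call("chrS", 100, "C", "A", gt = "0/1")
  expect_equal(match_genotype(hom_alt, ref_var(100, zygosity = "het")),
               "match")  # allele mode ignores zygosity
  expect_equal(match_genotype(hom_alt, ref_var(100, zygosity = "het"),
                              mode = "strict"), "mismatch")
  expect_equal(match_genotype(het, ref_var(100, zygosity = "het"),
                              mode = "strict"), "match")
  expect_equal(match_genotype(het, ref_var(100, zygosity = "hom"),
                              mode = "strict"), "mismatch")
  expect_equal(match_genotype(het, ref_var(100, zygosity = "unknown"),
                              mode = "strict"), "match")
})

test_that("compare_to_reference reproduces the printed worked example", {
  # reference of 241 unique variants, 68 overlapping positions, 67 matching
  ref <- random_reference(241, positions = seq(1000L, 241000L, by = 1000L),
                          cell_line = "COLO205")
  rv <- ref$variants
  calls <- bind_calls(lapply(1:68, function(i) {
    if (i <= 67)
      variant_call(rv$chrom[i], rv$pos[i], rv$ref[i], rv$mut[i], gt = "0/1")
    else  # one hom-ref mismatch
      variant_call(rv$chrom[i], rv$pos[i], rv$ref[i], gt = "0/0", ad = 25L)
  }))
  res <- compare_to_reference(as_profile(calls, "colo"), ref)
  expect_equal(res$n_reference, 241L)
  expect_equal(res$n_overlap, 68L)
  expect_equal(res$n_match, 67L)
  expect_equal(round_half_up(100 * res$coverage, 1), 28.2)
  expect_equal(round_half_up(100 * res$concordance, 1), 98.5)
})

test_that("comparison degenerate cases behave as specified", {
  ref <- random_reference(10, positions = seq(100L, 1000L, by = 100L))
  rv <- ref$variants
  all_match <- bind_calls(lapply(1:4, function(i)
    variant_call(rv$chrom[i], rv$pos[i], rv$ref[i], rv$mut[i], gt = "0/1")))
  res <- compare_to_reference(as_profile(all_match), ref)
  expect_equal(round_half_up(100 * res$coverage, 1), 40.0)
  expect_equal(res$concordance, 1)

  # zero overlap: coverage 0, concordance undefined (NA, never 0)
  off <- as_profile(variant_call("chrS", 99999, "A", "G", gt = "0/1"))
  res0 <- compare_to_reference(off, ref)
  expect_equal(res0$coverage, 0)
  expect_true(is.na(res0$concordance))

  # empty reference is an error distinct from an empty result
  empty_ref <- reference_profile("EMPTY", data.frame(
    chrom = character(0), pos = integer(0), ref = character(0),
    mut = character(0), stringsAsFactors = FALSE))
  expect_error(compare_to_reference(off, empty_ref),
               class = "snvauth_no_profile")
})

test_that("compare_to_reference agrees with the brute-force oracle", {
  set.seed(99)
  for (rep in 1:120) {
    n_ref <- sample(1:120, 1)
    n_calls <- sample(0:120, 1)
    pool <- sample.int(300, 150)
    ref <- random_reference(n_ref, positions = sample(pool, n_ref))
    calls <- if (n_calls > 0)
      random_calls(n_calls, positions = sample(pool, n_calls))
    else empty_calls_fixture()
    res <- compare_to_reference(as_profile(calls), ref)
    want <- oracle_compare(calls, ref$variants)
    expect_equal(res$n_overlap, want$n_overlap)
    expect_equal(res$n_match, want$n_match)
    expect_equal(res$n_match + res$n_mismatch, res$n_overlap)
  }
})

test_that("a profile is 100% concordant with a reference built from itself", {
  set.seed(5)
  calls <- random_calls(50)
  prof <- as_profile(calls, "self")
  res <- compare_to_reference(prof, profile_as_reference(prof))
  expect_equal(res$concordance, 1)
  expect_equal(res$n_mismatch, 0L)
})

test_that("uncalled reference additions lower coverage but not concordance", {
  set.seed(8)
  calls <- random_calls(30, positions = seq(100L, 3000L, by = 100L))
  prof <- as_profile(calls)
  ref <- profile_as_reference(prof)
  base <- compare_to_reference(prof, ref)
  extra <- rbind(ref$variants,
                 data.frame(chrom = "chrS", pos = seq(50000L, 50900L, 100L),
                            ref = "A", mut = "G", gene = NA, transcript = NA,
                            zygosity = "unknown", stringsAsFactors = FALSE))
  grown <- compare_to_reference(prof, reference_profile("R2", extra))
  expect_lt(grown$coverage, base$coverage)
  expect_equal(grown$concordance, base$concordance)
})

test_that("contamination screens report evidence levels, not bare verdicts", {
  ref <- random_reference(20, positions = seq(100L, 2000L, by = 100L),
                          cell_line = "HeLa")
  rv <- ref$variants
  # overlap 2, no matches: clean, no flag
  two_mismatch <- bind_calls(lapply(1:2, function(i)
    variant_call(rv$chrom[i], rv$pos[i], rv$ref[i], gt = "0/0", ad = 25L)))
  s <- screen_contaminant(as_profile(two_mismatch), ref)
  expect_false(s$contamination)
  expect_equal(s$status, "clean")
  expect_equal(s$type, "screen")
  # overlap 0: indeterminate, never clean
  s0 <- screen_contaminant(as_profile(variant_call("chrS", 77777, "A", "G",
                                                   gt = "0/1")), ref)
  expect_equal(s0$status, "indeterminate")
  expect_false(s0$contamination)
  # overlap 5, matches 5: warning
  five <- bind_calls(lapply(1:5, function(i)
    variant_call(rv$chrom[i], rv$pos[i], rv$ref[i], rv$mut[i], gt = "0/1")))
  s5 <- screen_contaminant(as_profile(five), ref)
  expect_true(s5$contamination)
  expect_equal(s5$status, "warning")
})

test_that("panel comparison counts covered loci and unordered genotype matches", {
  panel <- data.frame(
    locus_id = paste0("rs", 1:4), chrom = "chrS",
    pos = c(100L, 200L, 300L, 400L), cell_line = "X",
    genotype = c("A/G", "C/C", "G/T", "A/A"), stringsAsFactors = FALSE)
  class(panel) <- c("snp_panel", "data.frame")
  calls <- bind_calls(
    variant_call("chrS", 100, "A", "G", gt = "0/1"),          # het matches A/G
    variant_call("chrS", 200, "C", gt = "0/0", ad = 25L),     # hom-ref C/C
    variant_call("chrS", 300, "G", "C", gt = "0/1"))          # C/G != G/T
  res <- compare_to_panel(as_profile(calls), panel, "X")
  expect_equal(res$n_panel, 4L)
  expect_equal(res$n_overlap, 3L)
  expect_equal(res$n_match, 2L)
  expect_error(compare_to_panel(as_profile(calls), panel, "NOPE"),
               class = "snvauth_no_profile")
})

test_that("pairwise concordance has an exact diagonal and fractional matches", {
  a <- as_profile(bind_calls(
    variant_call("chrS", 100, "A", "G", gt = "0/1"),
    variant_call("chrS", 200, "C", "T", gt = "0/1"),
    variant_call("chrS", 300, "G", "A", gt = "0/1")), "a")
  b <- as_profile(bind_calls(
    variant_call("chrS", 100, "A", "G", gt = "0/1"),
    variant_call("chrS", 200, "C", "T", gt = "1/0"),  # same set, swapped order
    variant_call("chrS", 300, "G", "C", gt = "0/1"),  # different allele
    variant_call("chrS", 400, "T", "C", gt = "0/1")), "b")
  m <- pairwise_concordance(list(a = a, b = b))
  expect_equal(diag(unclass(m)), c(a = 1, b = 1))
  # allele sets: positions 100 and 200 agree, 300 does not: 2/3 -> 66.7%
  expect_equal(round_half_up(100 * m["a", "b"], 1), 66.7)
  expect_equal(m["a", "b"], m["b", "a"])
  # genotype-string mode additionally splits the swapped 1/0 at position 200
  g <- pairwise_concordance(list(a = a, b = b), mode = "genotype")
  expect_equal(round_half_up(100 * g["a", "b"], 1), 33.3)
})

test_that("characterize assigns each call its single highest-impact annotation", {
  m1 <- annotated_call(100, "HIGH", "T1", effect = "nonsense")
  m2 <- variant_call("chrS", 200, "A", "G", gt = "0/1",
    ann = data.frame(transcript = c("Ta", "Tb"), gene = "G",
                     effect = c("synonymous", "missense"),
                     impact = c("LOW", "MODERATE"), stringsAsFactors = FALSE))
  mm <- annotated_call(300, "MODIFIER", "T3", effect = "other")
  tab <- characterize(bind_calls(m1, m2), mm)
  imp <- tab$impact
  expect_equal(imp$match[imp$category == "HIGH"], 1L)
  expect_equal(imp$match[imp$category == "MODERATE"], 1L)  # Tb wins for m2
  expect_equal(imp$match[imp$category == "LOW"], 0L)
  expect_equal(imp$mismatch[imp$category == "MODIFIER"], 1L)
  expect_equal(sum(imp$match), 2L)
  expect_equal(sum(tab$effect$match), 2L)
  expect_equal(sum(imp$match_prop), 1)
})

test_that("characterisation proportions reproduce the printed percentages", {
  counts <- utils::read.delim(extdata("snv_characterisation_counts.tsv"))
  imp <- counts[counts$table == "impact", ]
  eff <- counts[counts$table == "effect", ]
  tab <- characterization_table(
    impact_match = stats::setNames(imp$match, imp$category),
    impact_mismatch = stats::setNames(imp$mismatch, imp$category),
    effect_match = stats::setNames(eff$match, eff$category),
    effect_mismatch = stats::setNames(eff$mismatch, eff$category))
  expect_equal(sum(tab$impact$match), 10231L)
  expect_equal(sum(tab$impact$mismatch), 193L)
  g <- function(df, cat, col) df[df$category == cat, col]
  expect_equal(round_half_up(100 * g(tab$impact, "HIGH", "match_prop"), 1), 2.7)
  expect_equal(round_half_up(100 * g(tab$impact, "HIGH", "mismatch_prop"), 1), 1.0)
  expect_equal(round_half_up(100 * g(tab$impact, "MODIFIER", "match_prop"), 1), 0.4)
  expect_equal(round_half_up(100 * g(tab$impact, "MODIFIER", "mismatch_prop"), 1), 17.6)
  expect_equal(g(tab$effect, "other", "match"), 0L)
  expect_equal(sum(tab$effect$match_prop), 1)
  expect_equal(sum(tab$effect$mismatch_prop), 1)
})

test_that("snvs_per_million matches the published sequencing table", {
  expect_equal(snvs_per_million(72203, 37087864), 1947L)
  expect_equal(snvs_per_million(670153, 255394483), 2624L)
  expect_equal(snvs_per_million(0, 1e6), 0L)
  expect_error(snvs_per_million(10, 0))
})

test_that("verdict requires both concordance and enough overlap", {
  mk_res <- function(n_ref, n_overlap, n_match) {
    ref <- random_reference(n_ref,
                            positions = seq(1000L, n_ref * 1000L, by = 1000L))
    rv <- ref$variants
    calls <- bind_calls(lapply(seq_len(n_overlap), function(i) {
      if (i <= n_match)
        variant_call(rv$chrom[i], rv$pos[i], rv$ref[i], rv$mut[i], gt = "0/1")
      else
        variant_call(rv$chrom[i], rv$pos[i], rv$ref[i], gt = "0/0", ad = 25L)
    }))
    compare_to_reference(as_profile(calls), ref)
  }
  # high concordance on a large overlap: authenticated
  v <- verdict(mk_res(2428, 1379, 1327))  # 96.2%
  expect_true(v$authenticated)
  # perfect concordance on 3 positions: not authenticated, low evidence
  v3 <- verdict(mk_res(100, 3, 3))
  expect_false(v3$authenticated)
  expect_true(any(grepl("insufficient overlap", v3$notes)))
  # non-related-level concordance: not authenticated
  v_bad <- verdict(mk_res(1000, 100, 68))
  expect_false(v_bad$authenticated)
  # zero overlap: indeterminate
  v0 <- verdict(mk_res(100, 0, 0))
  expect_equal(v0$status, "indeterminate")
})
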