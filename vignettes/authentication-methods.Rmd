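---
title: "Authenticating cell lines from RNA-seq variant profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Authenticating cell lines from RNA-seq variant profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(snvauth)
```

## The problem and the model

Cell lines are routinely misidentified or cross-contaminated, and the
incumbent identity checks (STR profiling, targeted SNP genotyping
panels) require dedicated assays. When RNA-seq data already exists for
a sample, the expressed transcripts themselves carry thousands of
single-nucleotide variants (SNVs) that can be read out of the
alignments. snvauth authenticates a sample by comparing the genotypes
of its expressed SNVs against a curated per-cell-line mutation profile
(a COSMIC-style export) and summarising the agreement in two
statistics:

* **coverage** — the fraction of the reference profile's unique SNVs at
  which the filtered RNA-seq call set has any call at all:
  overlap / unique reference SNVs. RNA-seq only sees expressed
  transcripts, so coverage far below 1 is expected (about 40% of
  genomic variants are typically visible).
* **concordance** — among the overlapping positions, the fraction whose
  genotype matches the reference: matches / overlap. Same-line
  comparisons sit in the high 90s; unrelated lines fall to roughly
  two-thirds, because any two human genomes share a large fraction of
  common polymorphisms.

A sample is *authenticated* when concordance reaches a threshold
(default 0.90, the level proposed for 48-locus SNP-panel
authentication) **and** the overlap is large enough to make that
concordance meaningful (default 25 positions). The overlap floor
matters: against a near-disjoint reference a handful of chance
overlaps can produce a spurious 100%.

Matching is allele-level by default: a reference mutation counts as
matched when its mutant allele is among the call's alleles. A strict
mode additionally demands zygosity agreement, but reference zygosity
annotations are often absent and RNA-seq allelic imbalance distorts
observed zygosity, so allele mode is the default. A confident
homozygous-reference call at a reference-mutation position counts as an
overlapping mismatch — the sample demonstrably lacks the expected
mutation there. This is what pushes concordance below 100% for
imperfect matches and what makes hom-ref calls informative at all.

## The filtering stack

Raw caller output is noisy; `build_profile()` applies, in order:

1. **Upstream flags and site quality.** Calls the upstream caller
   flagged, calls with phred-scaled strand bias FS > 30, and calls with
   quality-by-depth QD < 2 are removed. These directions follow the
   GATK RNA-seq convention (`FS > 30.0`, `QD < 2.0` are *failure*
   expressions). Absent FS/QD on an alt-carrying call fails the gate by
   default (`missing_stats = "fail"`): absent evidence should not pass a
   quality filter. Homozygous-reference records carry no variant
   quality statistics by construction, so they bypass the FS/QD gates
   (upstream flags still apply); failing them for missing statistics
   would remove the entire hom-ref class and defeat its purpose of
   extending coverage.
2. **Non-SNV removal.** Indels, MNVs and symbolic alleles are dropped;
   single-base records (including hom-ref) pass.
3. **Cluster removal.** Every SNV lying in any window of 35 bp
   (inclusive span: positions p, q are cluster-compatible iff
   |p − q| ≤ 34) containing at least 3 alt-carrying SNVs is removed —
   dense SNV clusters in RNA-seq are usually alignment artefacts near
   splice junctions. Hom-ref and non-SNV records are transparent to the
   window count. These are the GATK `-window 35 -cluster 3` semantics,
   stated here so results are reproducible bit for bit.
4. **Depth filter.** Calls with total allelic depth below 10 are
   removed; the boundary is inclusive (a depth-10 call stays). This is
   the main lever trading call count against genotype confidence.
5. **Highest-impact selection.** For each annotated transcript, only
   variants whose impact equals that transcript's maximum impact are
   kept (a variant annotated on several transcripts survives via any
   one of them). Unannotated calls are kept unconditionally.

The profile is then keyed by unique genomic position; when two passing
SNVs collide, the deeper call wins (ties: higher QD, then input order),
and the collision is logged. Every stage logs its removal count, so
`kept + removed` always reconciles with the input.

All thresholds live in `filter_config()` and are deliberately
configurable, but the defaults are the published operating point of the
pipeline and are what every number below refers to.

## Worked example

```{r example}
cfg <- sim_config(n_reference_variants = 500)
ref <- generate_reference_profile(cfg, seed = 1)
vcf <- tempfile(fileext = ".vcf")
generate_vcf(cfg, ref, vcf, seed = 2)
profile <- build_profile(read_vcf(vcf, include_hom_ref = TRUE),
                         filter_config(), "SYNTH1")
profile
comparison <- compare_to_reference(profile, ref)
comparison
verdict(comparison)
```

## Contamination screens, panels, and pairwise comparisons

Screening against a *contaminant's* profile (classically HeLa) is the
same computation with the opposite hope: matches are evidence of
admixture. The screen is reported as `matches/overlap` and raises a
warning when at least one SNV matches on an overlap of at least two.
A zero-overlap screen is reported as *indeterminate*, not clean — no
overlap is absence of evidence, and the distinction is preserved all
the way into the report.

`compare_to_panel()` checks called genotypes (as unordered base pairs)
against a SNP genotyping panel's expected genotypes per cell line, and
`pairwise_concordance()` compares whole filtered profiles against each
other — positions called in both samples match when their called
allele sets are identical (a genotype-string mode is available by
flag). Self-comparisons are exactly 100% by construction; related
lines (same patient, or parent and derivative) score near 100%.

`characterize()` tabulates matching versus mismatched SNVs by SnpEff
impact (MODIFIER < LOW < MODERATE < HIGH) and effect class (missense /
nonsense / synonymous / other), each call contributing its single
highest-impact annotation. Mismatches are strongly enriched for
MODIFIER annotations — non-coding calls are exactly where RNA-seq
genotyping is least reliable.

## Two-site haplotype classification

For two proximal single-base sites (e.g. two adjacent codon hotspots in
one gene), reads spanning both positions are classified into joint
allele categories wt/wt, wt/mut, mut/wt and mut/mut. A read is
*uninformative* unless it covers both positions with an aligned base
(a deletion spanning a site makes it uninformative); a third base or
`N` at either site makes it *other*, which is tracked but excluded from
the informative total. Per-replicate tallies are pooled by summing
counts and dividing by the summed totals — **not** by averaging
per-replicate proportions, which differs whenever replicate totals
differ and does not reproduce the published pooled means. Each
alignment record is classified independently; overlapping mates are not
deduplicated (no deduplication rule is defined at this stage).

## Depth subsampling as a robustness check

The original robustness experiment subsampled raw reads and re-ran
alignment and calling. At desk scale, `thin_depths()` substitutes a
binomial surrogate: every allelic depth is replaced by a
Binomial(depth, fraction) draw, alleles thinned to zero depth drop out
of the genotype (an alt thinned to zero collapses the call to hom-ref),
and the filter + comparison stack is re-run per fraction. This
preserves the mechanism under test — depth-driven SNV loss against
stable concordance — without re-implementing alignment or calling;
genotype re-evaluation is the simple drop-zero-allele rule, not a
likelihood recomputation. Absolute SNV counts are therefore not
comparable to read-level subsampling, but the qualitative shape (SNV
counts fall, concordance holds until the profile empties) is. At
fraction 1 the curve equals the unthinned pipeline exactly; each
fraction uses a substream seed derived from the base seed by a fixed
offset.

## What the synthetic generator emulates

The generator produces every input format with controlled ground
truth: a reference profile of `n_reference_variants` unique
substitutions, a single-sample VCF, a SNP panel and a SAM file of
two-site reads. Its defaults are fixed study conditions, not tuning
knobs:

* `expressed_fraction = 0.4` and `discordance_rate = 0.02` reproduce
  the regime of an authentic sample: coverage near 40% and concordance
  near 98%. Discordance is planted half as a wrong alternate allele
  and half as a hom-ref call, exercising both mismatch paths.
* the per-site depth model is negative binomial with mean 60 and
  dispersion 4 — a realistic expressed-transcript depth for experiments
  of tens of millions of reads, chosen once; its sub-10 tail is small,
  so the depth filter removes few reference-position calls.
* annotation and effect mixes follow the observed characterisation
  proportions of matching SNVs; haplotype ratios default to 1:1:1:0.
* 2% of alt calls draw a failing FS and 2% a failing QD; clusters,
  indels, low-depth calls and impact-shadowed pairs are planted in
  configurable numbers at known positions.

Two structural choices keep ground truth exact. Positions are laid on
a 100-bp grid, so 3-in-35-bp clusters exist only where planted, and a
profile generated on a different `grid_offset` occupies positions
disjoint from the primary profile — which gives contamination screens
an exact zero baseline (real cell lines share polymorphisms, so real
screens are noisier). And each variant is annotated on its own
transcript except the planted shadow pairs, so highest-impact selection
removes exactly the planted shadowed calls.

What the generator does *not* emulate: read-sequence realism (error
profiles, quality strings), splicing, allele-specific expression,
linkage between neighbouring variants, and the shared-polymorphism
background between distinct human cell lines. Passing tests on
synthetic data therefore demonstrate the correctness of the filtering
and comparison machinery under known truth, not the field error rates
of RNA-seq genotyping.

## Numerical conventions and degenerate inputs

* Fractions are kept at full precision internally; percentages are
  rounded half-up to one decimal only at reporting (base `round()`
  rounds half to even and does not reproduce conventionally printed
  values; `round_half_up()` is exported).
* Concordance at zero overlap is undefined and reported `NA`, never 0;
  verdicts on such comparisons are *indeterminate*.
* An empty input VCF yields an empty profile, not an error; an empty
  or absent reference profile is an error of class
  `snvauth_no_profile`, distinct from a present-but-uncovered one.
* Ties at duplicate positions break deterministically (depth, then QD,
  then input order), making `build_profile()` a pure function of its
  inputs.
* Simulation sizes used in the shipped tests (reference profiles of
  500–1000 variants, 8–20 seeds, 300–600 reads) are chosen so the full
  suite runs in minutes on one core while keeping binomial standard
  errors small enough for 3-sigma parameter-recovery checks.

## Known limitations

* The comparison needs a reference profile; best-match search across a
  whole profile database is out of scope, as are STR profiles and
  mycoplasma or cross-species screening.
* Coverage depends on expression and sequencing depth, so it is a
  property of the experiment as much as of the cell line; it supports
  the verdict only through the overlap floor.
* Allele-mode matching cannot distinguish loss of heterozygosity from
  a true match; strict mode can, but only where reference zygosity is
  recorded.
* The subsampling surrogate thins depths, not reads; it cannot detect
  robustness failures that originate in alignment or assembly.
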