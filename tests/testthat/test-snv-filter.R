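test_that("site-quality gates follow the FS>30 / QD<2 failure convention", {
  mk <- function(fs, qd) variant_call("chrS", 100, "A", "G", gt = "0/1",
                                      fs = fs, qd = qd)
  cases <- list(
    list(fs = 10, qd = 5, pass = TRUE),    # well inside both gates
    list(fs = 35, qd = 5, pass = FALSE),   # strand bias too high
    list(fs = 10, qd = 1.5, pass = FALSE), # quality by depth too low
    list(fs = 30, qd = 2, pass = TRUE))    # boundaries are not failures
  for (cs in cases) {
    out <- apply_site_quality_filters(mk(cs$fs, cs$qd))
    expect_equal(nrow(out$calls) == 1L, cs$pass,
                 label = sprintf("FS=%s QD=%s", cs$fs, cs$qd))
    expect_equal(nrow(out$calls) + out$removed, 1L)
  }
})

test_that("upstream-flagged calls are removed and hom-ref bypasses FS/QD", {
  calls <- bind_calls(
    variant_call("chrS", 100, "A", "G", gt = "0/1", fs = 5, qd = 10,
                 filter = "mySnpFilter"),
    variant_call("chrS", 200, "C", gt = "0/0", ad = 20L),  # no FS/QD at all
    variant_call("chrS", 300, "G", "T", gt = "0/1", fs = 5, qd = 10))
  out <- apply_site_quality_filters(calls)
  expect_equal(out$calls$pos, c(200L, 300L))
  expect_equal(out$removed, 1L)
})

test_that("absent FS/QD fails the gate in strict mode and passes in lenient", {
  call <- variant_call("chrS", 100, "A", "G", gt = "0/1",
                       fs = NA, qd = NA)
  strict <- apply_site_quality_filters(call, filter_config())
  expect_equal(nrow(strict$calls), 0L)
  lenient <- apply_site_quality_filters(
    call, filter_config(missing_stats = "pass"))
  expect_equal(nrow(lenient$calls), 1L)
})

test_that("cluster removal drops all members of 3-in-35bp windows", {
  mk <- function(positions) random_calls(length(positions), positions)
  # span 31 <= 35: all three removed
  out <- remove_snv_clusters(mk(c(100L, 110L, 130L)))
  expect_equal(nrow(out$calls), 0L)
  expect_equal(out$removed, 3L)
  # pairwise gaps exceed the window: all kept
  out <- remove_snv_clusters(mk(c(100L, 140L, 180L)))
  expect_equal(out$calls$pos, c(100L, 140L, 180L))
  # distant SNV survives its clustered neighbours
  out <- remove_snv_clusters(mk(c(100L, 110L, 130L, 400L)))
  expect_equal(out$calls$pos, 400L)
  # inclusive-span boundary: 134 - 100 = 34 clusters, 135 - 100 = 35 does not
  expect_equal(nrow(remove_snv_clusters(mk(c(100L, 117L, 134L)))$calls), 0L)
  expect_equal(nrow(remove_snv_clusters(mk(c(100L, 117L, 135L)))$calls), 3L)
})

test_that("cluster windows never span chromosomes and ignore non-SNVs", {
  split_chrom <- bind_calls(
    variant_call("chr1", 100, "A", "G", gt = "0/1", fs = 5, qd = 10),
    variant_call("chr1", 110, "C", "T", gt = "0/1", fs = 5, qd = 10),
    variant_call("chr2", 120, "G", "A", gt = "0/1", fs = 5, qd = 10))
  expect_equal(nrow(remove_snv_clusters(split_chrom)$calls), 3L)

  with_indel <- bind_calls(
    variant_call("chrS", 100, "A", "G", gt = "0/1"),
    variant_call("chrS", 110, "CT", "C", gt = "0/1"),  # indel: transparent
    variant_call("chrS", 130, "G", "A", gt = "0/1"),
    variant_call("chrS", 120, "T", gt = "0/0", ad = 20L))  # hom-ref too
  expect_equal(nrow(remove_snv_clusters(with_indel)$calls), 4L)
})

test_that("cluster removal agrees with the all-windows brute-force oracle", {
  set.seed(42)
  for (rep in 1:60) {
    n <- sample(3:200, 1)
    positions <- sort(sample.int(3000, n))
    calls <- random_calls(n, positions)
    got <- remove_snv_clusters(calls)
    want_removed <- oracle_cluster_removed(positions)
    expect_setequal(setdiff(positions, got$calls$pos), want_removed)
    expect_equal(got$removed, length(want_removed))
  }
})

test_that("depth filter boundary is inclusive at the configured minimum", {
  out <- depth_filter(bind_calls(
    variant_call("chrS", 100, "A", "G", gt = "0/1", ad = c(6L, 3L)),  # 9
    variant_call("chrS", 200, "C", "T", gt = "0/1", ad = c(6L, 4L)),  # 10
    variant_call("chrS", 300, "G", gt = "0/0", ad = 0L)))
  expect_equal(out$calls$pos, 200L)
  expect_equal(out$removed, 2L)
})

test_that("highest-impact selection works transcript by transcript", {
  # T1 carries HIGH and LOW: only HIGH survives
  calls <- bind_calls(annotated_call(100, "HIGH", "T1"),
                      annotated_call(200, "LOW", "T1"))
  expect_equal(highest_impact_selection(calls)$pos, 100L)

  # a singleton MODIFIER is its transcript's maximum
  single <- annotated_call(300, "MODIFIER", "T2")
  expect_equal(nrow(highest_impact_selection(single)), 1L)

  # LOW on T1 (max HIGH) but MODERATE on T3 (max MODERATE): retained via T3
  multi_ann <- variant_call("chrS", 400, "A", "G", gt = "0/1", ad = c(10L, 10L),
    fs = 5, qd = 10,
    ann = data.frame(transcript = c("T1", "T3"), gene = c("G1", "G3"),
                     effect = "missense", impact = c("LOW", "MODERATE"),
                     stringsAsFactors = FALSE))
  calls <- bind_calls(annotated_call(100, "HIGH", "T1"), multi_ann)
  expect_equal(highest_impact_selection(calls)$pos, c(100L, 400L))

  # unannotated calls (incl. hom-ref) are retained unconditionally
  calls <- bind_calls(annotated_call(100, "HIGH", "T1"),
                      annotated_call(200, "LOW", "T1"),
                      variant_call("chrS", 500, "A", "G", gt = "0/1"),
                      variant_call("chrS", 600, "C", gt = "0/0", ad = 20L))
  expect_equal(highest_impact_selection(calls)$pos, c(100L, 500L, 600L))
})

test_that("build_profile applies the stack in order with a faithful log", {
  # 20 calls: 2 upstream-flagged, 3 indels, 3 clustered, 2 below depth,
  # 1 impact-shadowed, 9 clean survivors
  clean <- lapply(1:9, function(i)
    annotated_call(1000L + 100L * i, "MODERATE", paste0("OK", i)))
  fixture <- bind_calls(c(clean, list(
    variant_call("chrS", 100, "A", "G", gt = "0/1", fs = 5, qd = 10,
                 filter = "FAIL1"),
    variant_call("chrS", 110, "A", "G", gt = "0/1", fs = 5, qd = 10,
                 filter = "FAIL2"),
    variant_call("chrS", 210, "AT", "A", gt = "0/1", fs = 5, qd = 10),
    variant_call("chrS", 220, "C", "CTT", gt = "0/1", fs = 5, qd = 10),
    variant_call("chrS", 230, "GC", "AT", gt = "0/1", fs = 5, qd = 10),
    annotated_call(300, tx = "CL1"), annotated_call(310, tx = "CL2"),
    annotated_call(320, tx = "CL3"),
    annotated_call(400, ad = c(4L, 4L), tx = "LD1"),
    annotated_call(410, ad = c(2L, 3L), tx = "LD2"),
    annotated_call(2000, "HIGH", "SH1"),
    annotated_call(2100, "LOW", "SH1"))))
  # the HIGH half of the shadow pair is among the survivors
  prof <- build_profile(fixture, filter_config(), "fx")
  expect_equal(nrow(prof$calls), 10L)  # 9 clean + shadow HIGH
  expect_equal(unname(prof$filter_log[c("site_quality", "non_snv", "cluster",
                                        "depth", "impact")]),
               c(2L, 3L, 3L, 2L, 1L))
  expect_equal(prof$n_input_calls, 21L)
  expect_equal(sum(prof$filter_log) + nrow(prof$calls), prof$n_input_calls)
})

test_that("an all-passing input yields a full profile with a zero log", {
  calls <- random_calls(25, positions = seq(1000L, 25000L, by = 1000L))
  prof <- build_profile(calls, filter_config(), "ok")
  expect_equal(nrow(prof$calls), 25L)
  expect_true(all(prof$filter_log == 0L))
})

test_that("position collisions keep the deepest call, then highest QD", {
  a <- variant_call("chrS", 100, "A", "G", gt = "0/1", ad = c(10L, 10L),
                    fs = 5, qd = 10)
  b <- variant_call("chrS", 100, "A", "T", gt = "0/1", ad = c(20L, 20L),
                    fs = 5, qd = 4)
  prof <- build_profile(bind_calls(a, b), filter_config(), "dup")
  expect_equal(nrow(prof$calls), 1L)
  expect_equal(prof$calls$alt[[1]], "T")  # deeper call wins
  expect_equal(unname(prof$filter_log["duplicate_position"]), 1L)

  c1 <- variant_call("chrS", 100, "A", "G", gt = "0/1", ad = c(10L, 10L),
                     fs = 5, qd = 12)
  c2 <- variant_call("chrS", 100, "A", "T", gt = "0/1", ad = c(10L, 10L),
                     fs = 5, qd = 4)
  prof <- build_profile(bind_calls(c2, c1), filter_config(), "dup")
  expect_equal(prof$calls$alt[[1]], "G")  # equal depth: higher QD wins
})

test_that("relaxing any single threshold never shrinks the profile", {
  set.seed(7)
  n <- 120
  calls <- bind_calls(lapply(seq_len(n), function(i) {
    variant_call("chrS", sample.int(50000, 1), "A", "G", gt = "0/1",
                 ad = c(sample(0:15, 1), sample(0:15, 1)),
                 fs = stats::runif(1, 0, 60), qd = stats::runif(1, 0, 10))
  }))
  base_cfg <- filter_config()
  base_n <- nrow(build_profile(calls, base_cfg)$calls)
  relaxed <- list(
    filter_config(fs_fail_threshold = 60),
    filter_config(qd_fail_threshold = 0.5),
    filter_config(min_total_depth = 5),
    filter_config(cluster_min_snvs = 5),
    filter_config(cluster_window = 10))
  for (cfg in relaxed)
    expect_gte(nrow(build_profile(calls, cfg)$calls), base_n)
})

test_that("build_profile is deterministic and commutes with chromosome splits", {
  set.seed(11)
  calls <- bind_calls(
    random_calls(40, positions = sample.int(5000, 40), chrom = "chr1"),
    random_calls(40, positions = sample.int(5000, 40), chrom = "chr2"))
  p1 <- build_profile(calls, filter_config(), "s")
  p2 <- build_profile(calls, filter_config(), "s")
  expect_identical(p1, p2)

  by_chrom <- lapply(c("chr1", "chr2"), function(ch)
    build_profile(calls[calls$chrom == ch, ], filter_config(), "s"))
  expect_setequal(
    paste0(p1$calls$chrom, ":", p1$calls$pos),
    c(paste0("chr1:", by_chrom[[1]]$calls$pos),
      paste0("chr2:", by_chrom[[2]]$calls$pos)))
})
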