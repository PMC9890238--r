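test_that("hypergeometric upper tail matches closed forms and the oracle", {
  # closed-form product case: 10 vs 0 at totals 1000/1000
  want <- prod((1000 - 0:9) / (2000 - 0:9))
  expect_equal(hyper_p(10, 0, 1000, 1000), want, tolerance = 1e-12)
  expect_equal(hyper_p(10, 0, 1000, 1000), 9.55e-4, tolerance = 1e-2)
  # zero negatives: the upper tail is all the mass
  expect_equal(hyper_p(0, 25, 1000, 1000), 1)
  # grid against brute-force mass summation
  set.seed(1)
  for (i in 1:60) {
    t_neg <- sample(50:5000, 1)
    t_pos <- sample(50:5000, 1)
    K <- sample(1:100, 1)
    c_neg <- sample(0:min(K, 50), 1)
    got <- hyper_p(c_neg, K - c_neg, t_neg, t_pos)
    want <- hyper_tail_oracle(c_neg, t_neg, t_pos, K)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("position_stats computes enrichment and stratum-wide BH", {
  lib <- design_library(data.frame(
    gene_id = "g1", transcript_id = "g1.1", priority_score = 1L,
    cds = random_cds_fixture(100, 1), stringsAsFactors = FALSE))
  # equal totals: fc is the coverage ratio
  tr <- structure(list(
    tracks = list(g1 = list(neg = c(30L, 0L, 0L), pos = c(10L, 5L, 0L))),
    t_neg = 1000L, t_pos = 1000L, n_skipped = c(unknown = 0, multi = 0),
    replicate = 1L, reporter = "zfh1"), class = "coverage_tracks")
  st <- position_stats(tr)
  expect_equal(st$fc[1], 3.0)
  expect_equal(st$p[2], 1)          # c_neg = 0
  expect_true(is.na(st$fc[3]))      # both zero
  expect_equal(st$fdr, bh_oracle(st$p), tolerance = 1e-12)
  expect_true(all(st$fdr >= st$p - 1e-12))
})

test_that("BH correction matches the brute-force oracle on random vectors", {
  set.seed(2)
  for (n in c(1, 10, 1000)) {
    p <- runif(n)^2
    expect_equal(p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("core regions are maximal qualifying runs of at least 60 nt", {
  base <- make_stats(p = rep(1, 300))
  # 59 qualifying positions: nothing
  s <- base; s$p[101:159] <- 1e-6
  expect_equal(nrow(call_core_regions(s)), 0L)
  # 60 qualifying positions: one region of exactly 60
  s <- base; s$p[101:160] <- 1e-6
  got <- call_core_regions(s)
  expect_equal(got$nt_start, 100L)
  expect_equal(got$nt_end, 160L)
  # two runs split by one failing position give two regions
  s <- base; s$p[c(41:100, 102:161)] <- 1e-6
  expect_equal(nrow(call_core_regions(s)), 2L)
  # each filter gates the run
  s <- base; s$p[101:160] <- 1e-6
  s$c_pos[120] <- 9L
  expect_equal(nrow(call_core_regions(s)), 0L)
  s$c_pos[120] <- 10L; s$fc[120] <- 1.49
  expect_equal(nrow(call_core_regions(s)), 0L)
  s$fc[120] <- 1.5
  expect_equal(nrow(call_core_regions(s)), 1L)
})

test_that("extension walks to the last sub-threshold position and trims", {
  # core at [100, 160); flank of 30 nt at p = 1e-4 on each side, then p = 1
  p <- rep(1, 400)
  p[101:160] <- 1e-6
  p[71:100] <- 1e-4
  p[161:190] <- 1e-4
  s <- make_stats(p)
  core <- data.frame(gene_id = "G1", nt_start = 100L, nt_end = 160L)
  got <- extend_regions(core, s)
  expect_equal(got$nt_start, 70L)
  expect_equal(got$nt_end, 190L)
  # flanks all above the extension threshold: extended = core
  s2 <- make_stats(replace(rep(1, 400), 101:160, 1e-6))
  expect_equal(extend_regions(core, s2)[, c("nt_start", "nt_end")],
               data.frame(nt_start = 100L, nt_end = 160L))
  # a qualifying island beyond a 60-nt failing gap is NOT reached ...
  p3 <- replace(rep(1, 400), 101:160, 1e-6)
  p3[221:230] <- 1e-4   # gap 160..220 is 60 failing nt
  expect_equal(extend_regions(core, make_stats(p3))$nt_end, 160L)
  # ... but is reached across a 59-nt gap, trimming the failures after it
  p4 <- replace(rep(1, 400), 101:160, 1e-6)
  p4[220:229] <- 1e-4   # gap 160..219 is 59 failing nt
  expect_equal(extend_regions(core, make_stats(p4))$nt_end, 229L)
  # overlapping extensions merge into one region
  two_cores <- data.frame(gene_id = "G1",
                          nt_start = c(100L, 180L), nt_end = c(160L, 240L))
  p5 <- replace(rep(1, 400), c(101:160, 181:240), 1e-6)
  p5[161:180] <- 1e-4
  got5 <- extend_regions(two_cores, make_stats(p5))
  expect_equal(nrow(got5), 1L)
  expect_equal(got5$nt_start, 100L)
  expect_equal(got5$nt_end, 240L)
})

test_that("calling is monotone in the thresholds", {
  set.seed(3)
  # blocky tracks so qualifying runs of >= 60 nt actually occur
  p <- rep(10^-runif(25, 0, 8), each = 30)
  fc <- rep(runif(25, 0.5, 5), each = 30)
  s <- make_stats(p, fc = fc)
  base <- call_core_regions(s)
  looser_p <- call_core_regions(s, max_p = 1e-4)
  looser_fc <- call_core_regions(s, min_fc = 1.2)
  covered <- function(strict, loose) {
    all(vapply(seq_len(nrow(strict)), function(i)
      any(loose$nt_start <= strict$nt_start[i] &
            loose$nt_end >= strict$nt_end[i]), logical(1)))
  }
  expect_true(covered(base, looser_p))
  expect_true(covered(base, looser_fc))
})

test_that("replicate intersection keeps the longer region on 50% overlap", {
  a <- data.frame(gene_id = "g", nt_start = 0L, nt_end = 100L)
  # overlap 50 = 50% of the shorter region: kept
  b <- data.frame(gene_id = "g", nt_start = 50L, nt_end = 150L)
  expect_equal(nrow(intersect_replicates(a, b)), 1L)
  # overlap 20 < 50%: dropped
  b2 <- data.frame(gene_id = "g", nt_start = 80L, nt_end = 300L)
  expect_equal(nrow(intersect_replicates(a, b2)), 0L)
  # identity: kept unchanged
  got <- intersect_replicates(a, a)
  expect_equal(got$nt_start, 0L)
  expect_equal(got$nt_end, 100L)
  # the longer of a matched pair is retained
  b3 <- data.frame(gene_id = "g", nt_start = 0L, nt_end = 160L)
  expect_equal(intersect_replicates(a, b3)$nt_end, 160L)
  # different genes never match
  b4 <- data.frame(gene_id = "h", nt_start = 0L, nt_end = 100L)
  expect_equal(nrow(intersect_replicates(a, b4)), 0L)
})

test_that("reporter merge keeps the longest region and records support", {
  z <- data.frame(gene_id = "g", nt_start = 0L, nt_end = 120L)
  e <- data.frame(gene_id = "g", nt_start = 30L, nt_end = 90L)
  got <- merge_reporters(z, e)
  expect_equal(nrow(got), 1L)
  expect_equal(got$nt_end, 120L)
  expect_equal(got$reporter_support, "ent1,zfh1")
  # region in only one reporter is kept with that support
  solo <- merge_reporters(z, e[0, ])
  expect_equal(solo$reporter_support, "zfh1")
  # identical regions in both reporters collapse to one
  both <- merge_reporters(z, z)
  expect_equal(nrow(both), 1L)
  expect_equal(both$reporter_support, "ent1,zfh1")
  # non-overlapping regions stay separate
  e2 <- data.frame(gene_id = "g", nt_start = 200L, nt_end = 300L)
  expect_equal(nrow(merge_reporters(z, e2)), 2L)
})

test_that("reporter preference applies the strict 1.3-fold rule", {
  expect_equal(reporter_preference(3.0, 2.0), "zfh1")    # ratio 1.5
  expect_equal(reporter_preference(2.0, 3.0), "ent1")
  expect_equal(reporter_preference(2.0, 2.0), "global")
  expect_equal(reporter_preference(2.6, 2.0), "global")  # 1.3 is not > 1.3
  expect_error(reporter_preference(-1, 2), "positive")
})

test_that("representative tile is the most enriched, leftmost on ties", {
  lib <- design_library(data.frame(
    gene_id = "g1", transcript_id = "g1.1", priority_score = 1L,
    cds = random_cds_fixture(150, 8), stringsAsFactors = FALSE))
  region <- data.frame(gene_id = "g1", nt_start = 0L, nt_end = 180L)
  counts <- data.frame(oligo_id = c("g1_t00000", "g1_t00006", "g1_t00012"),
                       n_neg = c(30L, 51L, 30L), n_pos = c(10L, 10L, 10L))
  got <- representative_tile(region, counts, lib, 1000L, 1000L)
  expect_equal(got$oligo_id, "g1_t00006")
  expect_equal(got$fc, 5.1)
  # region shorter than a tile falls back to maximal overlap: tiles at 0 and
  # 6 overlap [6, 100) equally, and the more enriched one wins
  small <- data.frame(gene_id = "g1", nt_start = 6L, nt_end = 100L)
  got2 <- representative_tile(small, counts, lib, 1000L, 1000L)
  expect_equal(got2$oligo_id, "g1_t00006")
  # tie: leftmost wins
  counts$n_neg <- 30L
  expect_equal(representative_tile(region, counts, lib, 1000L, 1000L)$oligo_id,
               "g1_t00000")
})

test_that("activity score classes use strict thresholds and nest", {
  act <- data.frame(tf = c("a", "b", "c"), score_sum = c(-36, 0, -20))
  got <- sensitivity_specificity(act, rd_tfs = "a")
  n <- setNames(got$n, got$class)
  expect_equal(unname(n[c("nonactivator", "weak", "repressor", "strong")]),
               c(3L, 2L, 1L, 1L))   # -20 is weak but not a repressor
  expect_equal(got$n_rd[got$class == "strong"], 1L)
  expect_equal(got$frac_rd[got$class == "nonactivator"], 1 / 3)
})

test_that("called regions satisfy their own thresholds when audited", {
  cfg <- sim_config(n_genes = 8L, protein_len_mean = 200,
                    protein_len_cv = 0.15, cells_per_replicate = 20000L,
                    n_replicates = 1L, seed = 31L)
  sim <- simulate_rdseq(cfg)
  collapsed <- collapse_umis(sim$fragments)
  tr <- to_gene_coords(collapsed, sim$lib)
  st <- position_stats(tr)
  regs <- call_rd_regions(tr)
  expect_gt(nrow(regs), 0)
  for (i in seq_len(nrow(regs))) {
    sub <- st[st$gene_id == regs$gene_id[i] & st$pos >= regs$nt_start[i] &
                st$pos < regs$nt_end[i], ]
    ok <- sub$c_neg >= 10 & sub$c_pos >= 10 & !is.na(sub$fc) &
      sub$fc >= 1.5 & sub$p <= 1e-5
    runs <- rle(ok)
    # the region contains a qualifying core run of >= 60 nt
    expect_true(any(runs$lengths[runs$values] >= 60))
    # region edges carry extension-level support
    expect_lte(sub$p[1], 1e-3)
    expect_lte(sub$p[nrow(sub)], 1e-3)
  }
})
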