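test_that("column conservation matches its closed form", {
  M <- conservation_matrix()
  expect_true(all(M > 0))
  # identical residues: self-similarity ratio is exactly 1
  expect_equal(column_conservation(rep("L", 5), M), 1)
  # 2-sequence column: M(a,b) / sqrt(M(a,a) M(b,b))
  want <- M["L", "I"] / sqrt(M["L", "L"] * M["I", "I"])
  expect_equal(column_conservation(c("L", "I"), M), want)
  # fewer than two residues: undefined
  expect_true(is.na(column_conservation(c("L", "-"), M)))
  expect_true(is.na(column_conservation(c("-", "-"), M)))
  # 3-sequence column: mean over the three pairs
  aa <- c("L", "I", "V")
  pairs <- combn(3, 2)
  want3 <- mean(apply(pairs, 2, function(ij)
    M[aa[ij[1]], aa[ij[2]]] /
      sqrt(M[aa[ij[1]], aa[ij[1]]] * M[aa[ij[2]], aa[ij[2]]])))
  expect_equal(column_conservation(aa, M), want3)
})

test_that("alignment conservation normalizes min-max and ignores order", {
  aln <- c(a = "LLLWK-", b = "LLIWR-", c = "LIVWKK")
  raw <- alignment_conservation(aln, normalize = FALSE)
  norm <- alignment_conservation(aln)
  ok <- !is.na(raw)
  expect_equal(norm[which.max(raw)], 1)
  expect_equal(norm[ok][which.min(raw[ok])], 0)
  expect_true(all(norm[ok] >= 0 & norm[ok] <= 1))
  expect_true(is.na(norm[6]))   # single residue column
  # invariance under sequence reordering
  expect_equal(alignment_conservation(aln[c(3, 1, 2)]), norm)
  # adding a duplicate sequence never decreases the raw score
  raw2 <- alignment_conservation(c(aln, d = aln[["a"]]), normalize = FALSE)
  expect_true(all(raw2[ok] >= raw[ok] - 1e-12))
})

test_that("mapping to the reference drops reference-gap columns", {
  aln <- c(ref = "LK-WF", sp1 = "LKAWF", sp2 = "LRAW-")
  sc <- alignment_conservation(aln)
  tr <- map_to_reference(aln, "ref", sc)
  expect_equal(length(tr$scores), 4L)          # width 5 - 1 gap
  expect_equal(tr$scores, sc[c(1, 2, 4, 5)])
  expect_equal(tr$n_sequences, 3L)
  # ungapped reference keeps the full width
  tr2 <- map_to_reference(aln, "sp1", sc)
  expect_equal(length(tr2$scores), 5L)
  expect_error(map_to_reference(aln, "nope"), "not in alignment")
})

test_that("motif versus flank means handle edges and flat tracks", {
  s <- c(rep(0, 5), rep(1, 5), rep(0, 5))
  got <- motif_vs_flank(5L, 10L, s)
  expect_equal(got$motif_mean, 1)
  expect_equal(got$flank_mean, 0)
  expect_false(got$truncated)
  # flat track: identical means
  flat <- motif_vs_flank(5L, 10L, rep(0.4, 15))
  expect_equal(flat$motif_mean, flat$flank_mean)
  # instance at position 0: downstream flank only, flagged
  edge <- motif_vs_flank(0L, 5L, s)
  expect_true(edge$truncated)
  expect_equal(edge$flank_mean, 1)   # positions 5..9
  expect_error(motif_vs_flank(10L, 20L, s), "outside")
})

test_that("paired Wilcoxon P-values match sign-assignment enumeration", {
  # all-positive differences, no ties: exact two-sided P = 2 / 2^n
  for (n in c(6, 8)) {
    d <- data.frame(type = "m", motif_mean = seq_len(n) + 0.5,
                    flank_mean = seq_len(n) * 0.3)
    got <- paired_wilcoxon_fdr(d)
    expect_equal(got$p, 2 / 2^n, tolerance = 1e-12)
  }
  # symmetric +/- differences of equal magnitude: statistic at the null
  d <- data.frame(type = "m", motif_mean = c(1.2, 0.8), flank_mean = 1)
  expect_equal(paired_wilcoxon_fdr(d)$p, 1, tolerance = 1e-9)
  # all-zero differences
  d0 <- data.frame(type = "m", motif_mean = 1, flank_mean = 1)
  expect_equal(paired_wilcoxon_fdr(d0)$p, 1)
  # random pair sets match the 2^n enumeration oracle
  set.seed(8)
  for (i in 1:5) {
    n <- sample(5:10, 1)
    diffs <- round(rnorm(n), 3)
    diffs <- diffs[diffs != 0]
    while (any(duplicated(abs(diffs))))
      diffs <- round(rnorm(n), 3)
    d <- data.frame(type = "m", motif_mean = diffs, flank_mean = 0)
    expect_equal(paired_wilcoxon_fdr(d)$p, wilcoxon_exact_oracle(diffs),
                 tolerance = 1e-9)
  }
  # BH across motif types
  d2 <- rbind(
    data.frame(type = "a", motif_mean = seq_len(8) + 1,
               flank_mean = seq_len(8) * 0.1),
    data.frame(type = "b", motif_mean = c(1.2, 0.8), flank_mean = 1))
  got2 <- paired_wilcoxon_fdr(d2)
  expect_equal(got2$fdr, bh_oracle(got2$p), tolerance = 1e-12)
})

test_that("metaplot medians align instances and respect protein ends", {
  tracks <- list(p1 = seq(0, 1, length.out = 201),
                 p2 = rep(0.5, 201))
  inst <- data.frame(sequence_id = "p1", aa_start = 100L, aa_end = 110L)
  # single instance: the metaplot is its own track slice (center = 105)
  mp <- conservation_metaplot(inst, tracks, half_window = 10)
  expect_equal(mp$median_score, tracks$p1[(105 - 10):(105 + 10) + 1])
  expect_true(all(mp$n == 1))
  # two instances: per-position midpoint of the two values
  inst2 <- rbind(inst, data.frame(sequence_id = "p2", aa_start = 100L,
                                  aa_end = 110L))
  mp2 <- conservation_metaplot(inst2, tracks, half_window = 5)
  expect_equal(mp2$median_score,
               (tracks$p1[(105 - 5):(105 + 5) + 1] + 0.5) / 2)
  # an instance near the protein start only contributes where it has data
  short <- list(px = rep(1, 20))
  inst3 <- data.frame(sequence_id = "px", aa_start = 2L, aa_end = 6L)
  mp3 <- conservation_metaplot(inst3, short, half_window = 10)
  expect_equal(mp3$n[mp3$rel_pos < -4], rep(0L, sum(mp3$rel_pos < -4)))
  expect_true(all(is.na(mp3$median_score[mp3$n == 0])))
  # start-aligned mode anchors on aa_start
  mp4 <- conservation_metaplot(inst, tracks, half_window = 3,
                               align = "start")
  expect_equal(mp4$median_score, tracks$p1[(100 - 3):(100 + 3) + 1])
})

test_that("synthetic alignments conserve planted motifs", {
  ref <- paste(rep("ACDEFGHIKL", 20), collapse = "")
  cons <- data.frame(aa_start = 50L, aa_end = 62L)
  aln <- simulate_alignment(ref, n_seqs = 12, sub_rate = 0.5,
                            conserved = cons, conserved_rate = 0.02,
                            seed = 3)
  expect_equal(unname(aln["ref"]), ref)
  tr <- map_to_reference(aln, "ref")
  inside <- mean(tr$scores[51:62])
  outside <- mean(tr$scores[-(51:62)])
  expect_gt(inside, outside)
  mv <- motif_vs_flank(50L, 62L, tr)
  expect_gt(mv$motif_mean, mv$flank_mean)
})
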