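aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

one_hot <- function(letters) {
  m <- matrix(0, 20, length(letters), dimnames = list(aa20, NULL))
  for (j in seq_along(letters)) m[letters[j], j] <- 1
  m
}

test_that("MEME minimal format round-trips", {
  p1 <- pwm("m1", one_hot(c("L", "A", "F")))
  m2 <- matrix(1 / 20, 20, 5, dimnames = list(aa20, NULL))
  p2 <- pwm("m2", m2)
  path <- tempfile(fileext = ".meme")
  write_meme(list(p1, p2), path)
  got <- read_meme(path)
  expect_length(got, 2L)
  expect_equal(got[[1]]$motif_id, "m1")
  expect_equal(got[[2]]$motif_id, "m2")
  expect_equal(got[[1]]$mat, p1$mat, tolerance = 1e-5)
  expect_equal(got[[2]]$mat, p2$mat, tolerance = 1e-5)
  # single-column motif parses to width 1
  path1 <- tempfile(fileext = ".meme")
  write_meme(list(pwm("w1", one_hot("L"))), path1)
  expect_equal(read_meme(path1)[[1]]$width, 1L)
  # malformed matrix rows are an error naming the motif
  lines <- readLines(path)
  lines[grep("^MOTIF m1", lines) + 2L] <- "0.5 0.5"
  bad <- tempfile(); writeLines(lines, bad)
  expect_error(read_meme(bad), "m1")
})

test_that("width-1 scan: single-letter null probabilities", {
  p <- pwm("L1", one_hot("L"))
  got <- scan_pwm(p, "LAL", p_threshold = 0.06)
  expect_equal(got$aa_start, c(0L, 2L))
  expect_equal(got$p, c(0.05, 0.05))
  # threshold 1 returns every window
  all_w <- scan_pwm(p, "LAL", p_threshold = 1)
  expect_equal(nrow(all_w), 3L)
  # scan hit count is monotone in the threshold
  expect_gte(nrow(all_w), nrow(got))
})

test_that("DP scan P-values equal brute-force enumeration for small widths", {
  set.seed(5)
  for (w in 2:3) {
    m <- matrix(rgamma(20 * w, 0.5), 20)
    m <- sweep(m, 2, colSums(m), "/")
    bg <- rgamma(20, 2); bg <- bg / sum(bg)
    p <- pwm(sprintf("r%d", w), m, background = bg)
    pep <- paste(sample(aa20, 30, replace = TRUE), collapse = "")
    got <- scan_pwm(p, pep, p_threshold = 1)
    expect_equal(nrow(got), 30 - w + 1)
    for (i in seq_len(nrow(got))) {
      win <- substr(pep, got$aa_start[i] + 1, got$aa_end[i])
      expect_equal(got$p[i], pwm_pvalue_oracle(p, win),
                   tolerance = 1e-9)
    }
  }
})

test_that("non-standard residues skip the window with a warning", {
  p <- pwm("L1", one_hot(c("L", "A")))
  expect_warning(got <- scan_pwm(p, "LXLA", p_threshold = 1), "skipped")
  expect_equal(nrow(got), 1L)   # only the LA window at position 2
  expect_equal(got$aa_start, 2L)
})

test_that("SLiM regex scan reports coordinates and overlapping matches", {
  pat <- list(pattern_id = "LIG_CtBP_PxDLS_1", regex = "P.DLS",
              class_p = 2e-4)
  got <- scan_slim(pat, "AAPMDLSAA")
  expect_equal(nrow(got), 1L)
  expect_equal(got$aa_start, 2L)
  expect_equal(got$aa_end, 7L)
  expect_equal(got$match, "PMDLS")
  expect_equal(got$p, 2e-4)
  # no match
  expect_equal(nrow(scan_slim(pat, "AAAAAA")), 0L)
  # overlapping matches on a tandem repeat are all reported
  got2 <- scan_slim(list(pattern_id = "x", regex = "ARA"), "ARARA")
  expect_equal(got2$aa_start, c(0L, 2L))
})

test_that("shipped SLiM patterns load and match canonical instances", {
  pats <- read_slim_patterns()
  expect_true(all(c("LIG_EH1_1", "LIG_CtBP_PxDLS_1") %in% pats$pattern_id))
  eh1 <- pats[pats$pattern_id == "LIG_EH1_1", ]
  # Engrailed EH1 core
  expect_gt(nrow(scan_slim(eh1, "LAFSISNILSD")), 0L)
})

test_that("Fisher enrichment matches the enumeration oracle", {
  got <- fisher_enrichment(10, 90, 10, 990)
  expect_equal(got$p, fisher_two_sided_oracle(10, 90, 10, 990),
               tolerance = 1e-9)
  expect_gt(got$odds_ratio, 1)
  # identical proportions: conditional odds ratio exactly 1
  expect_equal(fisher_enrichment(5, 95, 50, 950)$odds_ratio, 1,
               tolerance = 1e-9)
  # zero margin: P = 1, OR undefined
  z <- fisher_enrichment(0, 100, 0, 1000)
  expect_equal(z$p, 1)
  expect_true(is.na(z$odds_ratio))
  # random tables with margins <= 200
  set.seed(6)
  for (i in 1:10) {
    t <- sample(0:60, 4, replace = TRUE)
    got <- fisher_enrichment(t[1], t[2], t[3], t[4])
    if (all(rowSums(matrix(t, 2, byrow = TRUE)) > 0) &&
        all(colSums(matrix(t, 2, byrow = TRUE)) > 0))
      expect_equal(got$p, fisher_two_sided_oracle(t[1], t[2], t[3], t[4]),
                   tolerance = 1e-8)
  }
})

test_that("motif distance is a symmetric pseudo-metric with zero diagonal", {
  set.seed(7)
  mk <- function(w, seed) {
    set.seed(seed)
    m <- matrix(rgamma(20 * w, 0.4), 20)
    pwm(paste0("m", seed), sweep(m, 2, colSums(m), "/"))
  }
  a <- mk(6, 1); b <- mk(8, 2)
  expect_equal(motif_distance(a, a), 0)
  expect_equal(motif_distance(a, b), motif_distance(b, a), tolerance = 1e-12)
  expect_gt(motif_distance(a, b), 0)
  # overlap impossible below min_overlap
  short <- mk(3, 3)
  expect_equal(motif_distance(short, short, min_overlap = 4), Inf)
  # two disjoint one-hot width-4 motifs: only offset 0 is allowed, and the
  # distance equals the direct column-wise symmetric KL
  oh1 <- pwm("o1", one_hot(c("L", "L", "L", "L")))
  oh2 <- pwm("o2", one_hot(c("W", "W", "W", "W")))
  skl <- function(p, q) 0.5 * (sum(p * log2(p / q)) + sum(q * log2(q / p)))
  want <- mean(vapply(1:4, function(j) skl(oh1$mat[, j], oh2$mat[, j]),
                      numeric(1)))
  expect_equal(motif_distance(oh1, oh2, min_overlap = 4), want,
               tolerance = 1e-12)
  # distance matrix: symmetric, zero diagonal
  D <- motif_distance_matrix(list(a, b, oh1))
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 3))
})

test_that("motif clustering cuts the profile-correlation tree at 0.7", {
  # crafted block matrix: two groups with near-identical profiles
  D <- rbind(c(0, 0.1, 5, 5.2),
             c(0.1, 0, 5.1, 5.3),
             c(5, 5.1, 0, 0.1),
             c(5.2, 5.3, 0.1, 0))
  dimnames(D) <- list(letters[1:4], letters[1:4])
  cl <- cluster_motifs(D)
  expect_equal(length(unique(cl)), 2L)
  expect_equal(cl[["a"]], cl[["b"]])
  expect_equal(cl[["c"]], cl[["d"]])
  # duplicated motifs always co-cluster
  D2 <- D; D2[2, ] <- D2[1, ]; D2[, 2] <- D2[, 1]; D2[2, 2] <- 0
  cl2 <- cluster_motifs(D2)
  expect_equal(cl2[["a"]], cl2[["b"]])
  # cut above the tree keeps everything together
  expect_equal(length(unique(cluster_motifs(D, cut_height = 10))), 1L)
  # constant rows are tolerated with a warning
  D3 <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(D3) <- 0
  D3[1, ] <- 0; D3[, 1] <- 0
  expect_warning(cluster_motifs(D3), "constant")
})

test_that("RD classification applies known > novel > unexplained precedence", {
  elm <- data.frame(sequence_id = "rd1", pattern_id = "LIG_EH1_1",
                    stringsAsFactors = FALSE)
  meme <- data.frame(sequence_id = c("rd1", "rd2", "rd3", "rd4"),
                     motif_id = c("PLKKR", "PLKKR", "motif6", "PLKKR"),
                     p = c(1e-6, 1e-6, 1e-6, 1e-4),
                     stringsAsFactors = FALSE)
  got <- classify_rds(c("rd1", "rd2", "rd3", "rd4", "rd5"), elm, meme,
                      meme_p = 1e-5, exclude_motifs = "motif6")
  cls <- setNames(got$classes$class, got$classes$rd_id)
  expect_equal(unname(cls[c("rd1", "rd2", "rd3", "rd4", "rd5")]),
               c("known", "novel", "unexplained", "unexplained",
                 "unexplained"))
  # co-occurrence counts RDs carrying both motifs
  expect_equal(got$cooccurrence["LIG_EH1_1", "PLKKR"], 1L)
  expect_equal(unname(got$motif_counts["PLKKR"]), 2L)
})

test_that("logo frequencies average available sequences per position", {
  prots <- c(p1 = "MKKKLLLLWWWW", p2 = "MKKKLALLWWWW")
  inst <- data.frame(sequence_id = c("p1", "p2"),
                     aa_start = c(4L, 4L), aa_end = c(8L, 8L))
  f <- logo_frequencies(inst, prots, flank = 2L)
  expect_equal(ncol(f), 4 + 4)
  expect_equal(colSums(f), rep(1, 8), ignore_attr = TRUE)
  # position 2 of the core differs between the two instances
  expect_equal(f["L", "1"], 0.5)
  expect_equal(f["A", "1"], 0.5)
  # single instance: one-hot columns
  f1 <- logo_frequencies(inst[1, ], prots, flank = 0L)
  expect_true(all(apply(f1, 2, max) == 1))
  # truncated flank at the protein start: frequencies over available only
  inst2 <- data.frame(sequence_id = "p1", aa_start = 0L, aa_end = 4L)
  f2 <- logo_frequencies(inst2, prots, flank = 2L)
  expect_equal(attr(f2, "n")[1:2], c(0L, 0L))
  expect_equal(attr(f2, "n")[3], 1L)
  expect_error(logo_frequencies(inst[0, ], prots), "empty")
})
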