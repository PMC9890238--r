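# Independent brute-force oracles used to validate the package's statistics.
# These deliberately avoid the code paths (and where possible the library
# routines) they check.

# Upper-tail hypergeometric by direct mass summation over the support.
hyper_tail_oracle <- function(c_neg, t_neg, t_pos, K) {
  kmax <- min(K, t_neg)
  if (c_neg > kmax) return(0)
  ks <- max(c_neg, max(0, K - t_pos)):kmax
  sum(exp(lchoose(t_neg, ks) + lchoose(t_pos, K - ks) -
            lchoose(t_neg + t_pos, K)))
}

# Benjamini-Hochberg from the definition: q_(i) = min_{j >= i} n p_(j) / j.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- n * p[o] / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# Greedy count-ordered UMI absorption, written directly on strings.
umi_collapse_oracle <- function(umis, counts, max_mismatch = 2L) {
  ord <- order(-counts, umis)
  umis <- umis[ord]
  counts <- counts[ord]
  hamming <- function(a, b)
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  retained <- character(0)
  total <- numeric(0)
  for (i in seq_along(umis)) {
    placed <- FALSE
    for (r in seq_along(retained)) {
      if (hamming(retained[r], umis[i]) <= max_mismatch) {
        total[r] <- total[r] + counts[i]
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      retained <- c(retained, umis[i])
      total <- c(total, counts[i])
    }
  }
  data.frame(umi = retained, read_count = total, stringsAsFactors = FALSE)
}

# Exact PWM scan P-values by enumerating all 20^w windows, weighted by the
# background; shares only the discretization step with the scanner (the
# rounding is part of the score definition).
pwm_pvalue_oracle <- function(pw, peptide_window, granularity = 1e-3) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  s_int <- round(log2(sweep(pw$mat, 1, pw$background, "/")) / granularity)
  w <- pw$width
  grids <- do.call(expand.grid, rep(list(seq_len(20)), w))
  scores <- numeric(nrow(grids))
  weights <- rep(1, nrow(grids))
  for (j in seq_len(w)) {
    scores <- scores + s_int[grids[[j]], j]
    weights <- weights * pw$background[grids[[j]]]
  }
  idx <- match(strsplit(peptide_window, "")[[1]], aa)
  obs <- sum(s_int[cbind(idx, seq_len(w))])
  sum(weights[scores >= obs])
}

# Two-sided Fisher exact P by enumerating the hypergeometric support and
# summing tables at most as probable as the observed one (standard
# 1 + 1e-7 relative slack on "as probable").
fisher_two_sided_oracle <- function(a, b, c, d) {
  m <- a + b          # row 1 margin
  n <- c + d          # row 2 margin
  k <- a + c          # column 1 margin
  support <- max(0, k - n):min(k, m)
  probs <- exp(lchoose(m, support) + lchoose(n, k - support) -
                 lchoose(m + n, k))
  obs <- probs[support == a]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Exact two-sided paired signed-rank P by enumerating all 2^n sign vectors.
wilcoxon_exact_oracle <- function(diffs) {
  diffs <- diffs[diffs != 0]
  n <- length(diffs)
  r <- rank(abs(diffs))
  v_obs <- sum(r[diffs > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  v_all <- as.matrix(signs) %*% r
  p_le <- mean(v_all <= v_obs)
  p_ge <- mean(v_all >= v_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Small fragment-record constructor for collapse tests.
frag_records <- function(oligo_id, umi, fraction = "neg", replicate = 1L,
                         reporter = "zfh1", read_count = 1L) {
  data.frame(oligo_id = oligo_id, umi = umi, fraction = fraction,
             replicate = replicate, reporter = reporter,
             read_count = read_count, stringsAsFactors = FALSE)
}

# Position-stats table builder for hand-traced region-calling tests.
make_stats <- function(p, fc = 3, c_neg = 20L, c_pos = 20L,
                       gene_id = "G1") {
  n <- length(p)
  data.frame(gene_id = gene_id, pos = seq_len(n) - 1L,
             c_neg = rep_len(c_neg, n), c_pos = rep_len(c_pos, n),
             fc = rep_len(fc, n), p = p, fdr = p,
             stringsAsFactors = FALSE)
}

# Deterministic random CDS for library tests.
random_cds_fixture <- function(n_aa, seed = 1) {
  set.seed(seed)
  b <- c("A", "C", "G", "T")
  cod <- as.vector(outer(outer(b, b, paste0), b, paste0))
  cod <- setdiff(cod, c("TAA", "TAG", "TGA"))
  paste(sample(cod, n_aa, replace = TRUE), collapse = "")
}
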