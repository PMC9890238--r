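# Positional statistics, domain/IDR overlap categories and validation
# statistics (flow cytometry, paired t-tests, qPCR, correlation).

#' Scaled center of an interval within its protein
#'
#' Midpoint of the interval divided by the protein length, in \[0, 1\];
#' lets RD and DBD positions be compared across proteins of different size.
#'
#' @param aa_start,aa_end interval, 0-based half-open.
#' @param protein_len protein length in AA (> 0).
#' @return numeric in \[0, 1\].
#' @export
scaled_center <- function(aa_start, aa_end, protein_len) {
  if (any(protein_len <= 0)) stop("protein length must be positive")
  ((aa_start + aa_end) / 2) / protein_len
}

#' Reciprocal 50% overlap rule between an RD tile and an annotation
#'
#' TRUE when the overlap covers at least half of the annotated domain or at
#' least half of the RD interval. The rule is asymmetric in general: which
#' interval is the "domain" matters unless the lengths are equal.
#'
#' @param rd_start,rd_end RD interval (0-based half-open AA).
#' @param dom_start,dom_end domain interval.
#' @param min_frac overlap fraction required of either interval
#'   (default 0.5).
#' @return logical.
#' @export
overlaps_domain <- function(rd_start, rd_end, dom_start, dom_end,
                            min_frac = 0.5) {
  ov <- pmax(0, pmin(rd_end, dom_end) - pmax(rd_start, dom_start))
  ov >= min_frac * (dom_end - dom_start) | ov >= min_frac * (rd_end - rd_start)
}

#' Categorize RDs by overlap with annotated domains and IDRs
#'
#' Assigns each RD one mutually exclusive label with precedence
#' DBD > other_domain > IDR > unannotated, using the reciprocal 50% overlap
#' rule of [overlaps_domain()].
#'
#' @param rds data.frame: rd_id, protein_id, aa_start, aa_end.
#' @param annotations data.frame: protein_id, aa_start, aa_end, category in
#'   c("DBD", "other_domain", "IDR").
#' @param precedence category order, strongest first.
#' @return list: `categories` (data.frame rd_id, category), `fractions`
#'   (named proportions over all RDs, summing to 1).
#' @export
categorize_rds <- function(rds, annotations,
                           precedence = c("DBD", "other_domain", "IDR")) {
  cats <- character(nrow(rds))
  for (i in seq_len(nrow(rds))) {
    ann <- annotations[annotations$protein_id == rds$protein_id[i], ,
                       drop = FALSE]
    hit <- if (nrow(ann))
      ann$category[overlaps_domain(rds$aa_start[i], rds$aa_end[i],
                                   ann$aa_start, ann$aa_end)]
    else character(0)
    cats[i] <- if (length(hit))
      precedence[min(match(hit, precedence))] else "unannotated"
  }
  lev <- c(precedence, "unannotated")
  frac <- prop.table(table(factor(cats, levels = lev)))
  list(categories = data.frame(rd_id = rds$rd_id, category = cats,
                               stringsAsFactors = FALSE),
       fractions = frac)
}

#' Non-RD, non-overlapping background fragments
#'
#' Tiles each protein into consecutive non-overlapping windows of `size` AA
#' and drops windows overlapping any RD; the remainder is the background set
#' for prevalence and Fisher-enrichment comparisons.
#'
#' @param protein_lens named integer vector of protein lengths (AA).
#' @param rds data.frame: protein_id, aa_start, aa_end (may be empty).
#' @param size fragment size in AA (default 50).
#' @return data.frame: protein_id, aa_start, aa_end.
#' @export
background_fragments <- function(protein_lens, rds, size = 50L) {
  out <- lapply(names(protein_lens), function(p) {
    L <- protein_lens[[p]]
    if (L < size) return(NULL)
    starts <- seq.int(0L, L - size, by = size)
    d <- data.frame(protein_id = p, aa_start = starts,
                    aa_end = starts + size, stringsAsFactors = FALSE)
    r <- rds[rds$protein_id == p, , drop = FALSE]
    if (nrow(r)) {
      ov <- vapply(seq_len(nrow(d)), function(i)
        any(pmin(d$aa_end[i], r$aa_end) - pmax(d$aa_start[i], r$aa_start)
            > 0), logical(1))
      d <- d[!ov, , drop = FALSE]
    }
    d
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Tile-strength distributions by RD and motif status
#'
#' Splits tiles into three groups per motif - inside an RD with the motif,
#' outside RDs with the motif, outside RDs without the motif - and compares
#' groups with two-sided Wilcoxon rank-sum tests on the tiles' average
#' log2 fold-changes.
#'
#' @param tiles data.frame: oligo_id, log2_fc, in_rd (logical), has_motif
#'   (logical).
#' @return list: `groups` (named list of log2_fc vectors), `n` (sizes),
#'   `tests` (data.frame comparison, p; skipped comparisons get NA).
#' @export
tile_strength_groups <- function(tiles) {
  groups <- list(
    rd_motif = tiles$log2_fc[tiles$in_rd & tiles$has_motif],
    nord_motif = tiles$log2_fc[!tiles$in_rd & tiles$has_motif],
    nord_nomotif = tiles$log2_fc[!tiles$in_rd & !tiles$has_motif])
  cmp <- utils::combn(names(groups), 2)
  tests <- apply(cmp, 2, function(pair) {
    a <- groups[[pair[1]]]; b <- groups[[pair[2]]]
    p <- if (!length(a) || !length(b)) NA_real_
    else suppressWarnings(
      wilcox.test(a, b, alternative = "two.sided")$p.value)
    data.frame(comparison = paste(pair, collapse = "_vs_"), p = p,
               stringsAsFactors = FALSE)
  })
  list(groups = groups, n = vapply(groups, length, integer(1)),
       tests = do.call(rbind, tests))
}

#' Fold-change repression from flow-cytometry intensities
#'
#' Ratio of median reporter intensity in control cells over cells expressing
#' the tethered candidate; > 1 means repression.
#'
#' @param control,rd positive per-cell GFP intensities (transfection-gated).
#' @return scalar FC repression.
#' @export
fc_repression <- function(control, rd) {
  if (!length(control) || !length(rd)) stop("empty sample")
  m_ctrl <- median(control)
  m_rd <- median(rd)
  if (m_rd == 0 || m_ctrl == 0) stop("zero median intensity")
  m_ctrl / m_rd
}

#' Two-tailed paired t-test on log2 values
#'
#' @param a,b paired replicate series (e.g. median GFP per replicate),
#'   length >= 2.
#' @return list(t, df, p, undefined); `undefined` is TRUE (with p = NA) when
#'   the log2 differences have zero variance.
#' @export
paired_t_log2 <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- log2(a) - log2(b)
  if (isTRUE(all.equal(stats::var(d), 0)) || stats::var(d) == 0)
    return(list(t = NA_real_, df = length(d) - 1L, p = NA_real_,
                undefined = TRUE))
  tt <- t.test(log2(a), log2(b), paired = TRUE,
               alternative = "two.sided")
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, undefined = FALSE)
}

#' Delta-delta-Ct fold change
#'
#' `DeltaCt = mean Ct target - mean Ct housekeeping` per condition;
#' `DeltaDeltaCt = DeltaCt - DeltaCt(control)`; `FC = 2^(-DeltaDeltaCt)`.
#'
#' @param ct_target,ct_housekeeping mean Ct values in the condition of
#'   interest.
#' @param ct_target_ctrl,ct_housekeeping_ctrl mean Ct values in the control
#'   condition.
#' @return list(delta_ct, delta_delta_ct, fc).
#' @export
delta_delta_ct <- function(ct_target, ct_housekeeping,
                           ct_target_ctrl, ct_housekeeping_ctrl) {
  d <- ct_target - ct_housekeeping
  d0 <- ct_target_ctrl - ct_housekeeping_ctrl
  dd <- d - d0
  list(delta_ct = d, delta_delta_ct = dd, fc = 2^(-dd))
}

#' Pearson correlation with degeneracy guard
#'
#' @param x,y numeric vectors, length >= 3.
#' @return list(r, undefined); `undefined` is TRUE (r = NA) when either
#'   vector has zero variance.
#' @export
pcc <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    return(list(r = NA_real_, undefined = TRUE))
  list(r = cor(x, y), undefined = FALSE)
}
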