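# Per-position enrichment statistics and repressive-region calling.
#
# The test at each CDS position asks whether the GFP-negative fraction is
# over-represented among the fragments covering that position, at fixed
# sequencing depth: with N = T_neg + T_pos collapsed fragments library-wide,
# T_neg of them "negative", and K = c_neg + c_pos fragments drawn at the
# position, the one-sided upper-tail hypergeometric P(X >= c_neg).

#' Upper-tail hypergeometric P-value for per-position enrichment
#'
#' @param c_neg,c_pos coverage at the position in the GFP-negative /
#'   GFP-positive fraction (vectorized).
#' @param t_neg,t_pos stratum-wide collapsed fragment totals.
#' @return P(X >= c_neg) under the hypergeometric null.
#' @export
hyper_p <- function(c_neg, c_pos, t_neg, t_pos) {
  if (t_neg <= 0 || t_pos <= 0) stop("fraction totals must be positive")
  phyper(c_neg - 1, t_neg, t_pos, c_neg + c_pos, lower.tail = FALSE)
}

#' Per-position enrichment statistics for one screen stratum
#'
#' Fold-change is the depth-normalized coverage ratio
#' `(c_neg / T_neg) / (c_pos / T_pos)` (`Inf` when `c_pos = 0` and
#' `c_neg > 0`, `NA` when both are 0); P-values are upper-tail
#' hypergeometric (see [hyper_p()]); the Benjamini-Hochberg FDR is computed
#' across all positions of all genes in the stratum.
#'
#' @param tracks a `coverage_tracks` object (one replicate x reporter).
#' @return data.frame: gene_id, pos (0-based nt), c_neg, c_pos, fc, p, fdr.
#' @export
position_stats <- function(tracks) {
  stopifnot(inherits(tracks, "coverage_tracks"))
  t_neg <- tracks$t_neg
  t_pos <- tracks$t_pos
  if (t_neg <= 0 || t_pos <= 0) stop("fraction totals must be positive")
  parts <- lapply(names(tracks$tracks), function(g) {
    tr <- tracks$tracks[[g]]
    data.table::data.table(gene_id = g,
                           pos = seq_along(tr$neg) - 1L,
                           c_neg = tr$neg, c_pos = tr$pos)
  })
  st <- data.table::rbindlist(parts)
  st[, fc := (c_neg / t_neg) / (c_pos / t_pos)]
  st[c_neg == 0 & c_pos == 0, fc := NA_real_]
  st[, p := hyper_p(c_neg, c_pos, t_neg, t_pos)]
  st[, fdr := p.adjust(p, method = "BH")]
  out <- as.data.frame(st)
  attr(out, "t_neg") <- t_neg
  attr(out, "t_pos") <- t_pos
  out
}

#' Call core repressive regions
#'
#' A core region is a maximal run of consecutive positions with coverage of
#' at least `min_cov` fragments in both fractions, fold-change >=
#' `min_fc` and hypergeometric P <= `max_p`, spanning at least
#' `min_len_nt` nucleotides.
#'
#' @param stats output of [position_stats()].
#' @param min_cov minimal coverage required in each fraction (default 10).
#' @param min_fc minimal fold-change (default 1.5).
#' @param max_p maximal hypergeometric P (default 1e-5).
#' @param min_len_nt minimal region length in nt (default 60 = 20 AA).
#' @return data.frame: gene_id, nt_start, nt_end (0-based half-open).
#' @export
call_core_regions <- function(stats, min_cov = 10, min_fc = 1.5,
                              max_p = 1e-5, min_len_nt = 60L) {
  st <- data.table::as.data.table(stats)
  st[, ok := c_neg >= min_cov & c_pos >= min_cov &
       !is.na(fc) & fc >= min_fc & p <= max_p]
  regs <- st[, {
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values & r$lengths >= min_len_nt
    list(nt_start = starts[keep], nt_end = ends[keep])
  }, by = gene_id]
  as.data.frame(regs)
}

# Extension walk for one side. `p_out` is the P-value series walking outward
# from the region edge (first element = first position beyond the edge).
# The walk terminates once `stop_len` consecutive positions with
# p > ext_p have been seen, and the extension is trimmed back to the last
# position with p <= ext_p. Returns the number of positions added.
extend_side <- function(p_out, ext_p, stop_len) {
  q <- which(p_out <= ext_p)
  if (!length(q)) return(0L)
  # gaps of consecutive failures before each qualifying position
  gaps <- diff(c(0L, q)) - 1L
  chain <- which(cumsum(gaps >= stop_len) == 0L)
  if (!length(chain)) return(0L)
  q[max(chain)]
}

#' Extend core regions through flanking sub-threshold positions
#'
#' From each edge of each core region the caller walks outward, adding
#' flanking positions, and stops a side once `stop_len_nt` consecutive
#' positions with P > `ext_p` have been seen (or the CDS ends); the side is
#' then trimmed back so the region ends at the last position with
#' P <= `ext_p`. Overlapping extended regions of one gene are merged.
#'
#' @param cores core regions from [call_core_regions()].
#' @param stats output of [position_stats()].
#' @param ext_p extension P threshold (default 1e-3).
#' @param stop_len_nt run of failing positions that stops the walk
#'   (default 60).
#' @return data.frame: gene_id, nt_start, nt_end, merged where overlapping.
#' @export
extend_regions <- function(cores, stats, ext_p = 1e-3, stop_len_nt = 60L) {
  if (!nrow(cores))
    return(data.frame(gene_id = character(), nt_start = integer(),
                      nt_end = integer(), stringsAsFactors = FALSE))
  st <- data.table::as.data.table(stats)
  data.table::setkey(st, gene_id, pos)
  out <- lapply(seq_len(nrow(cores)), function(i) {
    g <- cores$gene_id[i]
    p <- st[gene_id == g][order(pos)]$p
    L <- length(p)
    s <- cores$nt_start[i]
    e <- cores$nt_end[i]
    left <- if (s > 0L) extend_side(rev(p[seq_len(s)]), ext_p, stop_len_nt)
            else 0L
    right <- if (e < L) extend_side(p[(e + 1L):L], ext_p, stop_len_nt)
             else 0L
    data.frame(gene_id = g, nt_start = s - left, nt_end = e + right,
               stringsAsFactors = FALSE)
  })
  ext <- do.call(rbind, out)
  # merge overlapping extensions per gene
  merged <- lapply(split(ext, ext$gene_id), function(d) {
    ir <- IRanges::reduce(IRanges::IRanges(d$nt_start + 1L, d$nt_end))
    data.frame(gene_id = d$gene_id[1],
               nt_start = IRanges::start(ir) - 1L,
               nt_end = IRanges::end(ir),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, merged)
  rownames(out) <- NULL
  out
}

#' Region-level enrichment within one stratum
#'
#' Mean depth-normalized coverage ratio over a region:
#' `(mean c_neg / T_neg) / (mean c_pos / T_pos)`.
#'
#' @param regions data.frame with gene_id, nt_start, nt_end.
#' @param tracks `coverage_tracks` for the stratum.
#' @return numeric vector of region fold-changes.
#' @export
region_fc <- function(regions, tracks) {
  vapply(seq_len(nrow(regions)), function(i) {
    tr <- tracks$tracks[[regions$gene_id[i]]]
    idx <- (regions$nt_start[i] + 1L):regions$nt_end[i]
    mn <- mean(tr$neg[idx]) / tracks$t_neg
    mp <- mean(tr$pos[idx]) / tracks$t_pos
    if (mp == 0) return(if (mn > 0) Inf else NA_real_)
    mn / mp
  }, numeric(1))
}

#' Call extended RD regions for one stratum
#'
#' Convenience wrapper: [position_stats()] -> [call_core_regions()] ->
#' [extend_regions()], annotating each region with its stratum enrichment
#' and minimal P.
#'
#' @inheritParams call_core_regions
#' @inheritParams extend_regions
#' @param tracks `coverage_tracks` for the stratum.
#' @return data.frame: gene_id, nt_start, nt_end, fc, min_p.
#' @export
call_rd_regions <- function(tracks, min_cov = 10, min_fc = 1.5,
                            max_p = 1e-5, min_len_nt = 60L,
                            ext_p = 1e-3, stop_len_nt = 60L) {
  stats <- position_stats(tracks)
  cores <- call_core_regions(stats, min_cov, min_fc, max_p, min_len_nt)
  regs <- extend_regions(cores, stats, ext_p, stop_len_nt)
  if (nrow(regs)) {
    regs$fc <- region_fc(regs, tracks)
    st <- data.table::as.data.table(stats)
    regs$min_p <- vapply(seq_len(nrow(regs)), function(i) {
      min(st[gene_id == regs$gene_id[i] & pos >= regs$nt_start[i] &
               pos < regs$nt_end[i]]$p)
    }, numeric(1))
  } else {
    regs$fc <- numeric(0)
    regs$min_p <- numeric(0)
  }
  regs
}

overlap_len <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

#' Intersect regions called in two replicates
#'
#' A pair of regions (one per replicate, same gene) matches when their
#' overlap is at least `min_overlap` of the shorter region; the longer
#' region of a matched pair is retained. Unmatched regions are dropped.
#'
#' @param a,b region data.frames (gene_id, nt_start, nt_end) from the two
#'   replicates.
#' @param min_overlap required overlap as a fraction of the shorter region
#'   (default 0.5).
#' @return data.frame of retained regions (unique intervals).
#' @export
intersect_replicates <- function(a, b, min_overlap = 0.5) {
  empty <- data.frame(gene_id = character(), nt_start = integer(),
                      nt_end = integer(), stringsAsFactors = FALSE)
  if (!nrow(a) || !nrow(b)) return(empty)
  kept <- list()
  for (i in seq_len(nrow(a))) {
    cand <- b[b$gene_id == a$gene_id[i], , drop = FALSE]
    if (!nrow(cand)) next
    ov <- overlap_len(a$nt_start[i], a$nt_end[i],
                      cand$nt_start, cand$nt_end)
    shorter <- pmin(a$nt_end[i] - a$nt_start[i],
                    cand$nt_end - cand$nt_start)
    hit <- which(ov >= min_overlap * shorter & ov > 0)
    for (j in hit) {
      len_a <- a$nt_end[i] - a$nt_start[i]
      len_b <- cand$nt_end[j] - cand$nt_start[j]
      kept[[length(kept) + 1L]] <-
        if (len_a >= len_b) a[i, c("gene_id", "nt_start", "nt_end")]
        else cand[j, c("gene_id", "nt_start", "nt_end")]
    }
  }
  if (!length(kept)) return(empty)
  out <- unique(do.call(rbind, kept))
  rownames(out) <- NULL
  out
}

#' Merge replicate-supported regions across reporter contexts
#'
#' Regions from the two reporter screens that overlap by at least
#' `min_overlap` of the shorter region collapse to the longest region of
#' their overlap cluster; `reporter_support` records which screens contained
#' a member of the cluster.
#'
#' @param z,e region data.frames for the two reporters (`e` may be NULL for
#'   a single-reporter screen).
#' @param reporters names of the two reporter contexts.
#' @param min_overlap overlap fraction of the shorter region (default 0.5).
#' @return data.frame: gene_id, nt_start, nt_end, reporter_support
#'   (comma-separated).
#' @export
merge_reporters <- function(z, e = NULL, reporters = c("zfh1", "ent1"),
                            min_overlap = 0.5) {
  if (is.null(e) || !nrow(e)) {
    if (!nrow(z))
      return(data.frame(gene_id = character(), nt_start = integer(),
                        nt_end = integer(),
                        reporter_support = character(),
                        stringsAsFactors = FALSE))
    out <- z[, c("gene_id", "nt_start", "nt_end")]
    out$reporter_support <- reporters[1]
    return(out)
  }
  if (!nrow(z)) {
    out <- e[, c("gene_id", "nt_start", "nt_end")]
    out$reporter_support <- reporters[2]
    return(out)
  }
  pool <- rbind(
    cbind(z[, c("gene_id", "nt_start", "nt_end")], src = reporters[1]),
    cbind(e[, c("gene_id", "nt_start", "nt_end")], src = reporters[2]))
  out <- lapply(split(pool, pool$gene_id), function(d) {
    n <- nrow(d)
    # union-find over the >=50%-of-shorter overlap relation
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i >= j) next
      ov <- overlap_len(d$nt_start[i], d$nt_end[i],
                        d$nt_start[j], d$nt_end[j])
      shorter <- min(d$nt_end[i] - d$nt_start[i],
                     d$nt_end[j] - d$nt_start[j])
      if (ov > 0 && ov >= min_overlap * shorter)
        parent[find(j)] <- find(i)
    }
    comp <- vapply(seq_len(n), find, integer(1))
    do.call(rbind, lapply(unique(comp), function(cc) {
      m <- d[comp == cc, , drop = FALSE]
      len <- m$nt_end - m$nt_start
      best <- which.max(len)
      data.frame(gene_id = m$gene_id[1],
                 nt_start = m$nt_start[best], nt_end = m$nt_end[best],
                 reporter_support = paste(sort(unique(m$src)),
                                          collapse = ","),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Reporter preference of an RD region
#'
#' An RD is labelled with a reporter when its enrichment in that reporter's
#' screens exceeds the other's by more than `threshold`-fold; otherwise it
#' is a "global" hit.
#'
#' @param fc_z,fc_e mean region enrichment in the two reporter contexts
#'   (both > 0).
#' @param threshold preference fold threshold (default 1.3; the boundary
#'   ratio itself is global).
#' @param labels reporter labels.
#' @return character vector in `c(labels, "global")`.
#' @export
reporter_preference <- function(fc_z, fc_e, threshold = 1.3,
                                labels = c("zfh1", "ent1")) {
  if (any(fc_z <= 0 | fc_e <= 0, na.rm = TRUE))
    stop("region enrichments must be positive")
  ifelse(fc_z / fc_e > threshold, labels[1],
         ifelse(fc_e / fc_z > threshold, labels[2], "global"))
}

#' Most repressive tile of a region
#'
#' Among library tiles fully contained in the (extended) region - or, when
#' none fits, the tiles overlapping it maximally - returns the tile with the
#' highest tile-level enrichment computed from its collapsed fragment
#' counts; ties go to the leftmost tile.
#'
#' @param region one-row region data.frame (gene_id, nt_start, nt_end).
#' @param counts per-tile collapsed counts (oligo_id, n_neg, n_pos), e.g.
#'   from [tile_counts()] summed over the supporting screens.
#' @param lib the `tile_library`.
#' @param t_neg,t_pos fragment totals matching `counts`.
#' @return list(oligo_id, fc, nt_start, aa_seq).
#' @export
representative_tile <- function(region, counts, lib, t_neg, t_pos) {
  tiles <- lib$tiles[lib$tiles$gene_id == region$gene_id &
                       !lib$tiles$multi_origin, , drop = FALSE]
  if (!nrow(tiles)) stop("no tiles for gene ", region$gene_id)
  tlen <- lib$tile_len
  inside <- tiles$nt_start >= region$nt_start &
    tiles$nt_start + tlen <= region$nt_end
  if (any(inside)) {
    cand <- tiles[inside, , drop = FALSE]
  } else {
    ov <- overlap_len(tiles$nt_start, tiles$nt_start + tlen,
                      region$nt_start, region$nt_end)
    if (max(ov) == 0) stop("no tile overlaps region")
    cand <- tiles[ov == max(ov), , drop = FALSE]
  }
  idx <- match(cand$oligo_id, counts$oligo_id)
  n_neg <- ifelse(is.na(idx), 0L, counts$n_neg[idx])
  n_pos <- ifelse(is.na(idx), 0L, counts$n_pos[idx])
  fc <- (n_neg / t_neg) / (n_pos / t_pos)
  fc[n_pos == 0 & n_neg > 0] <- Inf
  fc[n_pos == 0 & n_neg == 0] <- -Inf   # uncovered tiles never win
  ord <- order(-fc, -n_neg, cand$nt_start)
  best <- ord[1]
  list(oligo_id = cand$oligo_id[best], fc = fc[best],
       nt_start = cand$nt_start[best], aa_seq = cand$aa_seq[best])
}

#' Sensitivity/specificity against an external TF activity benchmark
#'
#' Classifies benchmark transcription factors by the sum of their activity
#' scores over the benchmark's contexts - nonactivator (sum <= 0), weakly
#' repressive (< -10), repressor (< -20), strongly repressive (< -35);
#' classes are nested - and reports, per class, how many have at least one
#' called RD under the standard and under the lenient calling thresholds.
#'
#' @param activity data.frame: tf, score_sum.
#' @param rd_tfs character vector of TFs with >= 1 RD at standard
#'   thresholds.
#' @param lenient_rd_tfs same under lenient calling (P <= 1e-3,
#'   FC >= 1.2).
#' @return data.frame: class, n, n_rd, frac_rd, n_rd_lenient,
#'   frac_rd_lenient.
#' @export
sensitivity_specificity <- function(activity, rd_tfs,
                                    lenient_rd_tfs = rd_tfs) {
  cls <- list(nonactivator = activity$score_sum <= 0,
              weak = activity$score_sum < -10,
              repressor = activity$score_sum < -20,
              strong = activity$score_sum < -35)
  out <- lapply(names(cls), function(k) {
    tfs <- activity$tf[cls[[k]]]
    n <- length(tfs)
    n_rd <- sum(tfs %in% rd_tfs)
    n_len <- sum(tfs %in% lenient_rd_tfs)
    data.frame(class = k, n = n,
               n_rd = n_rd, frac_rd = if (n) n_rd / n else NA_real_,
               n_rd_lenient = n_len,
               frac_rd_lenient = if (n) n_len / n else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
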