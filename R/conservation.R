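# Column conservation on multiple sequence alignments (Karlin-style
# normalized pairwise similarity), projection onto reference proteins, and
# motif-versus-flank conservation statistics.

#' Similarity matrix for conservation scoring
#'
#' BLOSUM62 shifted so its minimum entry maps to +1: the Karlin-style score
#' divides pairwise similarities by the geometric mean of the
#' self-similarities, which requires strictly positive entries.
#'
#' @return 20 x 20 positive similarity matrix over the amino-acid alphabet.
#' @export
conservation_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  B <- e$BLOSUM62[AA_ALPHABET, AA_ALPHABET]
  B + (1 - min(B))
}

#' Raw Karlin-style conservation of one alignment column
#'
#' `2 / (n (n - 1)) * sum_{i<j} M(a_i, a_j) / sqrt(M(a_i, a_i) M(a_j, a_j))`
#' over the non-gap residues of the column. Undefined (NA) with fewer than
#' two non-gap residues.
#'
#' @param column character vector of aligned residues (gaps as "-" or ".";
#'   residues outside the 20-letter alphabet are treated as gaps).
#' @param M positive similarity matrix (default [conservation_matrix()]).
#' @return raw score (unnormalized), or NA.
#' @export
column_conservation <- function(column, M = conservation_matrix()) {
  aa <- column[column %in% rownames(M)]
  n <- length(aa)
  if (n < 2L) return(NA_real_)
  idx <- match(aa, rownames(M))
  self <- sqrt(diag(M)[idx])
  tot <- 0
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    tot <- tot + sum(M[idx[i], idx[j]] / (self[i] * self[j]))
  }
  2 * tot / (n * (n - 1L))
}

#' Per-column conservation of an alignment, min-max normalized
#'
#' Raw Karlin-style scores for every column, then per-alignment min-max
#' normalization to \[0, 1\] (columns with fewer than two residues stay NA;
#' an alignment whose defined columns are all equal normalizes to 1).
#'
#' @param aln named character vector of aligned sequences (equal length).
#' @param M similarity matrix.
#' @param normalize apply the per-alignment min-max step (default TRUE).
#' @return numeric vector, one score per alignment column.
#' @export
alignment_conservation <- function(aln, M = conservation_matrix(),
                                   normalize = TRUE) {
  lens <- nchar(aln)
  if (length(unique(lens)) != 1L) stop("sequences are not aligned")
  mat <- do.call(rbind, strsplit(aln, ""))
  raw <- apply(mat, 2, function(col) column_conservation(col, M))
  if (!normalize) return(raw)
  ok <- !is.na(raw)
  if (!any(ok)) return(raw)
  lo <- min(raw[ok]); hi <- max(raw[ok])
  if (hi == lo) { raw[ok] <- 1; return(raw) }
  raw[ok] <- (raw[ok] - lo) / (hi - lo)
  raw
}

#' Project alignment conservation onto a reference protein
#'
#' Emits, in reference order, the scores of the columns where the reference
#' sequence has a residue; reference-gap columns are skipped.
#'
#' @param aln named character vector of aligned sequences.
#' @param ref_id name of the reference sequence in `aln`.
#' @param scores per-column scores (default: computed with
#'   [alignment_conservation()]).
#' @return object of class `conservation_track`: list(protein_id, scores,
#'   n_sequences).
#' @export
map_to_reference <- function(aln, ref_id, scores = NULL) {
  if (!ref_id %in% names(aln)) stop("reference ", ref_id, " not in alignment")
  if (is.null(scores)) scores <- alignment_conservation(aln)
  refc <- strsplit(aln[[ref_id]], "")[[1]]
  keep <- !(refc %in% c("-", "."))
  structure(list(protein_id = ref_id, scores = scores[keep],
                 n_sequences = length(aln)),
            class = "conservation_track")
}

#' Mean conservation of a motif instance versus its flanks
#'
#' The flank consists of one motif-length window upstream and one
#' downstream (total 2x the motif width; `flank_total` instead splits a
#' single motif-length across the two sides). Windows truncated at the
#' protein ends are used as available and flagged.
#'
#' @param aa_start,aa_end instance interval, 0-based half-open.
#' @param track a `conservation_track` (or plain numeric score vector).
#' @param flank_mode "per_side" (default; each side = motif width) or
#'   "total" (motif width split across sides).
#' @return list(motif_mean, flank_mean, truncated); flank_mean is NA when no
#'   flank residue exists.
#' @export
motif_vs_flank <- function(aa_start, aa_end, track,
                           flank_mode = c("per_side", "total")) {
  flank_mode <- match.arg(flank_mode)
  s <- if (inherits(track, "conservation_track")) track$scores else track
  L <- length(s)
  if (aa_start < 0L || aa_end > L || aa_end <= aa_start)
    stop("instance outside the conservation track")
  w <- aa_end - aa_start
  side <- if (flank_mode == "per_side") w else ceiling(w / 2)
  motif_mean <- mean(s[(aa_start + 1L):aa_end], na.rm = TRUE)
  up <- seq.int(aa_start - side + 1L, aa_start)
  down <- seq.int(aa_end + 1L, aa_end + side)
  up <- up[up >= 1L]
  down <- down[down <= L]
  truncated <- length(up) < side || length(down) < side
  fl <- s[c(up, down)]
  flank_mean <- if (length(fl)) mean(fl, na.rm = TRUE) else NA_real_
  list(motif_mean = motif_mean, flank_mean = flank_mean,
       truncated = truncated)
}

#' Paired Wilcoxon signed-rank tests of motif versus flank conservation
#'
#' One two-sided test per motif type on the (motif_mean, flank_mean) pairs;
#' exact for n <= `exact_max` without ties or zero differences, otherwise
#' the normal approximation with continuity correction; all-zero differences
#' give P = 1. BH correction across the motif types tested.
#'
#' @param pairs data.frame: type, motif_mean, flank_mean.
#' @param exact_max maximal n for the exact test (default 25).
#' @return data.frame: type, n, median_diff, p, fdr.
#' @export
paired_wilcoxon_fdr <- function(pairs, exact_max = 25L) {
  out <- lapply(split(pairs, pairs$type), function(d) {
    d <- d[complete.cases(d[, c("motif_mean", "flank_mean")]), ]
    diffs <- d$motif_mean - d$flank_mean
    n <- length(diffs)
    if (n == 0L || all(diffs == 0)) {
      p <- 1
    } else {
      nz <- diffs[diffs != 0]
      exact <- length(nz) <= exact_max && !any(duplicated(abs(nz)))
      p <- suppressWarnings(
        wilcox.test(d$motif_mean, d$flank_mean, paired = TRUE,
                    alternative = "two.sided", exact = exact,
                    correct = TRUE)$p.value)
    }
    data.frame(type = d$type[1], n = n, median_diff = median(diffs),
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$fdr <- p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Median conservation metaplot around motif instances
#'
#' Aligns instances on the motif center (or start) and reports, per relative
#' position within `+/- half_window`, the median conservation over the
#' instances with data at that position, together with their number.
#'
#' @param instances data.frame: sequence_id, aa_start, aa_end (0-based
#'   half-open).
#' @param tracks named list of conservation score vectors (or
#'   `conservation_track` objects) keyed by sequence_id.
#' @param half_window flank width in AA (default 100).
#' @param align "center" (default) or "start".
#' @return data.frame: rel_pos, median_score, n.
#' @export
conservation_metaplot <- function(instances, tracks, half_window = 100L,
                                  align = c("center", "start")) {
  align <- match.arg(align)
  if (!nrow(instances)) stop("no instances")
  rel <- seq.int(-half_window, half_window)
  vals <- matrix(NA_real_, nrow(instances), length(rel))
  for (i in seq_len(nrow(instances))) {
    tr <- tracks[[instances$sequence_id[i]]]
    s <- if (inherits(tr, "conservation_track")) tr$scores else tr
    anchor <- if (align == "center")
      floor((instances$aa_start[i] + instances$aa_end[i]) / 2)
    else instances$aa_start[i]
    pos <- anchor + rel + 1L   # 1-based index into s
    ok <- pos >= 1L & pos <= length(s)
    vals[i, ok] <- s[pos[ok]]
  }
  data.frame(rel_pos = rel,
             median_score = apply(vals, 2, median, na.rm = TRUE),
             n = colSums(!is.na(vals)))
}

#' Simulate a synthetic protein alignment
#'
#' Emits the reference plus `n_seqs - 1` mutated copies: every residue is
#' substituted with probability `sub_rate`, lowered to `conserved_rate`
#' inside the given intervals - a minimal stand-in for an orthogroup
#' alignment with conserved motifs (no indels, so the "alignment" is the
#' sequences themselves).
#'
#' @param ref reference amino-acid sequence.
#' @param n_seqs total sequences including the reference.
#' @param sub_rate per-site substitution probability outside conserved
#'   intervals.
#' @param conserved data.frame with aa_start, aa_end (0-based half-open), or
#'   NULL.
#' @param conserved_rate substitution probability inside conserved
#'   intervals.
#' @param seed integer seed.
#' @return named character vector of aligned sequences (reference first,
#'   named "ref").
#' @export
simulate_alignment <- function(ref, n_seqs, sub_rate = 0.5,
                               conserved = NULL, conserved_rate = 0.05,
                               seed = 1L) {
  set.seed(seed)
  chars <- strsplit(ref, "")[[1]]
  L <- length(chars)
  rate <- rep(sub_rate, L)
  if (!is.null(conserved) && nrow(conserved)) {
    for (i in seq_len(nrow(conserved))) {
      idx <- (conserved$aa_start[i] + 1L):conserved$aa_end[i]
      rate[idx] <- conserved_rate
    }
  }
  out <- c(ref = ref)
  for (k in seq_len(n_seqs - 1L)) {
    mut <- chars
    hit <- runif(L) < rate
    if (any(hit))
      mut[hit] <- vapply(mut[hit], function(a)
        sample(setdiff(AA_ALPHABET, a), 1L), character(1))
    out[paste0("sp", k)] <- paste(mut, collapse = "")
  }
  out
}
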