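# Protein motif analysis: minimal-MEME PWM input, FIMO-style scanning with
# exact P-values via dynamic programming over discretized log-odds scores,
# regex SLiM scanning, motif similarity/clustering and RD classification.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Construct a protein position weight matrix
#'
#' @param motif_id identifier.
#' @param mat 20 x w probability matrix (rows = amino acids in alphabetical
#'   one-letter order, columns sum to 1).
#' @param background length-20 background distribution (default uniform).
#' @param source free-text source tag (e.g. which RD subset it came from).
#' @param pseudo floor applied to zero cells, with renormalization
#'   (default 1e-4); keeps log-odds and KL finite.
#' @return object of class `pwm`.
#' @export
pwm <- function(motif_id, mat, background = rep(1 / 20, 20),
                source = NA_character_, pseudo = 1e-4) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 20) stop("PWM must have 20 rows (amino acids)")
  rownames(mat) <- AA_ALPHABET
  if (any(mat < 0)) stop("negative probabilities in PWM ", motif_id)
  # 1e-3 slack tolerates matrices rounded to printed precision
  if (any(abs(colSums(mat) - 1) > 1e-3))
    stop("PWM columns must sum to 1 (motif ", motif_id, ")")
  if (pseudo > 0) mat <- pmax(mat, pseudo)
  mat <- sweep(mat, 2, colSums(mat), "/")
  background <- background / sum(background)
  names(background) <- AA_ALPHABET
  structure(list(motif_id = motif_id, width = ncol(mat), mat = mat,
                 background = background, source = source),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("pwm", x$motif_id, "width", x$width, "\n")
  invisible(x)
}

#' Read motifs in MEME minimal text format
#'
#' Parses version, alphabet, background-frequency line and every
#' `letter-probability matrix` block. Zero cells are floored at `pseudo`
#' and columns renormalized.
#'
#' @param path MEME minimal format file.
#' @param pseudo pseudoprobability floor (default 1e-4).
#' @return list of `pwm` objects, in file order.
#' @export
read_meme <- function(path, pseudo = 1e-4) {
  lines <- trimws(readLines(path))
  bg <- rep(1 / 20, 20)
  names(bg) <- AA_ALPHABET
  i <- grep("^Background letter frequencies", lines)
  if (length(i)) {
    toks <- character(0)
    j <- i[1] + 1L
    while (j <= length(lines) && !grepl("^MOTIF", lines[j]) &&
           nzchar(lines[j])) {
      toks <- c(toks, strsplit(lines[j], "\\s+")[[1]])
      j <- j + 1L
    }
    if (length(toks) %% 2L == 0L && length(toks) > 0L) {
      lett <- toks[seq(1, length(toks), 2)]
      freq <- as.numeric(toks[seq(2, length(toks), 2)])
      hit <- match(AA_ALPHABET, lett)
      if (!anyNA(hit)) bg <- freq[hit]
    }
  }
  starts <- grep("^MOTIF\\b", lines)
  if (!length(starts)) stop("no MOTIF entries in ", path)
  lapply(starts, function(s) {
    motif_id <- strsplit(lines[s], "\\s+")[[1]][2]
    h <- s + 1L
    while (h <= length(lines) &&
           !grepl("^letter-probability matrix", lines[h]))
      h <- h + 1L
    if (h > length(lines))
      stop("motif ", motif_id, ": missing letter-probability matrix header")
    w <- as.integer(sub(".*\\bw=\\s*(\\d+).*", "\\1", lines[h]))
    alen <- as.integer(sub(".*alength=\\s*(\\d+).*", "\\1", lines[h]))
    if (is.na(alen)) alen <- 20L
    if (alen != 20L)
      stop("motif ", motif_id, ": alphabet length ", alen, ", expected 20")
    rows <- lines[(h + 1L):(h + w)]
    vals <- lapply(rows, function(r) as.numeric(strsplit(r, "\\s+")[[1]]))
    if (any(vapply(vals, length, integer(1)) != 20L) || anyNA(unlist(vals)))
      stop("motif ", motif_id, ": malformed probability row")
    mat <- t(do.call(rbind, vals))   # rows AA, cols positions
    pwm(motif_id, mat, background = bg, pseudo = pseudo)
  })
}

#' Write motifs in MEME minimal text format
#'
#' @param pwms list of `pwm` objects.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_meme <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACDEFGHIKLMNPQRSTVWY", "",
               "Background letter frequencies"), con)
  bg <- pwms[[1]]$background
  writeLines(paste(paste(AA_ALPHABET, sprintf("%.6f", bg)), collapse = " "),
             con)
  for (m in pwms) {
    writeLines(c("", paste("MOTIF", m$motif_id),
                 sprintf("letter-probability matrix: alength= 20 w= %d",
                         m$width)), con)
    for (j in seq_len(m$width))
      writeLines(paste(sprintf("%.6f", m$mat[, j]), collapse = " "), con)
  }
  invisible(path)
}

# Discretized log-odds score matrix (integer units of `granularity` bits)
# and the exact null score distribution over windows drawn from the
# background, computed by dynamic programming (convolution over columns).
pwm_score_table <- function(pwm, granularity = 1e-3) {
  s_bits <- log2(sweep(pwm$mat, 1, pwm$background, "/"))
  s_int <- round(s_bits / granularity)
  list(s_bits = s_bits, s_int = s_int)
}

#' FIMO-style PWM scan with exact P-values
#'
#' Scores every window of the peptide as the sum of per-column log2
#' likelihood ratios against the background. P-values are exact tail
#' probabilities of the null score distribution (windows drawn i.i.d. from
#' the background), computed by dynamic programming over columns after
#' discretizing scores to `granularity` bits; the observed score is
#' discretized identically, so DP and enumeration agree exactly.
#'
#' @param pwm a `pwm`.
#' @param peptide amino-acid sequence (character scalar).
#' @param p_threshold report windows with P not exceeding the threshold
#'   (default 1e-4, the stringent scanning cutoff; 1e-3 is the lenient
#'   one).
#' @param granularity score discretization in bits (default 1e-3).
#' @param sequence_id identifier recorded in the output.
#' @return data.frame: motif_id, sequence_id, aa_start, aa_end (0-based
#'   half-open), score (bits), p.
#' @export
scan_pwm <- function(pwm, peptide, p_threshold = 1e-4,
                     granularity = 1e-3, sequence_id = NA_character_) {
  w <- pwm$width
  n <- nchar(peptide)
  empty <- data.frame(motif_id = character(), sequence_id = character(),
                      aa_start = integer(), aa_end = integer(),
                      score = numeric(), p = numeric(),
                      stringsAsFactors = FALSE)
  if (n < w) return(empty)
  st <- pwm_score_table(pwm, granularity)
  null <- scan_null_tail(st$s_int, pwm$background)
  chars <- strsplit(peptide, "")[[1]]
  idx <- match(chars, AA_ALPHABET)
  starts <- seq_len(n - w + 1L)
  int_scores <- integer(length(starts))
  bits <- numeric(length(starts))
  valid <- logical(length(starts))
  for (k in seq_along(starts)) {
    ii <- idx[starts[k]:(starts[k] + w - 1L)]
    if (anyNA(ii)) next
    valid[k] <- TRUE
    int_scores[k] <- sum(st$s_int[cbind(ii, seq_len(w))])
    bits[k] <- sum(st$s_bits[cbind(ii, seq_len(w))])
  }
  if (any(!valid))
    warning(sum(!valid), " window(s) skipped (non-standard residues)")
  p <- rep(NA_real_, length(starts))
  p[valid] <- null$tail_p(int_scores[valid])
  hit <- valid & p <= p_threshold
  data.frame(motif_id = pwm$motif_id, sequence_id = sequence_id,
             aa_start = starts[hit] - 1L, aa_end = starts[hit] - 1L + w,
             score = bits[hit], p = p[hit], stringsAsFactors = FALSE)
}

# Exact null tail over integer window scores: DP convolution over columns,
# letters weighted by the background. Returns a closure mapping integer
# scores to P(T >= t).
scan_null_tail <- function(s_int, background) {
  w <- ncol(s_int)
  col_min <- apply(s_int, 2, min)
  lo <- sum(col_min)
  hi <- sum(apply(s_int, 2, max))
  probs <- c(1)   # distribution of (partial score - partial lo)
  off <- 0L       # partial lo accumulated
  for (j in seq_len(w)) {
    shifts <- s_int[, j] - col_min[j]
    newlen <- length(probs) + max(shifts)
    acc <- numeric(newlen)
    for (a in seq_len(20)) {
      sh <- shifts[a]
      acc[(sh + 1L):(sh + length(probs))] <-
        acc[(sh + 1L):(sh + length(probs))] + background[a] * probs
    }
    probs <- acc
    off <- off + col_min[j]
  }
  tail_from <- rev(cumsum(rev(probs)))   # P(T >= lo + k - 1), k index
  list(
    probs = probs, lo = lo, hi = hi,
    tail_p = function(t) {
      k <- t - lo + 1L
      out <- numeric(length(t))
      out[k <= 1L] <- 1
      inr <- k > 1L & k <= length(tail_from)
      out[inr] <- tail_from[k[inr]]
      # above the maximum achievable score: impossible, tail = 0
      out
    }
  )
}

#' Scan a peptide with a short-linear-motif regex
#'
#' Reports all matches, including overlapping ones (each start position is
#' tested with an anchored match). The `p` field carries the pattern's
#' configured class probability, not a computed value.
#'
#' @param pattern list or one-row data.frame with `pattern_id`, `regex`,
#'   and optionally `class_p` (default NA).
#' @param peptide amino-acid sequence.
#' @param sequence_id identifier recorded in the output.
#' @return data.frame: pattern_id, sequence_id, aa_start, aa_end (0-based
#'   half-open), match, p.
#' @export
scan_slim <- function(pattern, peptide, sequence_id = NA_character_) {
  rx <- paste0("^(?:", pattern$regex, ")")
  n <- nchar(peptide)
  hits <- list()
  for (s in seq_len(n)) {
    m <- regexpr(rx, substr(peptide, s, n), perl = TRUE)
    if (m == 1L) {
      len <- attr(m, "match.length")
      hits[[length(hits) + 1L]] <- data.frame(
        pattern_id = pattern$pattern_id, sequence_id = sequence_id,
        aa_start = s - 1L, aa_end = s - 1L + len,
        match = substr(peptide, s, s + len - 1L),
        p = if (!is.null(pattern$class_p)) pattern$class_p else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(pattern_id = character(), sequence_id = character(),
                      aa_start = integer(), aa_end = integer(),
                      match = character(), p = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, hits)
}

#' Load the shipped SLiM pattern config
#'
#' Editable TSV of regex patterns for co-repressor-interacting short linear
#' motifs (EH1/Groucho, WRPW/Groucho, PxDLS/CtBP, AAxxL-SID/Sin3A, HBM/HCF).
#' The shipped patterns are literature-consensus approximations; replace the
#' file with patterns from an ELM release for database-exact scans.
#'
#' @param path TSV with columns pattern_id, regex, cor_label, class_p;
#'   defaults to the file shipped with the package.
#' @return data.frame of patterns.
#' @export
read_slim_patterns <- function(path = system.file("extdata",
                                                  "slim_patterns.tsv",
                                                  package = "rdscreen")) {
  read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}

#' Two-sided Fisher enrichment of a motif in RD versus non-RD tiles
#'
#' @param rd_with,rd_without counts of RD tiles with/without the motif.
#' @param nonrd_with,nonrd_without same over all non-RD non-overlapping
#'   tiles.
#' @return list(odds_ratio, p, table). A zero margin gives p = 1 and
#'   OR = NA.
#' @export
fisher_enrichment <- function(rd_with, rd_without, nonrd_with,
                              nonrd_without) {
  tab <- matrix(c(rd_with, rd_without, nonrd_with, nonrd_without),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("rd", "nonrd"), c("with", "without")))
  if (any(tab < 0)) stop("counts must be nonnegative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(odds_ratio = NA_real_, p = 1, table = tab))
  ft <- fisher.test(tab, alternative = "two.sided")
  list(odds_ratio = unname(ft$estimate), p = ft$p.value, table = tab)
}

# symmetric Kullback-Leibler divergence between two distributions (bits)
sym_kl <- function(p, q) {
  0.5 * (sum(p * log2(p / q)) + sum(q * log2(q / p)))
}

#' Kullback-based distance between two protein PWMs
#'
#' For every ungapped offset with at least `min_overlap` aligned columns,
#' the distance is the mean symmetric Kullback-Leibler divergence over the
#' union span of the two motifs - aligned column pairs compared with each
#' other, columns left unaligned compared against the background. The motif
#' distance is the minimum over offsets (no reverse orientation: protein
#' motifs). Symmetric with zero diagonal.
#'
#' @param a,b `pwm` objects (pseudocount-floored columns keep the KL
#'   finite).
#' @param min_overlap minimal aligned columns per offset (default 4).
#' @return nonnegative distance; `Inf` when no offset reaches the minimal
#'   overlap.
#' @export
motif_distance <- function(a, b, min_overlap = 4L) {
  wa <- a$width; wb <- b$width
  bg <- a$background
  best <- Inf
  for (off in seq(-(wb - 1L), wa - 1L)) {
    ov <- min(wa, wb + off) - max(1L, 1L + off) + 1L
    if (ov < min_overlap) next
    span <- seq(min(1L, 1L + off), max(wa, wb + off))
    tot <- 0
    for (pos in span) {
      in_a <- pos >= 1L && pos <= wa
      jb <- pos - off
      in_b <- jb >= 1L && jb <= wb
      tot <- tot + if (in_a && in_b) sym_kl(a$mat[, pos], b$mat[, jb])
      else if (in_a) sym_kl(a$mat[, pos], bg)
      else sym_kl(b$mat[, jb], bg)
    }
    best <- min(best, tot / length(span))
  }
  best
}

#' All-pairs motif distance matrix
#'
#' @param pwms list of `pwm` objects.
#' @inheritParams motif_distance
#' @return symmetric matrix of [motif_distance()] values.
#' @export
motif_distance_matrix <- function(pwms, min_overlap = 4L) {
  n <- length(pwms)
  ids <- vapply(pwms, function(m) m$motif_id, character(1))
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    D[i, j] <- D[j, i] <- motif_distance(pwms[[i]], pwms[[j]], min_overlap)
  }
  D
}

#' Cluster motifs by correlation of their distance profiles
#'
#' The secondary metric between two motifs is 1 - Pearson correlation of
#' their rows in the distance matrix; complete-linkage agglomeration is cut
#' at `cut_height` to yield flat clusters. Rows with undefined correlation
#' (constant profiles) are treated as maximally distant, with a warning.
#'
#' @param D symmetric motif distance matrix (see
#'   [motif_distance_matrix()]).
#' @param cut_height tree cut height (default 0.7).
#' @return integer cluster labels named by motif id.
#' @export
cluster_motifs <- function(D, cut_height = 0.7) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  if (nrow(D) == 1L) return(setNames(1L, rownames(D)))
  cc <- suppressWarnings(cor(t(D)))
  d2 <- 1 - cc
  if (anyNA(d2)) {
    warning("constant distance profile(s): treated as maximally distant")
    d2[is.na(d2)] <- 2
  }
  diag(d2) <- 0
  hc <- hclust(as.dist(d2), method = "complete")
  cutree(hc, h = cut_height)
}

#' Classify RDs as known, novel or unexplained
#'
#' An RD is "known" when its representative tile carries an instance of an
#' annotated co-repressor-interacting SLiM; among the rest, RDs with a
#' discovered-motif (PWM) instance below `meme_p` - excluding designated
#' low-complexity motifs - are "novel"; the remainder are "unexplained".
#'
#' @param rd_ids character vector of RD identifiers (the universe).
#' @param elm_instances data.frame with `sequence_id` (RD id) and
#'   `pattern_id`.
#' @param meme_instances data.frame with `sequence_id`, `motif_id`, `p`.
#' @param meme_p classification P cutoff for PWM instances (default 1e-5).
#' @param exclude_motifs motif ids ignored for classification (e.g.
#'   low-complexity Q/H runs).
#' @return list: `classes` (data.frame rd_id, class), `motif_counts`
#'   (per-motif RD counts), `cooccurrence` (motif x motif RD count matrix).
#' @export
classify_rds <- function(rd_ids, elm_instances, meme_instances,
                         meme_p = 1e-5, exclude_motifs = character()) {
  known <- unique(elm_instances$sequence_id)
  mi <- meme_instances[!is.na(meme_instances$p) &
                         meme_instances$p < meme_p &
                         !(meme_instances$motif_id %in% exclude_motifs), ,
                       drop = FALSE]
  novel <- setdiff(unique(mi$sequence_id), known)
  class <- ifelse(rd_ids %in% known, "known",
                  ifelse(rd_ids %in% novel, "novel", "unexplained"))
  pairs <- rbind(
    data.frame(rd = elm_instances$sequence_id,
               motif = elm_instances$pattern_id,
               stringsAsFactors = FALSE),
    data.frame(rd = mi$sequence_id, motif = mi$motif_id,
               stringsAsFactors = FALSE))
  pairs <- unique(pairs[pairs$rd %in% rd_ids, , drop = FALSE])
  motif_counts <- table(pairs$motif)
  motifs <- sort(unique(pairs$motif))
  co <- matrix(0L, length(motifs), length(motifs),
               dimnames = list(motifs, motifs))
  for (r in unique(pairs$rd)) {
    ms <- pairs$motif[pairs$rd == r]
    co[ms, ms] <- co[ms, ms] + 1L
  }
  list(classes = data.frame(rd_id = rd_ids, class = class,
                            stringsAsFactors = FALSE),
       motif_counts = motif_counts, cooccurrence = co)
}

#' Per-position amino-acid frequencies around motif instances
#'
#' Retrieves each instance's core plus `flank` residues on each side from
#' its source protein (positions falling outside the protein are treated as
#' missing) and returns per-position residue frequencies over the available
#' sequences - the matrix behind an amino-acid sequence logo.
#'
#' @param instances data.frame: sequence_id, aa_start, aa_end (0-based
#'   half-open, constant width).
#' @param proteins named character vector of protein sequences.
#' @param flank flanking residues on each side (default 10).
#' @return 20 x (width + 2 * flank) frequency matrix (columns sum to 1 over
#'   observed residues) with attribute `n` = sequences observed per
#'   position.
#' @export
logo_frequencies <- function(instances, proteins, flank = 10L) {
  if (!nrow(instances)) stop("empty instance set")
  w <- unique(instances$aa_end - instances$aa_start)
  if (length(w) != 1L) stop("instances must share one core width")
  ncol_out <- w + 2L * flank
  chars <- matrix(NA_character_, nrow(instances), ncol_out)
  for (i in seq_len(nrow(instances))) {
    seqc <- proteins[[instances$sequence_id[i]]]
    if (is.null(seqc) || is.na(seqc))
      stop("protein ", instances$sequence_id[i], " not provided")
    L <- nchar(seqc)
    pos <- (instances$aa_start[i] - flank + 1L):(instances$aa_end[i] + flank)
    ok <- pos >= 1L & pos <= L
    chars[i, ok] <- substring(seqc, pos[ok], pos[ok])
  }
  freq <- matrix(0, 20, ncol_out,
                 dimnames = list(AA_ALPHABET,
                                 seq_len(ncol_out) - flank - 1L))
  n <- integer(ncol_out)
  for (j in seq_len(ncol_out)) {
    col <- chars[, j]
    col <- col[!is.na(col) & col %in% AA_ALPHABET]
    n[j] <- length(col)
    if (n[j]) freq[, j] <- tabulate(match(col, AA_ALPHABET), 20) / n[j]
  }
  attr(freq, "n") <- n
  freq
}
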