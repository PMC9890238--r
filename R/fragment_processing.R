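# UMI deduplication and protein-centric coverage.
#
# Coordinate convention, used everywhere in the package: nucleotide positions
# are 0-based half-open offsets within a CDS; the amino-acid coordinate of a
# nucleotide is floor(nt / 3); user-facing reports convert to 1-based closed
# AA intervals.

umis_to_int_matrix <- function(umis, umi_len) {
  matrix(utf8ToInt(paste(umis, collapse = "")),
         ncol = umi_len, byrow = TRUE)
}

# Greedy count-ordered absorption within one oligo group. `mat` rows are
# UMIs (integer codes) already sorted by descending read_count, ties broken
# lexicographically. Returns the index of the retained representative for
# each row.
greedy_absorb <- function(mat, max_mismatch) {
  n <- nrow(mat)
  rep_of <- integer(n)
  retained <- integer(0)
  for (i in seq_len(n)) {
    assigned <- FALSE
    for (r in retained) {
      if (sum(mat[r, ] != mat[i, ]) <= max_mismatch) {
        rep_of[i] <- r
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      retained <- c(retained, i)
      rep_of[i] <- i
    }
  }
  rep_of
}

#' Collapse UMI duplicates
#'
#' Within each (fraction, replicate, reporter, oligo_id) group, fragments
#' whose UMIs differ by at most `max_mismatch` of the `umi_len` nucleotides
#' are treated as PCR duplicates of one molecule. Collapse is greedy in
#' decreasing read-count order (ties broken lexicographically by UMI): each
#' UMI is absorbed into the first already-retained UMI within Hamming
#' distance `max_mismatch`, so absorption is not transitive. Malformed UMIs
#' (wrong length or characters outside ACGT) are dropped with a warning
#' reporting their number.
#'
#' @param records fragment table: data.frame with columns oligo_id, umi,
#'   fraction, replicate, reporter and optionally read_count (default 1).
#' @param max_mismatch maximal Hamming distance absorbed (default 2).
#' @param umi_len expected UMI length (default 10).
#' @return collapsed fragment table, one row per retained molecule, with
#'   read_count summed over absorbed duplicates.
#' @export
collapse_umis <- function(records, max_mismatch = 2L, umi_len = 10L) {
  req <- c("oligo_id", "umi", "fraction", "replicate", "reporter")
  stopifnot(all(req %in% names(records)))
  dt <- data.table::as.data.table(records)
  if (!"read_count" %in% names(dt)) dt[, read_count := 1L]
  ok <- nchar(dt$umi) == umi_len & !grepl("[^ACGT]", dt$umi)
  if (!all(ok)) {
    warning(sum(!ok), " record(s) with malformed UMIs rejected")
    dt <- dt[ok]
  }
  if (!nrow(dt)) return(as.data.frame(dt))
  # identical (group, UMI) rows are exact duplicates: pool reads first
  dt <- dt[, .(read_count = sum(read_count)),
           by = .(fraction, replicate, reporter, oligo_id, umi)]
  data.table::setorder(dt, fraction, replicate, reporter, oligo_id,
                       -read_count, umi)
  dt[, grp := .GRP, by = .(fraction, replicate, reporter, oligo_id)]
  mat <- umis_to_int_matrix(dt$umi, umi_len)
  grp_rows <- split(seq_len(nrow(dt)), dt$grp)
  keep_umi <- dt$umi
  for (rows in grp_rows) {
    if (length(rows) == 1L) next
    rep_of <- greedy_absorb(mat[rows, , drop = FALSE], max_mismatch)
    keep_umi[rows] <- dt$umi[rows[rep_of]]
  }
  dt[, umi := keep_umi]
  out <- dt[, .(read_count = sum(read_count)),
            by = .(oligo_id, umi, fraction, replicate, reporter)]
  data.table::setorder(out, fraction, replicate, reporter, oligo_id, umi)
  as.data.frame(out)
}

#' Protein-centric coverage tracks for one screen stratum
#'
#' Transforms collapsed, oligo-centric fragments of a single
#' (replicate, reporter) stratum into per-gene coverage: each collapsed
#' fragment adds +1 over the nucleotide interval
#' `[nt_start, nt_start + tile_len)` of its gene in its fraction's track.
#' Multi-origin tiles (identical sequence from several loci, which cannot be
#' mapped uniquely) and unknown oligo ids are counted and skipped.
#'
#' @param collapsed collapsed fragment table (see [collapse_umis()])
#'   restricted to one replicate and one reporter, containing both fractions.
#' @param lib the `tile_library` the fragments map to.
#' @param drop_multi_origin exclude multi-origin tiles (default TRUE).
#' @return object of class `coverage_tracks`: list with `tracks` (named list
#'   gene -> list(neg, pos) integer vectors of CDS length), `t_neg`/`t_pos`
#'   (stratum-wide collapsed fragment totals), `n_skipped`.
#' @export
to_gene_coords <- function(collapsed, lib, drop_multi_origin = TRUE) {
  stopifnot(inherits(lib, "tile_library"))
  if (length(unique(collapsed$replicate)) > 1L ||
      length(unique(collapsed$reporter)) > 1L)
    stop("to_gene_coords expects a single (replicate, reporter) stratum")
  tiles <- lib$tiles
  idx <- match(collapsed$oligo_id, tiles$oligo_id)
  unknown <- is.na(idx)
  multi <- !unknown & drop_multi_origin & tiles$multi_origin[idx]
  skip <- unknown | multi
  n_skipped <- c(unknown = sum(unknown), multi_origin = sum(multi))
  use <- which(!skip)
  gene <- tiles$gene_id[idx[use]]
  start <- tiles$nt_start[idx[use]]
  fraction <- collapsed$fraction[use]
  tlen <- lib$tile_len
  tracks <- lapply(seq_len(nrow(lib$genes)), function(i) {
    L <- lib$genes$cds_len[i]
    list(neg = integer(L), pos = integer(L))
  })
  names(tracks) <- lib$genes$gene_id
  for (fr in c("neg", "pos")) {
    sel <- fraction == fr
    if (!any(sel)) next
    by_gene <- split(start[sel], gene[sel])
    for (g in names(by_gene)) {
      L <- length(tracks[[g]][[fr]])
      cov <- IRanges::coverage(
        IRanges::IRanges(start = by_gene[[g]] + 1L, width = tlen),
        width = L)
      tracks[[g]][[fr]] <- as.integer(cov)
    }
  }
  structure(
    list(tracks = tracks,
         t_neg = sum(fraction == "neg"),
         t_pos = sum(fraction == "pos"),
         n_skipped = n_skipped,
         replicate = collapsed$replicate[1],
         reporter = collapsed$reporter[1]),
    class = "coverage_tracks"
  )
}

#' @export
print.coverage_tracks <- function(x, ...) {
  cat("coverage_tracks:", length(x$tracks), "genes; T_neg =", x$t_neg,
      ", T_pos =", x$t_pos, "\n")
  invisible(x)
}

#' Counts-per-million normalized track
#'
#' Display-only scaling of a coverage vector by its stratum total:
#' `coverage * 1e6 / total`. Statistics always use raw collapsed counts.
#'
#' @param coverage integer coverage vector.
#' @param total stratum-wide collapsed fragment total (> 0).
#' @return numeric CPM vector.
#' @export
normalized_track <- function(coverage, total) {
  if (total <= 0) stop("stratum total must be positive")
  coverage * 1e6 / total
}

#' Per-tile collapsed fragment counts
#'
#' Counts collapsed molecules per (oligo_id, fraction) for one stratum;
#' used for representative-tile selection and tile-strength analyses.
#'
#' @inheritParams to_gene_coords
#' @return data.frame: oligo_id, n_neg, n_pos.
#' @export
tile_counts <- function(collapsed, lib, drop_multi_origin = TRUE) {
  dt <- data.table::as.data.table(collapsed)
  tiles <- lib$tiles
  idx <- match(dt$oligo_id, tiles$oligo_id)
  keep <- !is.na(idx) & !(drop_multi_origin & tiles$multi_origin[idx])
  dt <- dt[keep]
  counts <- dt[, .N, by = .(oligo_id, fraction)]
  wide <- data.table::dcast(counts, oligo_id ~ fraction, value.var = "N",
                            fill = 0L)
  for (col in c("neg", "pos"))
    if (!col %in% names(wide)) wide[, (col) := 0L]
  out <- as.data.frame(wide[, .(oligo_id, n_neg = neg, n_pos = pos)])
  out
}

#' Export coverage as bedGraph against the concatenated linear genome
#'
#' @param tracks a `coverage_tracks` object.
#' @param fraction "neg" or "pos".
#' @param genome result of [linear_genome()] (provides per-gene offsets).
#' @param path output file.
#' @param chrom chromosome name used for the concatenated sequence.
#' @return invisibly, the path.
#' @export
write_bedgraph <- function(tracks, fraction, genome, path,
                           chrom = "linear") {
  stopifnot(inherits(tracks, "coverage_tracks"),
            fraction %in% c("neg", "pos"))
  offs <- genome$offsets
  rows <- list()
  for (i in seq_len(nrow(offs))) {
    g <- offs$gene_id[i]
    v <- tracks$tracks[[g]][[fraction]]
    if (is.null(v)) next
    r <- S4Vectors::Rle(v)
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- ends - S4Vectors::runLength(r)
    rows[[i]] <- data.frame(
      chrom = chrom,
      start = offs$offset[i] + starts,
      end = offs$offset[i] + ends,
      value = S4Vectors::runValue(r))
  }
  bed <- do.call(rbind, rows)
  bed <- bed[bed$value != 0, , drop = FALSE]
  header <- sprintf("track type=bedGraph name=\"%s_%s_rep%s\"",
                    tracks$reporter, fraction, tracks$replicate)
  writeLines(header, path)
  write.table(bed, path, append = TRUE, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
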