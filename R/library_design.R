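#' @import data.table
#' @importFrom stats p.adjust phyper fisher.test wilcox.test t.test cor
#'   median cutree hclust as.dist rbinom rgamma rgeom runif setNames
#'   complete.cases aggregate quantile
#' @importFrom utils head tail write.table read.delim
#' @importFrom tools md5sum
NULL

# 5'/3' constant linkers flanking every synthesized oligo (partial Illumina
# i5 / i7 adapters).
ADAPTER_5 <- "TCCCTACACGACGCTCTTCCGATCT"
ADAPTER_3 <- "AGATCGGAAGAGCACACGTCTGAAC"

#' Validate a gene catalog
#'
#' A gene catalog is a data.frame with columns `gene_id`, `transcript_id`,
#' `priority_score` (integer 1-8; 1-4 = high-confidence genes tiled at 6-nt
#' steps, 5-8 tiled at 15-nt steps) and `cds` (nucleotide coding sequence).
#' Entries whose CDS is shorter than one tile or whose length is not a
#' multiple of 3 are dropped with a warning.
#'
#' @param catalog data.frame with the columns above.
#' @param tile_len tile length in nt (default 150).
#' @return the validated catalog (possibly with rows dropped).
#' @export
validate_catalog <- function(catalog, tile_len = 150L) {
  req <- c("gene_id", "transcript_id", "priority_score", "cds")
  missing_cols <- setdiff(req, names(catalog))
  if (length(missing_cols))
    stop("catalog is missing columns: ", paste(missing_cols, collapse = ", "))
  if (!nrow(catalog)) stop("empty gene catalog")
  if (anyDuplicated(catalog$gene_id))
    stop("duplicated gene_id in catalog")
  if (!all(catalog$priority_score %in% 1:8))
    stop("priority_score must be an integer in 1..8")
  len <- nchar(catalog$cds)
  bad_frame <- len %% 3L != 0L
  too_short <- len < tile_len
  if (any(bad_frame | too_short)) {
    warning(sum(bad_frame | too_short), " catalog entr(ies) rejected: ",
            sum(too_short), " shorter than ", tile_len, " nt, ",
            sum(bad_frame), " not a multiple of 3")
    catalog <- catalog[!(bad_frame | too_short), , drop = FALSE]
  }
  if (!nrow(catalog)) stop("no catalog entry passes the length checks")
  catalog
}

#' Step size for a gene priority score
#'
#' High-priority genes (score 1-4) are tiled densely at 6-nt (2-AA) steps,
#' lower-priority genes (score 5-8) at 15-nt (5-AA) steps.
#'
#' @param score integer vector of priority scores in 1..8.
#' @return integer vector of step sizes in nt.
#' @export
step_for_score <- function(score) {
  stopifnot(all(score %in% 1:8))
  ifelse(score <= 4L, 6L, 15L)
}

# no.init.codon: a tile can start mid-protein, so TTG/CTG must not be
# treated as initiator methionines
translate_nt <- function(nt) {
  as.character(Biostrings::translate(Biostrings::DNAStringSet(nt),
                                     no.init.codon = TRUE,
                                     if.fuzzy.codon = "X"))
}

#' Tile one CDS into frame-preserving windows
#'
#' Windows of `tile_len` nt start at 0, `step`, 2*`step`, ... while they fit
#' within the CDS. When the regular grid does not reach the end of the CDS,
#' one flush-end tile at start `L - tile_len` is appended provided that start
#' is a multiple of 3 (`flush_end = TRUE`), so the C-terminus is covered
#' without breaking the reading frame.
#'
#' @param cds nucleotide sequence (character scalar), length a multiple of 3
#'   and at least `tile_len`.
#' @param step step size in nt; must be a positive multiple of 3.
#' @param tile_len tile length in nt (default 150 = 50 AA).
#' @param flush_end append a frame-preserving flush-end tile when the grid
#'   leaves the C-terminus uncovered (default TRUE).
#' @return data.frame with columns `nt_start` (0-based offset), `nt_seq`,
#'   `aa_seq`, `step_used`.
#' @export
tile_cds <- function(cds, step, tile_len = 150L, flush_end = TRUE) {
  L <- nchar(cds)
  if (L %% 3L != 0L) stop("CDS length is not a multiple of 3")
  if (L < tile_len) stop("CDS shorter than one tile (", tile_len, " nt)")
  if (step <= 0L || step %% 3L != 0L)
    stop("step must be a positive multiple of 3")
  starts <- seq.int(0L, L - tile_len, by = step)
  last <- starts[length(starts)]
  flush <- L - tile_len
  if (flush_end && last < flush && flush %% 3L == 0L)
    starts <- c(starts, flush)
  nt <- substring(cds, starts + 1L, starts + tile_len)
  data.frame(
    nt_start = as.integer(starts),
    nt_seq = nt,
    aa_seq = translate_nt(nt),
    step_used = as.integer(step),
    stringsAsFactors = FALSE
  )
}

#' Design the full tiling library over a gene catalog
#'
#' Tiles every gene with the step size implied by its priority score,
#' collapses identical 150-nt sequences for the distinct-fragment count
#' (every origin is retained in `origins`), and flags multi-origin tiles,
#' which are excluded from per-gene coverage downstream because they cannot
#' be mapped uniquely.
#'
#' @param catalog validated gene catalog (see [validate_catalog()]).
#' @param tile_len tile length in nt.
#' @param flush_end see [tile_cds()].
#' @return an object of class `tile_library`: list with `tiles` (data.frame:
#'   oligo_id, gene_id, nt_start, step_used, nt_seq, aa_seq, multi_origin,
#'   has_stop), `origins` (all (gene,start) origins incl. duplicates),
#'   `n_distinct` (distinct 150-nt sequence count), `adapter_5`, `adapter_3`.
#' @export
design_library <- function(catalog, tile_len = 150L, flush_end = TRUE) {
  catalog <- validate_catalog(catalog, tile_len)
  per_gene <- lapply(seq_len(nrow(catalog)), function(i) {
    g <- catalog[i, ]
    t <- tile_cds(g$cds, step_for_score(g$priority_score), tile_len,
                  flush_end)
    t$gene_id <- g$gene_id
    t
  })
  tiles <- data.table::rbindlist(per_gene)
  data.table::setcolorder(tiles, c("gene_id", "nt_start"))
  tiles[, oligo_id := sprintf("%s_t%05d", gene_id, nt_start)]
  dup <- tiles[, .N, by = nt_seq]
  n_distinct <- nrow(dup)
  multi <- dup[N > 1L, nt_seq]
  tiles[, multi_origin := nt_seq %in% multi]
  tiles[, has_stop := grepl("*", aa_seq, fixed = TRUE)]
  origins <- as.data.frame(tiles[, .(oligo_id, gene_id, nt_start, nt_seq)])
  genes <- data.frame(gene_id = catalog$gene_id,
                      cds_len = nchar(catalog$cds),
                      stringsAsFactors = FALSE)
  structure(
    list(tiles = as.data.frame(tiles), origins = origins, genes = genes,
         n_distinct = n_distinct, tile_len = as.integer(tile_len),
         adapter_5 = ADAPTER_5, adapter_3 = ADAPTER_3),
    class = "tile_library"
  )
}

#' @export
print.tile_library <- function(x, ...) {
  cat("tile_library:", nrow(x$tiles), "tiles over",
      length(unique(x$tiles$gene_id)), "genes;",
      x$n_distinct, "distinct fragments\n")
  invisible(x)
}

#' Full-length synthesis oligo for a tile
#'
#' Prepends/appends the 25-nt constant linkers, yielding the 200-nt oligo as
#' synthesized.
#'
#' @param nt_seq tile nucleotide sequence(s) (150 nt each).
#' @param lib a `tile_library` (source of the adapter sequences); optional.
#' @return character vector of 200-nt oligos.
#' @export
with_adapters <- function(nt_seq, lib = NULL) {
  a5 <- if (is.null(lib)) ADAPTER_5 else lib$adapter_5
  a3 <- if (is.null(lib)) ADAPTER_3 else lib$adapter_3
  stopifnot(nchar(a5) == 25L, nchar(a3) == 25L)
  paste0(a5, nt_seq, a3)
}

#' Strip the constant linkers from a synthesis oligo
#'
#' @param oligo 200-nt oligo(s) produced by [with_adapters()].
#' @inheritParams with_adapters
#' @return the inner tile sequence(s).
#' @export
strip_adapters <- function(oligo, lib = NULL) {
  a5 <- if (is.null(lib)) ADAPTER_5 else lib$adapter_5
  a3 <- if (is.null(lib)) ADAPTER_3 else lib$adapter_3
  if (!all(startsWith(oligo, a5) & endsWith(oligo, a3)))
    stop("oligo does not carry the expected adapters")
  substr(oligo, nchar(a5) + 1L, nchar(oligo) - nchar(a3))
}

#' Concatenated "linear genome" for browser-track export
#'
#' Concatenates the genes' CDSs in catalog order, separated by a spacer of
#' N's, and returns both the sequence and the per-gene offset table used to
#' project CDS coordinates onto the linear genome.
#'
#' @param catalog validated gene catalog.
#' @param spacer number of N's between genes (default 2100).
#' @return list with `seq` (single character), `offsets` (data.frame:
#'   gene_id, offset, length).
#' @export
linear_genome <- function(catalog, spacer = 2100L) {
  catalog <- validate_catalog(catalog)
  lens <- nchar(catalog$cds)
  offs <- cumsum(c(0L, head(lens + spacer, -1L)))
  list(
    seq = paste(catalog$cds, collapse = strrep("N", spacer)),
    offsets = data.frame(gene_id = catalog$gene_id, offset = offs,
                         length = lens, stringsAsFactors = FALSE)
  )
}
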