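# Readers and writers for the exchanged plain-text formats. TSV is the
# interchange backbone; FASTA goes through Biostrings; BED/bedGraph are
# browser exports against the concatenated linear genome.

#' Read a gene catalog from TSV + CDS FASTA
#'
#' @param tsv_path TSV with columns gene_id, transcript_id, priority_score,
#'   cds_fasta_id (the FASTA record holding the CDS).
#' @param fasta_path nucleotide FASTA of coding sequences.
#' @return validated gene catalog data.frame.
#' @export
read_catalog <- function(tsv_path, fasta_path) {
  tab <- read.delim(tsv_path, stringsAsFactors = FALSE)
  req <- c("gene_id", "transcript_id", "priority_score", "cds_fasta_id")
  if (!all(req %in% names(tab)))
    stop("catalog TSV must have columns: ", paste(req, collapse = ", "))
  cds <- Biostrings::readDNAStringSet(fasta_path)
  names(cds) <- sub("\\s.*$", "", names(cds))
  hit <- match(tab$cds_fasta_id, names(cds))
  if (anyNA(hit))
    stop("CDS FASTA records missing for: ",
         paste(tab$cds_fasta_id[is.na(hit)], collapse = ", "))
  tab$cds <- as.character(cds[hit])
  validate_catalog(tab[, c("gene_id", "transcript_id", "priority_score",
                           "cds")])
}

#' Write a tile library (TSV, synthesis-oligo FASTA, linear genome)
#'
#' @param lib a `tile_library`.
#' @param catalog the catalog the library was designed from (for the linear
#'   genome); NULL skips the genome export.
#' @param dir output directory.
#' @param spacer N-spacer between genes in the linear genome.
#' @return invisibly, the written paths.
#' @export
write_library <- function(lib, catalog = NULL, dir,
                          spacer = 2100L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, "library.tsv")
  write.table(lib$tiles[, c("oligo_id", "gene_id", "nt_start", "step_used",
                            "nt_seq", "aa_seq")],
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  oligos <- Biostrings::DNAStringSet(with_adapters(lib$tiles$nt_seq, lib))
  names(oligos) <- lib$tiles$oligo_id
  fa <- file.path(dir, "oligos.fasta")
  Biostrings::writeXStringSet(oligos, fa)
  paths <- c(tsv, fa)
  if (!is.null(catalog)) {
    lg <- linear_genome(catalog, spacer)
    gen <- Biostrings::DNAStringSet(lg$seq)
    names(gen) <- "linear"
    gfa <- file.path(dir, "linear_genome.fasta")
    Biostrings::writeXStringSet(gen, gfa)
    write.table(lg$offsets, file.path(dir, "linear_offsets.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, gfa)
  }
  invisible(paths)
}

#' Read / write fragment tables
#'
#' Fragment tables are TSV with columns oligo_id, umi, fraction (neg/pos),
#' replicate, reporter and optionally read_count.
#'
#' @param path TSV file.
#' @return data.frame fragment table.
#' @export
read_fragments <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("oligo_id", "umi", "fraction", "replicate", "reporter")
  if (!all(req %in% names(tab)))
    stop("fragment TSV must have columns: ", paste(req, collapse = ", "))
  if (!all(tab$fraction %in% c("neg", "pos")))
    stop("fraction must be 'neg' or 'pos'")
  tab
}

#' @rdname read_fragments
#' @param fragments fragment table to write.
#' @export
write_fragments <- function(fragments, path) {
  write.table(fragments, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write called regions as TSV (1-based closed AA intervals)
#'
#' Internally coordinates are 0-based half-open nucleotide offsets; reports
#' use 1-based closed amino-acid intervals.
#'
#' @param regions final region table from [rd_pipeline()].
#' @param path output TSV.
#' @param cfg optional `pipeline_config` echoed into the header.
#' @return invisibly, the path.
#' @export
write_regions_tsv <- function(regions, path, cfg = NULL) {
  out <- regions
  if (nrow(out)) {
    out$aa_first <- out$aa_start + 1L
    out$aa_last <- out$aa_end
  } else {
    out$aa_first <- integer(0)
    out$aa_last <- integer(0)
  }
  drop <- c("aa_start", "aa_end")
  out <- out[, setdiff(names(out), drop), drop = FALSE]
  if (!is.null(cfg)) {
    write_tsv_with_header(out, path, cfg)
  } else {
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Export regions as BED against the linear genome
#'
#' @param regions region table (gene_id, nt_start, nt_end).
#' @param genome result of [linear_genome()].
#' @param path output BED file (0-based half-open, as BED requires).
#' @param chrom chromosome name of the concatenated sequence.
#' @return invisibly, the path.
#' @export
write_regions_bed <- function(regions, genome, path, chrom = "linear") {
  offs <- genome$offsets
  idx <- match(regions$gene_id, offs$gene_id)
  if (anyNA(idx)) stop("region gene(s) missing from the linear genome")
  bed <- data.frame(
    chrom = chrom,
    start = offs$offset[idx] + regions$nt_start,
    end = offs$offset[idx] + regions$nt_end,
    name = sprintf("%s_rd%02d", regions$gene_id,
                   seq_len(nrow(regions))))
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read an aligned FASTA into a named character vector
#'
#' @param path aligned FASTA (protein).
#' @return named character vector of aligned sequences.
#' @export
read_alignment <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  out <- as.character(aa)
  names(out) <- sub("\\s.*$", "", names(aa))
  out
}
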