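# Synthetic sort-seq screen generator. Emulates the generative structure of
# a pooled tethering screen: one library tile per cell, FACS partition into
# GFP-negative / GFP-positive fractions with a sort-error floor, 10-nt UMIs,
# geometric PCR duplication and per-nucleotide UMI sequencing errors.

SENSE_CODONS <- local({
  b <- c("A", "C", "G", "T")
  cod <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(cod, c("TAA", "TAG", "TGA"))
})

#' Simulation configuration
#'
#' Bundles every knob of the synthetic screen. Defaults describe the standard
#' validation scenario: 60 genes of ~400 AA, a quarter of them carrying one
#' planted repressive interval of 12 AA with strength in \[0.8, 1\], 2%
#' missorting, 200,000 cells per replicate and two replicates.
#'
#' @param n_genes number of genes in the synthetic catalog.
#' @param protein_len_mean,protein_len_cv gamma-distributed protein length
#'   (AA), mean and coefficient of variation.
#' @param min_protein_len floor on protein length (AA); shorter draws are
#'   redrawn.
#' @param priority_score tiling priority score given to every synthetic gene
#'   (1-4 = 6-nt steps, 5-8 = 15-nt steps).
#' @param fraction_with_rd fraction of genes carrying exactly one planted
#'   repressive interval; the planted count is `floor(n_genes * fraction)`.
#' @param strength_range range of the planted repressive strength s in (0,1];
#'   a cell whose tile fully contains the planted core sorts GFP-negative
#'   with probability `b + (1 - b) * s`.
#' @param core_len length (AA) of the planted minimal functional core.
#' @param sort_error FACS missorting probability b in \[0,1).
#' @param cells_per_replicate cells simulated (and sorted) per replicate.
#' @param n_replicates replicates per reporter.
#' @param dirichlet_alpha symmetric Dirichlet concentration for tile
#'   abundances in the plasmid pool.
#' @param pcr_mean mean PCR copy number per molecule (geometric, >= 1).
#' @param umi_len UMI length in nt.
#' @param umi_error_rate per-nucleotide UMI sequencing error probability.
#' @param reporter2_multiplier optional scalar or per-gene named vector;
#'   when non-NULL a second reporter context ("ent1") is simulated with
#'   planted strengths `pmin(1, strength * multiplier)`.
#' @param seed integer seed fixing the whole simulation bit-for-bit.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 60L,
                       protein_len_mean = 400,
                       protein_len_cv = 0.25,
                       min_protein_len = 100L,
                       priority_score = 1L,
                       fraction_with_rd = 0.25,
                       strength_range = c(0.8, 1),
                       core_len = 12L,
                       sort_error = 0.02,
                       cells_per_replicate = 200000L,
                       n_replicates = 2L,
                       dirichlet_alpha = 5,
                       pcr_mean = 1.5,
                       umi_len = 10L,
                       umi_error_rate = 0.001,
                       reporter2_multiplier = NULL,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              protein_len_mean = protein_len_mean,
              protein_len_cv = protein_len_cv,
              min_protein_len = as.integer(min_protein_len),
              priority_score = as.integer(priority_score),
              fraction_with_rd = fraction_with_rd,
              strength_range = strength_range,
              core_len = as.integer(core_len),
              sort_error = sort_error,
              cells_per_replicate = as.integer(cells_per_replicate),
              n_replicates = as.integer(n_replicates),
              dirichlet_alpha = dirichlet_alpha,
              pcr_mean = pcr_mean,
              umi_len = as.integer(umi_len),
              umi_error_rate = umi_error_rate,
              reporter2_multiplier = reporter2_multiplier,
              seed = as.integer(seed))
  stopifnot(cfg$n_genes >= 1L,
            cfg$fraction_with_rd >= 0, cfg$fraction_with_rd <= 1,
            all(cfg$strength_range > 0), all(cfg$strength_range <= 1),
            cfg$sort_error >= 0, cfg$sort_error < 1,
            cfg$pcr_mean >= 1,
            cfg$umi_error_rate >= 0, cfg$umi_error_rate <= 1,
            cfg$core_len >= 1L)
  class(cfg) <- "sim_config"
  cfg
}

random_cds <- function(n_aa) {
  paste(sample(SENSE_CODONS, n_aa, replace = TRUE), collapse = "")
}

#' Simulate a gene catalog with planted repressive intervals
#'
#' CDSs are uniform draws over the 61 sense codons (no internal stop in the
#' designed frame). `floor(n_genes * fraction_with_rd)` genes, chosen at
#' random, carry exactly one planted repressive interval equal to its
#' functional core.
#'
#' @param cfg a [sim_config()].
#' @return list with `catalog` (gene catalog data.frame) and `truth`
#'   (data.frame: gene_id, aa_start, aa_end 0-based half-open, strength,
#'   core_len; zero rows when nothing is planted).
#' @export
simulate_catalog <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  shape <- 1 / cfg$protein_len_cv^2
  n_aa <- integer(cfg$n_genes)
  for (i in seq_len(cfg$n_genes)) {
    len <- 0L
    while (len < cfg$min_protein_len)
      len <- as.integer(round(rgamma(1, shape = shape,
                                     scale = cfg$protein_len_mean / shape)))
    n_aa[i] <- len
  }
  gene_id <- sprintf("G%03d", seq_len(cfg$n_genes))
  catalog <- data.frame(
    gene_id = gene_id,
    transcript_id = paste0(gene_id, ".1"),
    priority_score = cfg$priority_score,
    cds = vapply(n_aa, random_cds, character(1)),
    stringsAsFactors = FALSE
  )
  n_rd <- floor(cfg$n_genes * cfg$fraction_with_rd)
  if (n_rd > 0) {
    carriers <- sort(sample.int(cfg$n_genes, n_rd))
    margin <- 5L
    aa_start <- vapply(carriers, function(i) {
      lo <- margin
      hi <- n_aa[i] - cfg$core_len - margin
      if (hi < lo) lo <- 0L
      if (hi < lo) hi <- lo
      as.integer(sample(lo:hi, 1))
    }, integer(1))
    truth <- data.frame(
      gene_id = gene_id[carriers],
      aa_start = aa_start,
      aa_end = aa_start + cfg$core_len,
      strength = runif(n_rd, cfg$strength_range[1], cfg$strength_range[2]),
      core_len = cfg$core_len,
      stringsAsFactors = FALSE
    )
  } else {
    truth <- data.frame(gene_id = character(), aa_start = integer(),
                        aa_end = integer(), strength = numeric(),
                        core_len = integer(), stringsAsFactors = FALSE)
  }
  list(catalog = catalog, truth = truth)
}

# integer <-> UMI string helpers (base-4 encoding, A=0 C=1 G=2 T=3)
umi_int_to_string <- function(x, umi_len) {
  bases <- c("A", "C", "G", "T")
  out <- matrix("", nrow = length(x), ncol = umi_len)
  for (k in seq_len(umi_len)) {
    out[, k] <- bases[x %% 4L + 1L]
    x <- x %/% 4L
  }
  do.call(paste0, as.data.frame(out, stringsAsFactors = FALSE))
}

mutate_umis <- function(umi_int, umi_len, rate) {
  if (rate <= 0) return(umi_int)
  n <- length(umi_int)
  nerr <- rbinom(n, umi_len, rate)
  hit <- which(nerr > 0L)
  for (i in hit) {
    pos <- sample.int(umi_len, nerr[i])
    for (p in pos) {
      digit <- (umi_int[i] %/% 4^(p - 1L)) %% 4L
      newd <- sample(setdiff(0:3, digit), 1L)
      umi_int[i] <- umi_int[i] + (newd - digit) * 4^(p - 1L)
    }
  }
  umi_int
}

# per-tile planted strength: full containment of the planted core by the
# tile's 50-AA window
tile_strengths <- function(tiles, truth, tile_aa = 50L) {
  s <- numeric(nrow(tiles))
  if (!nrow(truth)) return(s)
  aa_start <- tiles$nt_start %/% 3L
  for (j in seq_len(nrow(truth))) {
    sel <- tiles$gene_id == truth$gene_id[j] &
      aa_start <= truth$aa_start[j] &
      aa_start + tile_aa >= truth$aa_end[j]
    s[sel] <- pmax(s[sel], truth$strength[j])
  }
  s
}

#' Simulate the sorted screen over a tile library
#'
#' Each cell carries one library tile (abundances drawn once per screen from
#' a symmetric Dirichlet). A cell sorts GFP-negative with probability
#' `b + (1 - b) * s` where `s` is the planted strength of its tile (0 when
#' the tile does not fully contain a planted core). Every sorted molecule
#' receives a uniform random UMI, is PCR-amplified with geometric copy
#' counts, and each read's UMI is corrupted per-nucleotide at
#' `umi_error_rate`.
#'
#' @param lib a `tile_library` (see [design_library()]).
#' @param truth planted-interval data.frame from [simulate_catalog()].
#' @param cfg a [sim_config()].
#' @return list with `fragments` (uncollapsed fragment table: oligo_id, umi,
#'   fraction in neg/pos, replicate, reporter, read_count) and `truth_counts`
#'   (per-tile true sorted cell counts: oligo_id, replicate, reporter,
#'   cells_neg, cells_pos).
#' @export
simulate_screen <- function(lib, truth, cfg) {
  stopifnot(inherits(lib, "tile_library"), inherits(cfg, "sim_config"))
  tiles <- lib$tiles
  if (!nrow(tiles)) stop("empty tile library")
  set.seed(cfg$seed + 1L)
  K <- nrow(tiles)
  abund <- rgamma(K, shape = cfg$dirichlet_alpha, rate = 1)
  abund <- abund / sum(abund)
  reporters <- "zfh1"
  strengths <- list(zfh1 = tile_strengths(tiles, truth))
  if (!is.null(cfg$reporter2_multiplier)) {
    reporters <- c(reporters, "ent1")
    mult <- cfg$reporter2_multiplier
    if (!is.null(names(mult))) {
      m <- mult[tiles$gene_id]
      m[is.na(m)] <- 1
    } else m <- rep(mult, K)
    strengths$ent1 <- pmin(1, strengths$zfh1 * m)
  }
  b <- cfg$sort_error
  frag_parts <- list()
  count_parts <- list()
  for (rep_id in seq_len(cfg$n_replicates)) {
    for (rp in reporters) {
      n_tile <- as.vector(stats::rmultinom(1, cfg$cells_per_replicate, abund))
      p_neg <- b + (1 - b) * strengths[[rp]]
      n_neg <- rbinom(K, n_tile, p_neg)
      n_pos <- n_tile - n_neg
      count_parts[[length(count_parts) + 1L]] <- data.frame(
        oligo_id = tiles$oligo_id, replicate = rep_id, reporter = rp,
        cells_neg = n_neg, cells_pos = n_pos, stringsAsFactors = FALSE)
      for (fr in c("neg", "pos")) {
        n_mol <- if (fr == "neg") n_neg else n_pos
        total <- sum(n_mol)
        if (total == 0L) next
        oligo <- rep(tiles$oligo_id, n_mol)
        umi_int <- sample.int(4L^cfg$umi_len, total, replace = TRUE) - 1L
        copies <- rgeom(total, prob = 1 / cfg$pcr_mean) + 1L
        read_oligo <- rep(oligo, copies)
        read_umi <- mutate_umis(rep(umi_int, copies), cfg$umi_len,
                                cfg$umi_error_rate)
        dt <- data.table::data.table(oligo_id = read_oligo, umi_i = read_umi)
        dt <- dt[, .(read_count = .N), by = .(oligo_id, umi_i)]
        frag_parts[[length(frag_parts) + 1L]] <- data.frame(
          oligo_id = dt$oligo_id,
          umi = umi_int_to_string(dt$umi_i, cfg$umi_len),
          fraction = fr, replicate = rep_id, reporter = rp,
          read_count = dt$read_count, stringsAsFactors = FALSE)
      }
    }
  }
  fragments <- if (length(frag_parts))
    as.data.frame(data.table::rbindlist(frag_parts))
  else
    data.frame(oligo_id = character(), umi = character(),
               fraction = character(), replicate = integer(),
               reporter = character(), read_count = integer(),
               stringsAsFactors = FALSE)
  list(fragments = fragments,
       truth_counts = as.data.frame(data.table::rbindlist(count_parts)))
}

#' One-call synthetic screen
#'
#' Convenience wrapper chaining [simulate_catalog()], [design_library()] and
#' [simulate_screen()].
#'
#' @param cfg a [sim_config()].
#' @return list with `catalog`, `truth`, `lib`, `fragments`, `truth_counts`.
#' @export
simulate_rdseq <- function(cfg) {
  cat_truth <- simulate_catalog(cfg)
  lib <- design_library(cat_truth$catalog)
  scr <- simulate_screen(lib, cat_truth$truth, cfg)
  c(cat_truth, list(lib = lib), scr)
}
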