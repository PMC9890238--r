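# End-to-end orchestration: UMI collapse -> per-stratum coverage and region
# calling -> replicate intersection -> cross-reporter merge -> enrichment
# recalculation, preference and representative tiles.

nt_to_aa_interval <- function(nt_start, nt_end) {
  list(aa_start = nt_start %/% 3L, aa_end = (nt_end + 2L) %/% 3L)
}

#' Run the repressive-domain calling pipeline on a fragment table
#'
#' Collapses UMIs, builds coverage per (reporter, replicate) stratum, calls
#' extended regions per stratum, keeps regions supported by all replicates
#' of a reporter (>= `min_overlap` of the shorter region, longer region
#' retained), merges across reporters (longest region retained), then
#' recalculates each surviving region's enrichment in every screen, labels
#' reporter preference and picks the most repressive 50-AA representative
#' tile.
#'
#' @param fragments uncollapsed fragment table (oligo_id, umi, fraction,
#'   replicate, reporter, read_count).
#' @param lib the `tile_library`.
#' @param min_cov,min_fc,max_p,min_len_nt core-calling thresholds (see
#'   [call_core_regions()]).
#' @param ext_p,stop_len_nt extension parameters (see [extend_regions()]).
#' @param min_overlap replicate/reporter overlap fraction (default 0.5).
#' @param preference_fold reporter preference threshold (default 1.3).
#' @param umi_mismatch UMI collapse Hamming threshold (default 2).
#' @param collapsed set TRUE when `fragments` is already UMI-collapsed.
#' @return list: `regions` (final RD table with AA coordinates, per-reporter
#'   enrichment, preference, representative tile), `per_stratum` (regions
#'   per replicate x reporter), `tracks` (coverage per stratum),
#'   `collapsed` (collapsed fragment table).
#' @export
rd_pipeline <- function(fragments, lib, min_cov = 10, min_fc = 1.5,
                        max_p = 1e-5, min_len_nt = 60L, ext_p = 1e-3,
                        stop_len_nt = 60L, min_overlap = 0.5,
                        preference_fold = 1.3, umi_mismatch = 2L,
                        collapsed = FALSE) {
  coll <- if (collapsed) fragments
          else collapse_umis(fragments, max_mismatch = umi_mismatch)
  reporters <- sort(unique(coll$reporter))
  tracks <- list()
  per_stratum <- list()
  rep_regions <- list()
  for (rp in reporters) {
    reps <- sort(unique(coll$replicate[coll$reporter == rp]))
    regs <- list()
    for (r in reps) {
      key <- paste(rp, r, sep = ".")
      sub <- coll[coll$reporter == rp & coll$replicate == r, , drop = FALSE]
      tracks[[key]] <- to_gene_coords(sub, lib)
      regs[[as.character(r)]] <- call_rd_regions(
        tracks[[key]], min_cov, min_fc, max_p, min_len_nt, ext_p,
        stop_len_nt)
      per_stratum[[key]] <- regs[[as.character(r)]]
    }
    supported <- regs[[1]][, c("gene_id", "nt_start", "nt_end")]
    if (length(regs) > 1L)
      for (k in 2:length(regs))
        supported <- intersect_replicates(
          supported, regs[[k]][, c("gene_id", "nt_start", "nt_end")],
          min_overlap)
    rep_regions[[rp]] <- supported
  }
  merged <- if (length(reporters) == 2L)
    merge_reporters(rep_regions[[reporters[1]]],
                    rep_regions[[reporters[2]]],
                    reporters = reporters, min_overlap = min_overlap)
  else merge_reporters(rep_regions[[reporters[1]]], NULL,
                       reporters = c(reporters, NA))
  if (!nrow(merged)) {
    return(list(regions = cbind(merged,
                                data.frame(aa_start = integer(),
                                           aa_end = integer())),
                per_stratum = per_stratum, tracks = tracks,
                collapsed = coll))
  }
  # enrichment of every surviving region recalculated in every screen
  fc_by_rep <- list()
  for (rp in reporters) {
    keys <- grep(paste0("^", rp, "\\."), names(tracks), value = TRUE)
    fcs <- vapply(keys, function(k) region_fc(merged, tracks[[k]]),
                  numeric(nrow(merged)))
    fcs <- matrix(fcs, nrow = nrow(merged))
    fc_by_rep[[rp]] <- rowMeans(fcs)
    merged[[paste0("fc_", rp)]] <- fc_by_rep[[rp]]
  }
  if (length(reporters) == 2L) {
    merged$preference <- reporter_preference(
      fc_by_rep[[reporters[1]]], fc_by_rep[[reporters[2]]],
      threshold = preference_fold, labels = reporters)
  } else {
    merged$preference <- NA_character_
  }
  aa <- nt_to_aa_interval(merged$nt_start, merged$nt_end)
  merged$aa_start <- aa$aa_start
  merged$aa_end <- aa$aa_end
  # representative tile: collapsed counts pooled over the supporting screens
  merged$representative_tile <- NA_character_
  merged$representative_fc <- NA_real_
  merged$representative_aa_seq <- NA_character_
  for (i in seq_len(nrow(merged))) {
    support <- strsplit(merged$reporter_support[i], ",")[[1]]
    sub <- coll[coll$reporter %in% support, , drop = FALSE]
    counts <- tile_counts(sub, lib)
    t_neg <- sum(sub$fraction == "neg")
    t_pos <- sum(sub$fraction == "pos")
    rt <- representative_tile(merged[i, ], counts, lib, t_neg, t_pos)
    merged$representative_tile[i] <- rt$oligo_id
    merged$representative_fc[i] <- rt$fc
    merged$representative_aa_seq[i] <- rt$aa_seq
  }
  list(regions = merged, per_stratum = per_stratum, tracks = tracks,
       collapsed = coll)
}

#' Precision and recall of called regions against planted truth
#'
#' A called region and a planted interval match when their AA-interval
#' overlap is at least `min_overlap` of the shorter of the two.
#'
#' @param regions called regions with gene_id, aa_start, aa_end.
#' @param truth planted intervals with gene_id, aa_start, aa_end.
#' @param min_overlap overlap fraction of the shorter interval
#'   (default 0.5).
#' @return list(precision, recall, n_called, n_truth, true_positive).
#' @export
evaluate_recovery <- function(regions, truth, min_overlap = 0.5) {
  n_called <- nrow(regions)
  n_truth <- nrow(truth)
  if (!n_called || !n_truth)
    return(list(precision = if (n_called) 0 else NA_real_,
                recall = if (n_truth) 0 else NA_real_,
                n_called = n_called, n_truth = n_truth,
                true_positive = 0L))
  called_hit <- logical(n_called)
  truth_hit <- logical(n_truth)
  for (i in seq_len(n_called)) {
    sel <- which(truth$gene_id == regions$gene_id[i])
    for (j in sel) {
      ov <- min(regions$aa_end[i], truth$aa_end[j]) -
        max(regions$aa_start[i], truth$aa_start[j])
      shorter <- min(regions$aa_end[i] - regions$aa_start[i],
                     truth$aa_end[j] - truth$aa_start[j])
      if (ov > 0 && ov >= min_overlap * shorter) {
        called_hit[i] <- TRUE
        truth_hit[j] <- TRUE
      }
    }
  }
  list(precision = mean(called_hit), recall = mean(truth_hit),
       n_called = n_called, n_truth = n_truth,
       true_positive = sum(called_hit))
}

PIPELINE_DEFAULTS <- list(
  tile_len = 150L, step_high = 6L, step_low = 15L,
  umi_mismatch = 2L, min_cov = 10, min_fc = 1.5, max_p = 1e-5,
  ext_p = 1e-3, min_len_nt = 60L, stop_len_nt = 60L, overlap = 0.5,
  preference = 1.3, fimo_stringent = 1e-4, fimo_lenient = 1e-3,
  classify_meme_p = 1e-5, lenient_p = 1e-3, lenient_fc = 1.2,
  cluster_cut = 0.7, flank_logo = 10L, metaplot = 100L, seed = 1L
)

#' Pipeline configuration with standard thresholds
#'
#' Returns the default thresholds used throughout the pipeline (tile length
#' 150 nt; tiling steps 6/15 nt; UMI mismatch 2; coverage >= 10; FC >= 1.5;
#' P <= 1e-5 over >= 60 nt; extension P 1e-3; 50% overlaps; 1.3-fold
#' preference; PWM scan cutoffs 1e-4/1e-3; lenient calling P 1e-3 / FC 1.2;
#' motif-tree cut 0.7; logo flank 10; metaplot half-window 100), overridden
#' by any named arguments. Unknown names are an error.
#'
#' @param ... named overrides of the defaults.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  over <- list(...)
  unknown <- setdiff(names(over), names(PIPELINE_DEFAULTS))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(PIPELINE_DEFAULTS, over)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys must be a subset of the defaults of [pipeline_config()]; unknown
#' keys are a hard error.
#'
#' @param path YAML file of key: value pairs.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

output_header <- function(cfg) {
  c(sprintf("# rdscreen %s",
            as.character(utils::packageVersion("rdscreen"))),
    sprintf("# config_hash=%s seed=%d", config_hash(cfg),
            as.integer(cfg$seed)))
}

write_tsv_with_header <- function(df, path, cfg) {
  writeLines(output_header(cfg), path)
  suppressWarnings(
    write.table(df, path, append = TRUE, sep = "\t", quote = FALSE,
                row.names = FALSE))
  invisible(path)
}

#' Run a simulation-driven end-to-end screen analysis
#'
#' Simulates a catalog and screen under `sim`, designs the library, runs
#' [rd_pipeline()] under the thresholds in `cfg`, and writes the artifact
#' directory: library, collapsed fragments, final regions, per-stratum
#' regions and the recovery summary, every file headed by package version,
#' config hash and seed.
#'
#' @param cfg a [pipeline_config()].
#' @param sim a [sim_config()] (defaults to `sim_config(seed = cfg$seed)`).
#' @param out_dir output directory (created if needed).
#' @return invisibly, the [rd_pipeline()] result plus `recovery` and
#'   `truth`.
#' @export
run_pipeline <- function(cfg = pipeline_config(),
                         sim = sim_config(seed = cfg$seed),
                         out_dir) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim_out <- simulate_rdseq(sim)
  res <- rd_pipeline(sim_out$fragments, sim_out$lib,
                     min_cov = cfg$min_cov, min_fc = cfg$min_fc,
                     max_p = cfg$max_p, min_len_nt = cfg$min_len_nt,
                     ext_p = cfg$ext_p, stop_len_nt = cfg$stop_len_nt,
                     min_overlap = cfg$overlap,
                     preference_fold = cfg$preference,
                     umi_mismatch = cfg$umi_mismatch)
  rec <- evaluate_recovery(res$regions, sim_out$truth)
  write_tsv_with_header(sim_out$lib$tiles, file.path(out_dir, "library.tsv"),
                        cfg)
  write_tsv_with_header(res$collapsed,
                        file.path(out_dir, "collapsed_fragments.tsv"), cfg)
  write_regions_tsv(res$regions, file.path(out_dir, "rd_regions.tsv"), cfg)
  write_tsv_with_header(sim_out$truth, file.path(out_dir, "truth.tsv"), cfg)
  write_tsv_with_header(
    data.frame(metric = c("precision", "recall", "n_called", "n_truth"),
               value = c(rec$precision, rec$recall, rec$n_called,
                         rec$n_truth)),
    file.path(out_dir, "recovery.tsv"), cfg)
  invisible(c(res, list(recovery = rec, truth = sim_out$truth)))
}
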