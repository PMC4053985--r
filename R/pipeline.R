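#' Pipeline configuration with the standard thresholds
#'
#' Collects every threshold of the analysis chain with its standard
#' default: detection p 0.01, missingness 0.10, ageCG q 0.05, non-ageCG
#' q 0.5, shore width 2,000 bp, FPKM 0.05 / 0.25, phred 30, depth 20,
#' CTCF distance 5,000 bp, 10,000 permutation replicates. Overrides are
#' recorded in the run manifest.
#'
#' @param ... named overrides of the defaults.
#' @return a named list of class `pipeline_config` with an `overrides`
#'   attribute.
#' @export
pipeline_config <- function(...) {
  cfg <- list(det_p = 0.01, max_missing = 0.10, age_q = 0.05,
              nonage_q = 0.5, shore_bp = 2000, fpkm_low = 0.05,
              fpkm_high = 0.25, min_phred = 30, min_depth = 20,
              ctcf_far_bp = 5000, perm_reps = 10000, perm_seed = 1,
              combat_mode = "parametric", regional_df = "t",
              min_n = 4)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) stopf("unknown config field(s): %s",
                             paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  attr(cfg, "overrides") <- ov
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the array arm: intensities to per-tissue ageCG tables
#'
#' Per tissue: background subtraction, detection p-values, beta scores,
#' detection/missingness/annotation filtering, empirical-Bayes batch
#' normalization, per-CpG age regression with gender covariate, FDR and
#' ageCG classification. Tissues are processed separately throughout
#' (batch is confounded with tissue across experiments).
#'
#' @param panel an [intensity_panel()] covering all samples.
#' @param sample_sheet data frame: sample_id, tissue, age, gender, batch.
#' @param probes probe annotation (probe_id, chrom, cpg_pos, gene,
#'   snp_flag, multimap_flag).
#' @param config a [pipeline_config()].
#' @return list per tissue: `beta` (normalized matrix), `results`
#'   (age-model table with tissue column), `qc`; plus `combined` (all
#'   tissues' results bound together) and `manifest`.
#' @export
run_array_pipeline <- function(panel, sample_sheet, probes,
                               config = pipeline_config()) {
  stopifnot(inherits(panel, "intensity_panel"))
  detp <- detection_pvalue(panel)
  panel_bg <- subtract_background(panel)
  beta_all <- beta_from_panel(panel_bg)
  tissues <- unique(sample_sheet$tissue)
  out <- list()
  for (tt in tissues) {
    ids <- sample_sheet$sample_id[sample_sheet$tissue == tt]
    beta <- beta_all[, colnames(beta_all) %in% ids, drop = FALSE]
    filt <- filter_matrix(beta, detp, probes, det_p = config$det_p,
                          max_missing = config$max_missing)
    batch <- panel$batch[match(colnames(filt), colnames(panel$A))]
    norm <- combat_normalize(filt, batch, mode = config$combat_mode)
    sheet_t <- sample_sheet[sample_sheet$sample_id %in% colnames(norm), ]
    res <- fit_age_models(norm, sheet_t, min_n = config$min_n)
    res <- classify_cpgs(res, age_q = config$age_q,
                         nonage_q = config$nonage_q)
    res$tissue <- tt
    out[[tt]] <- list(beta = norm, results = res,
                      qc = attr(filt, "qc"))
  }
  combined <- do.call(rbind, lapply(out, `[[`, "results"))
  rownames(combined) <- NULL
  manifest <- list(
    tissues = tissues,
    n_probes_in = nrow(beta_all),
    n_samples_in = ncol(beta_all),
    n_tested = vapply(out, function(o) nrow(o$results), numeric(1)),
    n_agecg = vapply(out, function(o)
      sum(o$results$class == "ageCG", na.rm = TRUE), numeric(1)),
    thresholds = unclass(config),
    overrides = attr(config, "overrides"))
  c(out, list(combined = combined, manifest = manifest))
}

#' Run the sequencing arm: reads to regional age-effect tests
#'
#' Converts and maps reads (exact match, forward strand only), removes
#' duplicates, calls per-CpG methylation with phred and depth filters,
#' then fits the regional AR(1) mixed model per target and applies the
#' per-target FDR.
#'
#' @param reads read table (read_id, sample_id, mate, seq, qual).
#' @param targets target table (target_id, chrom, start, end, seq).
#' @param sample_ages named numeric vector, sample id -> age.
#' @param config a [pipeline_config()].
#' @param merge_targets optional target-merge list, see
#'   [fit_regional_models()].
#' @return list: `calls`, `fits`, `fdr`, `mapping` (unmapped/ambiguous
#'   counts), `manifest`.
#' @export
run_bisseq_pipeline <- function(reads, targets, sample_ages,
                                config = pipeline_config(),
                                merge_targets = NULL) {
  mp <- map_reads(reads, targets)
  dd <- dedupe(mp$mapped)
  calls <- call_methylation(dd, targets, min_q = config$min_phred,
                            min_depth = config$min_depth)
  fits <- fit_regional_models(calls, sample_ages,
                              merge_targets = merge_targets,
                              df_method = config$regional_df)
  fdr <- target_fdr(fits, q_threshold = config$age_q)
  manifest <- list(n_reads = nrow(reads), n_mapped = nrow(mp$mapped),
                   n_after_dedupe = nrow(dd),
                   n_unmapped = mp$n_unmapped,
                   n_ambiguous = mp$n_ambiguous,
                   n_cpg_calls = nrow(calls),
                   n_targets_fit = nrow(fits),
                   n_widespread = sum(fdr$widespread_effect),
                   thresholds = unclass(config))
  list(calls = calls, fits = fits, fdr = fdr,
       mapping = mp[c("n_unmapped", "n_ambiguous")], manifest = manifest)
}
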