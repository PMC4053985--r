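#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator: cohort layout,
#' per-context true age-effect distributions, beadchip batch effects, the
#' intensity model, and the bisulfite-sequencing read model. The defaults
#' describe the study conditions the package is designed around: four
#' tissues of 40 samples each with ages 20-90 years, 2,000 array probes of
#' which 5% carry a true age effect, and 19-sample targeted bisulfite
#' sequencing with an age slope of 0.5 percentage points per year.
#'
#' The true-effect model follows the island dichotomy seen in tissue
#' methylation aging: probes inside CpG islands receive small positive
#' slopes shared across tissues; probes outside islands receive larger
#' negative slopes, each specific to one tissue.
#'
#' @param seed integer; all generator randomness derives from it. Identical
#'   configs produce byte-identical outputs.
#' @param n_tissues,n_samples_per_tissue cohort layout.
#' @param age_range numeric length-2, years; ages are uniform on it.
#' @param n_probes,n_negctrl array size and negative controls per channel.
#' @param n_batches beadchips per tissue (samples assigned round-robin).
#' @param frac_island,frac_shore proportions of probes placed in islands and
#'   shores; the remainder is placed away from islands. Must sum to <= 1.
#' @param frac_true proportion of probes with a true nonzero slope.
#' @param frac_true_island of the true probes, the proportion given a
#'   shared positive island effect; the rest get tissue-specific negative
#'   effects outside islands.
#' @param effect_model list with elements `pos_slope` and `neg_slope`
#'   (length-2 ranges of slope magnitude, per-beta per year), and
#'   `intercept_island`, `intercept_shore`, `intercept_other` (ranges of
#'   baseline beta).
#' @param slope_jitter_sd_per_kb spatial drift of true slopes within a gene
#'   cluster (random-walk step sd per sqrt-kb), so neighboring CpGs have
#'   more similar slopes than distant ones.
#' @param gender_effect additive beta offset applied to a random 5% of
#'   probes for one gender, exercising the covariate.
#' @param batch_offsets list with per-batch vectors `beta_add` (additive
#'   shift on the beta scale), `add_A`, `add_B` (additive intensity shifts
#'   per channel) and `mult` (multiplicative intensity scale).
#' @param noise_sd beta-scale biological/technical noise sd.
#' @param intensity list: `total_mean`, `total_cv` (per-probe total
#'   intensity scale, lognormal), `bg_mean`, `bg_sd` (background
#'   fluorescence), `bg_cv` (lognormal per-sample variation of the
#'   background level, shared by probes and negative controls, so
#'   control-based subtraction can remove it), `dropout` (per-cell
#'   probability of signal failure).
#' @param frac_snp,frac_multimap proportions of probes flagged for SNPs or
#'   multi-mapping in the simulated annotation.
#' @param chrom_len,n_islands,n_genes,n_ctcf,n_lads,n_states annotation
#'   sizing on the single synthetic chromosome "chrS".
#' @param bisseq list: `n_targets`, `target_len`, `read_len`, `depth_mean`
#'   (mean per-CpG read depth), `base_error_rate`, `conversion_failure_rate`,
#'   `frac_lowq` (fraction of bases with phred < 30), `phi_true` (per-bp
#'   AR(1) correlation of within-sample methylation deviations),
#'   `beta_age_true` (percentage points per year), `m_mid` (methylation at
#'   the age midpoint, percent), `sigma_dev` (sd of the spatially correlated
#'   deviations, percent), `n_young`, `n_old` (validation cohort sizes).
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_tissues = 4L,
                       n_samples_per_tissue = 40L,
                       age_range = c(20, 90),
                       n_probes = 2000L,
                       n_negctrl = 100L,
                       n_batches = 2L,
                       frac_island = 0.40,
                       frac_shore = 0.30,
                       frac_true = 0.05,
                       frac_true_island = 0.5,
                       effect_model = list(
                         pos_slope = c(0.001, 0.002),
                         neg_slope = c(0.002, 0.004),
                         intercept_island = c(0.05, 0.25),
                         intercept_shore = c(0.20, 0.55),
                         intercept_other = c(0.50, 0.85)),
                       slope_jitter_sd_per_kb = 5e-4,
                       gender_effect = 0.02,
                       batch_offsets = NULL,
                       noise_sd = 0.03,
                       intensity = list(total_mean = 4000, total_cv = 0.3,
                                        bg_mean = 200, bg_sd = 30,
                                        bg_cv = 0.2, dropout = 0.01),
                       frac_snp = 0.01,
                       frac_multimap = 0.01,
                       chrom_len = 1e7,
                       n_islands = 80L,
                       n_genes = 150L,
                       n_ctcf = 100L,
                       n_lads = 10L,
                       n_states = 10L,
                       bisseq = list()) {
  if (length(age_range) != 2 || age_range[1] >= age_range[2])
    stopf("age_range must be (min, max) with min < max")
  if (frac_island + frac_shore > 1)
    stopf("frac_island + frac_shore must be <= 1")
  if (frac_true < 0 || frac_true > 1) stopf("frac_true must be in [0,1]")
  if (is.null(batch_offsets)) {
    b <- seq_len(n_batches) - 1
    batch_offsets <- list(beta_add = 0.05 * b,
                          add_A = rep(0, n_batches),
                          add_B = rep(0, n_batches),
                          mult = rep(1, n_batches))
  }
  for (nm in c("beta_add", "add_A", "add_B", "mult"))
    if (length(batch_offsets[[nm]]) != n_batches)
      stopf("batch_offsets$%s must have length n_batches", nm)
  bs_default <- list(n_targets = 5L, target_len = 600L, read_len = 72L,
                     depth_mean = 50, base_error_rate = 0.001,
                     conversion_failure_rate = 0.005, frac_lowq = 0.05,
                     phi_true = 0.993, beta_age_true = 0.5, m_mid = 50,
                     m_amp = 20, sigma_dev = 5, n_young = 9L, n_old = 10L)
  bs_default[names(bisseq)] <- bisseq
  if (bs_default$depth_mean <= 0) stopf("bisseq depth_mean must be > 0")
  cfg <- list(seed = as.integer(seed), n_tissues = as.integer(n_tissues),
              n_samples_per_tissue = as.integer(n_samples_per_tissue),
              age_range = age_range, n_probes = as.integer(n_probes),
              n_negctrl = as.integer(n_negctrl),
              n_batches = as.integer(n_batches),
              frac_island = frac_island, frac_shore = frac_shore,
              frac_true = frac_true, frac_true_island = frac_true_island,
              effect_model = effect_model,
              slope_jitter_sd_per_kb = slope_jitter_sd_per_kb,
              gender_effect = gender_effect, batch_offsets = batch_offsets,
              noise_sd = noise_sd, intensity = intensity,
              frac_snp = frac_snp, frac_multimap = frac_multimap,
              chrom_len = chrom_len, n_islands = as.integer(n_islands),
              n_genes = as.integer(n_genes), n_ctcf = as.integer(n_ctcf),
              n_lads = as.integer(n_lads), n_states = as.integer(n_states),
              bisseq = bs_default)
  class(cfg) <- "sim_config"
  cfg
}
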