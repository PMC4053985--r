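#' Empirical-Bayes batch normalization of a beta matrix
#'
#' Removes beadchip batch effects from a filtered beta matrix using the
#' ComBat location/scale model (additive and multiplicative per-batch
#' effects shrunk toward empirical-Bayes priors; parametric
#' normal/inverse-gamma priors or the nonparametric Monte-Carlo variant).
#' Intended to be run on one tissue at a time: batch is confounded with
#' tissue across experiments, so joint normalization would suppress
#' genuine between-tissue methylation differences.
#'
#' Missing values are imputed with the per-probe mean for the adjustment
#' only and set back to missing afterwards; the output is clipped to
#' `[0, 1]`. Probes that are entirely missing or have zero variance are
#' passed through unchanged.
#'
#' @param beta probes x samples beta matrix (one tissue).
#' @param batch per-sample batch labels; every batch needs >= 2 samples.
#' @param mode `"parametric"` (default; deterministic) or
#'   `"nonparametric"` (the original study's choice; slower).
#' @return normalized beta matrix, stage `"normalized"`.
#' @export
combat_normalize <- function(beta, batch,
                             mode = c("parametric", "nonparametric")) {
  mode <- match.arg(mode)
  if (length(batch) != ncol(beta)) stopf("one batch label per sample required")
  batch <- as.character(batch)
  tab <- table(batch)
  if (length(tab) == 1) {
    warnf("single batch: normalization is an identity map")
    out <- clip01(beta)
    attr(out, "stage") <- "normalized"
    return(out)
  }
  if (any(tab < 2))
    stopf("batch(es) with a single sample: %s",
          paste(names(tab)[tab < 2], collapse = ", "))
  imputed <- beta
  pm <- rowMeans(beta, na.rm = TRUE)
  na_idx <- which(is.na(beta))
  if (length(na_idx)) imputed[na_idx] <- pm[row(beta)[na_idx]]
  ## probes ComBat cannot standardize: all-missing or zero pooled variance
  v <- apply(imputed, 1, var)
  usable <- is.finite(v) & v > 0
  out <- imputed
  if (sum(usable) > 0) {
    adj <- suppressMessages(
      sva::ComBat(dat = imputed[usable, , drop = FALSE], batch = batch,
                  par.prior = (mode == "parametric")))
    out[usable, ] <- adj
  }
  if (length(na_idx)) out[na_idx] <- NA_real_
  out <- clip01(out)
  attr(out, "stage") <- "normalized"
  out
}
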