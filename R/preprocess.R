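#' Construct a two-channel intensity panel
#'
#' Holds raw probe intensities for the unmethylated (A) and methylated (B)
#' bead types of each CpG, per-sample negative-control intensities for both
#' color channels, and beadchip batch labels.
#'
#' @param A,B numeric probes x samples matrices with dimnames (probe ids,
#'   sample ids); A is the unmethylated-channel, B the methylated-channel
#'   intensity.
#' @param channel per-probe detection color, `"green"` or `"red"`.
#' @param negctrl list with `green` and `red` matrices (negative controls x
#'   samples); at least one control per sample per channel.
#' @param batch per-sample beadchip labels.
#' @param bg_subtracted logical stage flag.
#' @return object of class `intensity_panel`.
#' @export
intensity_panel <- function(A, B, channel, negctrl, batch,
                            bg_subtracted = FALSE) {
  if (!all(dim(A) == dim(B))) stopf("A and B must have identical dimensions")
  if (length(channel) != nrow(A)) stopf("one channel label per probe required")
  if (!all(channel %in% c("green", "red"))) stopf("channel must be green|red")
  if (length(batch) != ncol(A)) stopf("one batch label per sample required")
  for (ch in c("green", "red")) {
    m <- negctrl[[ch]]
    if (is.null(m) || ncol(m) != ncol(A) || nrow(m) < 1)
      stopf("negctrl$%s must have >= 1 control row and one column per sample", ch)
  }
  structure(list(A = A, B = B, channel = channel, negctrl = negctrl,
                 batch = batch, bg_subtracted = bg_subtracted),
            class = "intensity_panel")
}

#' @export
print.intensity_panel <- function(x, ...) {
  cat(sprintf("intensity_panel: %d probes x %d samples (%s), %d+%d negctrl/sample\n",
              nrow(x$A), ncol(x$A),
              if (x$bg_subtracted) "background-subtracted" else "raw",
              nrow(x$negctrl$green), nrow(x$negctrl$red)))
  invisible(x)
}

#' Subtract negative-control background fluorescence
#'
#' For each sample and color channel, the median of that sample's
#' negative-control intensities in that channel is subtracted from every
#' probe intensity (both A and B bead types) detected in that channel.
#' Resulting intensities may be negative; they are resolved later by the
#' beta-score clipping rules.
#'
#' @param panel an [intensity_panel()].
#' @return the panel with background-subtracted A and B.
#' @export
subtract_background <- function(panel) {
  stopifnot(inherits(panel, "intensity_panel"))
  for (ch in c("green", "red")) {
    m <- panel$negctrl[[ch]]
    bad <- colSums(!is.na(m)) == 0
    if (any(bad))
      stopf("no %s negative controls for sample(s): %s", ch,
            paste(colnames(panel$A)[bad], collapse = ", "))
  }
  med <- sapply(c(green = "green", red = "red"), function(ch)
    apply(panel$negctrl[[ch]], 2, median, na.rm = TRUE))
  for (ch in c("green", "red")) {
    pr <- panel$channel == ch
    panel$A[pr, ] <- sweep(panel$A[pr, , drop = FALSE], 2, med[, ch], "-")
    panel$B[pr, ] <- sweep(panel$B[pr, , drop = FALSE], 2, med[, ch], "-")
  }
  panel$bg_subtracted <- TRUE
  panel
}

#' Detection p-values against the negative-control background
#'
#' Per probe and sample, the total signal A + B is ranked against the
#' sample's pooled negative-control intensities from both channels:
#' `p = (1 + #{controls >= signal}) / (1 + n_controls)` (add-one smoothed
#' empirical upper-tail probability). A probe is detected when p falls
#' below the chosen threshold (0.01 in the standard pipeline). Intended to
#' be computed on the raw (unsubtracted) panel.
#'
#' @param panel an [intensity_panel()].
#' @return probes x samples matrix of p-values.
#' @export
detection_pvalue <- function(panel) {
  stopifnot(inherits(panel, "intensity_panel"))
  total <- panel$A + panel$B
  out <- matrix(NA_real_, nrow(total), ncol(total), dimnames = dimnames(total))
  for (s in seq_len(ncol(total))) {
    ctl <- c(panel$negctrl$green[, s], panel$negctrl$red[, s])
    ctl <- ctl[!is.na(ctl)]
    if (length(ctl) == 0) stopf("no negative controls for sample %s",
                                colnames(total)[s])
    ctl <- sort(ctl)
    n_ge <- length(ctl) - findInterval(total[, s], ctl, left.open = TRUE)
    out[, s] <- (1 + n_ge) / (1 + length(ctl))
  }
  out
}

#' Beta-score from background-subtracted intensities
#'
#' `beta = B / (A + B)` with no vendor +100 correction term. Negative B
#' (methylated probe below background) maps to 0; beta above 1 (A below
#' background) maps to 1; non-positive total signal maps to missing.
#'
#' @param A,B numeric vectors/matrices of background-subtracted intensities.
#' @return beta values in `[0, 1]` or `NA`.
#' @export
compute_beta <- function(A, B) {
  out <- B / (A + B)
  out[which(B < 0)] <- 0
  out[which(A < 0 & B >= 0)] <- 1
  out[which((A + B) <= 0)] <- NA_real_
  out
}

#' Beta matrix from an intensity panel
#'
#' @param panel a background-subtracted [intensity_panel()].
#' @return probes x samples beta matrix with `stage` attribute `"raw"`.
#' @export
beta_from_panel <- function(panel) {
  stopifnot(inherits(panel, "intensity_panel"))
  if (!panel$bg_subtracted)
    warnf("computing beta scores from a panel without background subtraction")
  b <- compute_beta(panel$A, panel$B)
  attr(b, "stage") <- "raw"
  b
}

#' Filter a beta matrix by detection, missingness and probe annotation
#'
#' Applied in a fixed order: (1) entries with detection p >= `det_p` are
#' set missing; (2) samples with more than `max_missing` missing values are
#' removed; (3) probes with more than `max_missing` missing values are
#' removed; (4) probes flagged as containing a SNP (MAF >= 3% within 15 bp
#' of the CpG) or as multi-mapping are removed. Counts depend on this
#' order, so it is not configurable.
#'
#' @param beta probes x samples beta matrix.
#' @param detp matching detection p-value matrix (may cover a superset of
#'   rows/columns; matched by dimnames), or `NULL` to skip step 1.
#' @param annot probe annotation with `probe_id`, `snp_flag`,
#'   `multimap_flag`, or `NULL` to skip step 4.
#' @param det_p,max_missing thresholds (defaults 0.01 and 0.10).
#' @return filtered beta matrix, stage `"filtered"`, with a `qc` attribute
#'   listing dropped samples/probes and reasons.
#' @export
filter_matrix <- function(beta, detp = NULL, annot = NULL, det_p = 0.01,
                          max_missing = 0.10) {
  qc <- list()
  if (!is.null(detp)) {
    detp <- detp[rownames(beta), colnames(beta), drop = FALSE]
    beta[which(detp >= det_p)] <- NA_real_
  }
  miss_s <- colMeans(is.na(beta))
  drop_s <- miss_s > max_missing
  qc$dropped_samples <- colnames(beta)[drop_s]
  if (all(drop_s)) stopf("all samples exceed %.0f%% missingness",
                         100 * max_missing)
  beta <- beta[, !drop_s, drop = FALSE]
  miss_p <- rowMeans(is.na(beta))
  drop_p <- miss_p > max_missing
  qc$dropped_probes_missing <- rownames(beta)[drop_p]
  beta <- beta[!drop_p, , drop = FALSE]
  if (!is.null(annot)) {
    flagged <- annot$probe_id[annot$snp_flag | annot$multimap_flag]
    drop_f <- rownames(beta) %in% flagged
    qc$dropped_probes_flagged <- rownames(beta)[drop_f]
    beta <- beta[!drop_f, , drop = FALSE]
  }
  attr(beta, "stage") <- "filtered"
  attr(beta, "qc") <- qc
  beta
}
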