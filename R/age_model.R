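## OLS core shared by fit_age_model and fit_age_models: y ~ 1 + age + gender
## on complete cases. Returns slope/intercept/se/p/r2/n or NAs if untestable.
ols_age_core <- function(y, age, gender01, min_n = 4) {
  ok <- !is.na(y) & !is.na(age) & !is.na(gender01)
  n <- sum(ok)
  na_row <- list(slope = NA_real_, intercept = NA_real_, se_slope = NA_real_,
                 p = NA_real_, r2 = NA_real_, n_used = n, testable = FALSE)
  if (n < min_n) return(na_row)
  y <- y[ok]; age <- age[ok]; g <- gender01[ok]
  if (var(age) == 0) return(na_row)
  X <- cbind(`(Intercept)` = 1, age = age)
  if (var(g) > 0) X <- cbind(X, gender = g)
  k <- ncol(X)
  fit <- lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  df <- n - k
  sigma2 <- rss / df
  XtXinv <- chol2inv(qr.R(fit$qr))
  se <- sqrt(sigma2 * diag(XtXinv))
  tstat <- fit$coefficients["age"] / se[2]
  p <- if (df > 0) 2 * pt(-abs(tstat), df) else NA_real_
  list(slope = unname(fit$coefficients["age"]),
       intercept = unname(fit$coefficients["(Intercept)"]),
       se_slope = unname(se[2]), p = unname(p),
       r2 = if (tss > 0) 1 - rss / tss else NA_real_,
       n_used = n, testable = TRUE)
}

#' Per-CpG linear regression of methylation on age
#'
#' Ordinary least squares of a single probe's beta-scores on age with a
#' binary gender covariate; the age effect is tested with a two-sided
#' t-test. Probes with fewer than `min_n` complete observations or no age
#' variance are flagged untestable (missing p).
#'
#' @param beta_row numeric vector of beta-scores for one probe.
#' @param ages numeric ages in years.
#' @param genders gender labels (2 levels, factor/character/0-1).
#' @param min_n minimum complete observations (default 4, keeping the
#'   t-test defined).
#' @return one-row data frame: slope (delta-beta/year), intercept
#'   (predicted beta at age 0 for the reference gender), se_slope, p, r2,
#'   n_used, sign.
#' @export
fit_age_model <- function(beta_row, ages, genders, min_n = 4) {
  g01 <- code_gender(genders)
  r <- ols_age_core(as.numeric(beta_row), as.numeric(ages), g01, min_n)
  data.frame(slope = r$slope, intercept = r$intercept, se_slope = r$se_slope,
             p = r$p, r2 = r$r2, n_used = r$n_used,
             sign = slope_sign(r$slope), stringsAsFactors = FALSE)
}

code_gender <- function(genders) {
  if (is.numeric(genders)) return(as.numeric(genders))
  f <- factor(genders)
  if (nlevels(f) > 2) stopf("gender must have at most 2 levels")
  as.numeric(f) - 1
}

slope_sign <- function(s) {
  ifelse(is.na(s) | s == 0, NA_character_,
         ifelse(s > 0, "positive", "negative"))
}

#' Fit age models for every probe of a beta matrix
#'
#' Runs [fit_age_model()] per probe (case-wise deletion of missing
#' beta-scores), applies Benjamini-Hochberg FDR across the tested probes,
#' and classifies each CpG (see [classify_cpgs()]).
#'
#' @param beta probes x samples beta matrix.
#' @param sample_sheet data frame with `sample_id`, `age`, `gender`
#'   matching the matrix columns.
#' @param min_n minimum complete observations per probe.
#' @return data frame (one row per probe): probe_id, slope, intercept,
#'   se_slope, p, q, r2, n_used, sign, class.
#' @export
fit_age_models <- function(beta, sample_sheet, min_n = 4) {
  idx <- match(colnames(beta), sample_sheet$sample_id)
  if (anyNA(idx)) stopf("samples missing from sample sheet: %s",
                        paste(colnames(beta)[is.na(idx)], collapse = ", "))
  ages <- as.numeric(sample_sheet$age[idx])
  g01 <- code_gender(sample_sheet$gender[idx])
  rows <- lapply(seq_len(nrow(beta)), function(i)
    ols_age_core(beta[i, ], ages, g01, min_n))
  res <- data.frame(probe_id = rownames(beta),
                    slope = vapply(rows, `[[`, 0, "slope"),
                    intercept = vapply(rows, `[[`, 0, "intercept"),
                    se_slope = vapply(rows, `[[`, 0, "se_slope"),
                    p = vapply(rows, `[[`, 0, "p"),
                    r2 = vapply(rows, `[[`, 0, "r2"),
                    n_used = vapply(rows, function(r) as.numeric(r$n_used), 0),
                    stringsAsFactors = FALSE)
  res$q <- bh_fdr(res$p)
  res$sign <- slope_sign(res$slope)
  classify_cpgs(res)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Standard step-up q-values, capped at 1. Missing p-values are excluded
#' from the adjustment (they do not count toward the number of tests) and
#' re-inserted as missing.
#'
#' @param pvals numeric p-values in `[0, 1]`, `NA` allowed.
#' @return q-values of the same length.
#' @export
bh_fdr <- function(pvals) {
  q <- rep(NA_real_, length(pvals))
  ok <- !is.na(pvals)
  q[ok] <- p.adjust(pvals[ok], method = "BH")
  q
}

#' Classify CpGs into ageCG / non-ageCG / intermediate
#'
#' ageCG: q < 0.05 (significant age association); non-ageCG: q > 0.5 (no
#' detectable age effect); intermediate otherwise (excluded from
#' ageCG-versus-non-ageCG contrasts).
#'
#' @param results data frame with a `q` column.
#' @param age_q,nonage_q thresholds (defaults 0.05 and 0.5, strict).
#' @return `results` with a `class` column added.
#' @export
classify_cpgs <- function(results, age_q = 0.05, nonage_q = 0.5) {
  q <- results$q
  results$class <- ifelse(is.na(q), NA_character_,
                          ifelse(q < age_q, "ageCG",
                                 ifelse(q > nonage_q, "nonageCG",
                                        "intermediate")))
  results
}

#' Slope concordance of neighboring ageCGs within genes
#'
#' For every gene carrying two or more ageCGs, all ageCG pairs contribute:
#' the sign-agreement fraction per gene and overall, and the absolute
#' slope difference stratified by pairwise genomic distance
#' (`[0,100)`, `[100,500)`, `[500,Inf)` bp).
#'
#' @param results age-model table with `probe_id`, `slope`, `class`.
#' @param annot probe annotation with `probe_id`, `cpg_pos` and a `gene`
#'   column (multiple symbols separated by `";"`; a probe contributes to
#'   each).
#' @return list: `per_gene` (gene, n_agecg, n_pairs, agreement),
#'   `pairs` (gene, distance, abs_dslope, bin), `agreement` (pooled
#'   fraction over all pairs), `by_bin` (mean |delta slope| per distance
#'   bin). Empty data frames if no gene has >= 2 ageCGs.
#' @export
neighbor_concordance <- function(results, annot) {
  age <- results[!is.na(results$class) & results$class == "ageCG", ,
                 drop = FALSE]
  age <- merge(age, annot[, c("probe_id", "cpg_pos", "gene")], by = "probe_id")
  age <- age[!is.na(age$gene) & age$gene != "", , drop = FALSE]
  expanded <- do.call(rbind, lapply(seq_len(nrow(age)), function(i) {
    gs <- strsplit(age$gene[i], ";", fixed = TRUE)[[1]]
    if (length(gs) == 0) return(NULL)
    data.frame(gene = gs, probe_id = age$probe_id[i], slope = age$slope[i],
               cpg_pos = age$cpg_pos[i], stringsAsFactors = FALSE)
  }))
  empty <- list(per_gene = data.frame(gene = character(0), n_agecg = integer(0),
                                      n_pairs = integer(0),
                                      agreement = numeric(0)),
                pairs = data.frame(gene = character(0), distance = numeric(0),
                                   abs_dslope = numeric(0), bin = character(0)),
                agreement = NA_real_, by_bin = NULL)
  if (is.null(expanded) || nrow(expanded) == 0) return(empty)
  per_gene <- list(); pair_rows <- list()
  for (g in unique(expanded$gene)) {
    sub <- expanded[expanded$gene == g, , drop = FALSE]
    if (nrow(sub) < 2) next
    cmb <- combn(nrow(sub), 2)
    agree <- sign(sub$slope[cmb[1, ]]) == sign(sub$slope[cmb[2, ]])
    dist <- abs(sub$cpg_pos[cmb[1, ]] - sub$cpg_pos[cmb[2, ]])
    dsl <- abs(sub$slope[cmb[1, ]] - sub$slope[cmb[2, ]])
    per_gene[[g]] <- data.frame(gene = g, n_agecg = nrow(sub),
                                n_pairs = ncol(cmb),
                                agreement = mean(agree),
                                stringsAsFactors = FALSE)
    pair_rows[[g]] <- data.frame(gene = g, distance = dist, abs_dslope = dsl,
                                 agree = agree, stringsAsFactors = FALSE)
  }
  if (length(per_gene) == 0) return(empty)
  pg <- do.call(rbind, per_gene); rownames(pg) <- NULL
  pr <- do.call(rbind, pair_rows); rownames(pr) <- NULL
  pr$bin <- cut(pr$distance, c(0, 100, 500, Inf), right = FALSE,
                labels = c("[0,100)", "[100,500)", "[500,Inf)"))
  by_bin <- aggregate(abs_dslope ~ bin, data = pr, FUN = mean)
  list(per_gene = pg, pairs = pr[, c("gene", "distance", "abs_dslope", "bin")],
       agreement = mean(pr$agree), by_bin = by_bin)
}
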