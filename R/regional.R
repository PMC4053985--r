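## Shared fitting engine for the regional models. Formula terms:
## pct ~ age [+ pos_kb] [+ age:pos_kb], random intercept per sample
## (optional), continuous AR(1) residual correlation over position.
fit_regional_engine <- function(data, target_id, interaction, random_intercept,
                                method, df_method, ar1 = TRUE) {
  d <- data[!is.na(data$pct) & !is.na(data$age) & !is.na(data$pos), ,
            drop = FALSE]
  d$sample <- as.character(d$sample)
  n_samples <- length(unique(d$sample))
  n_cpgs <- length(unique(d$pos))
  if (n_samples < 2) stopf("need >= 2 samples with data")
  if (n_cpgs < 2 && interaction)
    stopf("age x position interaction inestimable with a single CpG")
  if (var(d$age[!duplicated(d$sample)]) == 0)
    stopf("all ages equal: age effect inestimable")
  ## position centered and in kb for conditioning; correlation distances
  ## stay in bp so phi is the per-bp correlation
  d$pos_kb <- (d$pos - mean(d$pos)) / 1000
  base <- list(target_id = target_id, n_samples = n_samples,
               n_cpgs = n_cpgs, n_obs = nrow(d),
               beta_age = NA_real_, se_age = NA_real_, stat_age = NA_real_,
               p_age = NA_real_, beta_pos = NA_real_, p_pos = NA_real_,
               beta_agepos = NA_real_, p_agepos = NA_real_,
               phi = NA_real_, sigma2_subject = NA_real_,
               sigma2_resid = NA_real_, loglik = NA_real_,
               converged = FALSE)
  single_cpg <- n_cpgs < 2
  form <- if (single_cpg) pct ~ age
          else if (interaction) pct ~ age + pos_kb + age:pos_kb
          else pct ~ age + pos_kb
  use_ar1 <- ar1 && !single_cpg
  fit <- tryCatch({
    if (!use_ar1 && !random_intercept) {
      ## phi pinned to 0 and no subject variance: independent errors, OLS
      stats::lm(form, data = d)
    } else if (random_intercept) {
      corr <- if (use_ar1) nlme::corCAR1(form = ~pos | sample) else NULL
      nlme::lme(form, random = ~1 | sample, correlation = corr,
                data = d, method = method,
                control = nlme::lmeControl(maxIter = 200, msMaxIter = 200,
                                           opt = "optim"))
    } else {
      nlme::gls(form, correlation = nlme::corCAR1(form = ~pos | sample),
                data = d, method = method,
                control = nlme::glsControl(maxIter = 200, msMaxIter = 200))
    }
  }, error = function(e) e)
  if (inherits(fit, "error")) {
    base$error <- conditionMessage(fit)
    return(base)
  }
  if (inherits(fit, "lm")) {
    sm <- summary(fit)$coefficients
    grab <- function(nm, col) if (nm %in% rownames(sm)) sm[nm, col] else NA_real_
    base$beta_age <- grab("age", 1); base$se_age <- grab("age", 2)
    base$stat_age <- grab("age", 3); base$p_age <- grab("age", 4)
    if ("pos_kb" %in% rownames(sm)) {
      base$beta_pos <- sm["pos_kb", 1] / 1000
      base$p_pos <- sm["pos_kb", 4]
    }
    if ("age:pos_kb" %in% rownames(sm)) {
      base$beta_agepos <- sm["age:pos_kb", 1] / 1000
      base$p_agepos <- sm["age:pos_kb", 4]
    }
    base$sigma2_resid <- summary(fit)$sigma^2
    base$sigma2_subject <- 0; base$phi <- 0
    base$loglik <- as.numeric(logLik(fit))
    base$converged <- TRUE
    return(base)
  }
  tt <- summary(fit)$tTable
  get_row <- function(nm) {
    i <- match(nm, rownames(tt))
    if (is.na(i)) c(NA_real_, NA_real_) else c(tt[i, 1], tt[i, 2])
  }
  wald <- function(est, se) {
    z <- est / se
    p <- if (df_method == "t")
      2 * pt(-abs(z), df = max(1, n_samples - 2))
    else 2 * pnorm(-abs(z))
    list(z = z, p = p)
  }
  ra <- get_row("age")
  wa <- wald(ra[1], ra[2])
  base$beta_age <- ra[1]; base$se_age <- ra[2]
  base$stat_age <- wa$z; base$p_age <- wa$p
  rp <- get_row("pos_kb")
  if (!is.na(rp[1])) {
    base$beta_pos <- rp[1] / 1000  # report per bp
    base$p_pos <- wald(rp[1], rp[2])$p
  }
  ri <- get_row("age:pos_kb")
  if (!is.na(ri[1])) {
    base$beta_agepos <- ri[1] / 1000
    base$p_agepos <- wald(ri[1], ri[2])$p
  }
  cs <- fit$modelStruct$corStruct
  if (!is.null(cs)) base$phi <- as.numeric(coef(cs, unconstrained = FALSE))
  base$sigma2_resid <- fit$sigma^2
  base$sigma2_subject <- if (inherits(fit, "lme"))
    as.numeric(nlme::VarCorr(fit)["(Intercept)", "Variance"]) else 0
  base$loglik <- as.numeric(logLik(fit))
  base$converged <- TRUE
  base
}

regional_row <- function(x) {
  data.frame(target_id = x$target_id, beta_age = x$beta_age,
             se_age = x$se_age, stat_age = x$stat_age, p_age = x$p_age,
             beta_pos = x$beta_pos, p_pos = x$p_pos,
             beta_agepos = x$beta_agepos, p_agepos = x$p_agepos,
             phi = x$phi, sigma2_subject = x$sigma2_subject,
             sigma2_resid = x$sigma2_resid, loglik = x$loglik,
             converged = x$converged, n_samples = x$n_samples,
             n_cpgs = x$n_cpgs, n_obs = x$n_obs, stringsAsFactors = FALSE)
}

#' Regional linear mixed model with continuous AR(1) correlation
#'
#' Models percent methylation across all CpGs of one target as
#' `pct_ij = b0 + beta_age * age_i + beta_pos * pos_j + b_i + e_ij` with a
#' per-sample random intercept `b_i` and within-sample residual
#' correlation `phi^|pos_j - pos_j'|` (continuous-distance AR(1), corCAR1;
#' phi is the correlation at 1 bp separation). Estimated by REML; the
#' age effect is tested with a Wald statistic against a normal reference
#' against a t reference with `n_samples - 2` degrees of freedom by
#' default (age varies between samples, so between-sample information
#' drives the test; a normal reference is available but is
#' anti-conservative at validation-cohort sample sizes).
#' Missing-percentage rows (depth below threshold) are dropped; the
#' correlation structure uses the actual positions of the remaining CpGs.
#' Position enters the fixed effects centered and scaled to kb;
#' `beta_pos` is reported per bp.
#'
#' With a single CpG per target the position terms and the correlation
#' drop out and (with `random_intercept = FALSE`) the fit reduces to the
#' ordinary least-squares age regression.
#'
#' @param data data frame with columns `sample`, `age`, `pos` (1-based bp),
#'   `pct` (0-100).
#' @param target_id label carried into the output.
#' @param random_intercept keep the per-sample random intercept (default
#'   TRUE); `FALSE` pins the subject variance to zero and fits
#'   generalized least squares with the same correlation.
#' @param ar1 keep the continuous AR(1) residual correlation (default
#'   TRUE); `FALSE` pins phi to zero (independent residuals), which
#'   together with `random_intercept = FALSE` reduces the fit exactly to
#'   ordinary least squares.
#' @param method `"REML"` (default) or `"ML"`.
#' @param df_method `"t"` (default) or `"normal"` for the Wald reference.
#' @return one-row data frame: target_id, beta_age, se_age, stat_age,
#'   p_age, beta_pos, p_pos, beta_agepos, p_agepos, phi, sigma2_subject,
#'   sigma2_resid, loglik, converged, n_samples, n_cpgs, n_obs.
#'   Non-convergence yields `converged = FALSE` with missing estimates.
#' @export
fit_car1_mixed <- function(data, target_id = "target",
                           random_intercept = TRUE, method = "REML",
                           df_method = c("t", "normal"), ar1 = TRUE) {
  df_method <- match.arg(df_method)
  regional_row(fit_regional_engine(data, target_id, interaction = FALSE,
                                   random_intercept = random_intercept,
                                   method = method, df_method = df_method,
                                   ar1 = ar1))
}

#' Age-by-position interaction variant of the regional model
#'
#' Adds an `age x position` fixed effect (position centered before
#' multiplication) to [fit_car1_mixed()]; a significant interaction
#' indicates that the slope of the age effect changes along the target.
#' Inestimable with a single CpG.
#'
#' @inheritParams fit_car1_mixed
#' @return as [fit_car1_mixed()], with `beta_agepos` (pct/year/bp) and
#'   `p_agepos` filled in.
#' @export
fit_interaction_model <- function(data, target_id = "target",
                                  random_intercept = TRUE, method = "REML",
                                  df_method = c("t", "normal"), ar1 = TRUE) {
  df_method <- match.arg(df_method)
  regional_row(fit_regional_engine(data, target_id, interaction = TRUE,
                                   random_intercept = random_intercept,
                                   method = method, df_method = df_method,
                                   ar1 = ar1))
}

#' Fit regional models for every target of a methylation call table
#'
#' Joins per-CpG calls to sample ages and runs [fit_car1_mixed()] per
#' target. Targets can be merged into a single model (for overlapping
#' capture targets covering the same CpGs) via `merge_targets`; merging is
#' otherwise refused to protect grouping integrity.
#'
#' @param calls methylation calls from [call_methylation()].
#' @param sample_ages named numeric vector (sample id -> age).
#' @param merge_targets optional named list: new id -> character vector of
#'   target ids to combine.
#' @param ... passed to [fit_car1_mixed()].
#' @return data frame with one row per fitted model.
#' @export
fit_regional_models <- function(calls, sample_ages, merge_targets = NULL,
                                ...) {
  d <- calls[!is.na(calls$pct), , drop = FALSE]
  d$age <- sample_ages[d$sample_id]
  if (anyNA(d$age)) stopf("age missing for sample(s): %s",
                          paste(unique(d$sample_id[is.na(d$age)]),
                                collapse = ", "))
  d$model_id <- d$target_id
  for (nm in names(merge_targets)) {
    ids <- merge_targets[[nm]]
    sub <- d[d$target_id %in% ids, , drop = FALSE]
    by_t <- split(sub$sample_id, sub$target_id)
    if (length(by_t) > 1 &&
        length(Reduce(intersect, lapply(by_t, unique))) == 0)
      stopf("refusing to merge targets %s: no shared samples",
            paste(ids, collapse = ", "))
    d$model_id[d$target_id %in% ids] <- nm
  }
  out <- lapply(split(d, d$model_id), function(sub) {
    dat <- data.frame(sample = sub$sample_id, age = sub$age, pos = sub$pos,
                      pct = sub$pct, stringsAsFactors = FALSE)
    tryCatch(fit_car1_mixed(dat, target_id = sub$model_id[1], ...),
             error = function(e) {
               r <- regional_row(list(target_id = sub$model_id[1],
                                      beta_age = NA_real_, se_age = NA_real_,
                                      stat_age = NA_real_, p_age = NA_real_,
                                      beta_pos = NA_real_, p_pos = NA_real_,
                                      beta_agepos = NA_real_,
                                      p_agepos = NA_real_, phi = NA_real_,
                                      sigma2_subject = NA_real_,
                                      sigma2_resid = NA_real_,
                                      loglik = NA_real_, converged = FALSE,
                                      n_samples = length(unique(sub$sample_id)),
                                      n_cpgs = length(unique(sub$pos)),
                                      n_obs = nrow(sub)))
               r$error <- conditionMessage(e)
               r
             })
  })
  out <- data.table::rbindlist(out, fill = TRUE)
  as.data.frame(out)
}

#' Per-target FDR for widespread age effects
#'
#' Benjamini-Hochberg across converged targets; a target is flagged as
#' showing a widespread age effect when q < 0.05. Non-converged targets
#' are reported unflagged with missing q.
#'
#' @param fits output of [fit_regional_models()] (needs `target_id`,
#'   `p_age`, `converged`).
#' @param q_threshold flag threshold (default 0.05).
#' @return data frame: target_id, p, q, widespread_effect, converged.
#' @export
target_fdr <- function(fits, q_threshold = 0.05) {
  if (!any(fits$converged)) stopf("no converged targets")
  out <- data.frame(target_id = fits$target_id, p = fits$p_age,
                    q = NA_real_, widespread_effect = FALSE,
                    converged = fits$converged, stringsAsFactors = FALSE)
  ok <- out$converged & !is.na(out$p)
  out$q[ok] <- p.adjust(out$p[ok], method = "BH")
  out$widespread_effect <- !is.na(out$q) & out$q < q_threshold
  out
}
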