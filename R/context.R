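#' Classify CpG positions as island / shore / other
#'
#' A CpG (1-based cytosine coordinate) is an island CpG if it falls inside
#' an island interval (0-based half-open), a shore CpG if its distance to
#' the nearest island is between 1 and 2,000 bp inclusive ("within 2 kb"),
#' and "other" beyond that. Distance is measured between the 0-based CpG
#' position and the nearest retained island base
#' (`start - p0` or `p0 - (end - 1)`).
#'
#' @param cpg_pos numeric vector of 1-based CpG coordinates.
#' @param islands island intervals (see [genomic_intervals()]); must be
#'   disjoint within chromosome.
#' @param chrom chromosome of each CpG (recycled; default `"chrS"`).
#'   Positions on chromosomes absent from the island set get context
#'   `"other"` with infinite distance.
#' @param shore_bp shore width in bp (default 2000, boundary inclusive).
#' @return data frame (cpg_pos, chrom, context, distance_to_island).
#' @export
classify_context <- function(cpg_pos, islands, chrom = "chrS",
                             shore_bp = 2000) {
  p0 <- as.numeric(cpg_pos) - 1
  chrom <- rep_len(as.character(chrom), length(p0))
  dist <- rep(Inf, length(p0))
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    ivc <- islands[islands$chrom == ch, , drop = FALSE]
    if (nrow(ivc) == 0) next
    ivc <- ivc[order(ivc$start), , drop = FALSE]
    if (!intervals_disjoint(ivc)) stopf("islands overlap on %s", ch)
    idx <- findInterval(p0[sel], ivc$start)
    inside <- idx >= 1 & p0[sel] < ivc$end[pmax(idx, 1)]
    d_left <- ifelse(idx >= 1, p0[sel] - (ivc$end[pmax(idx, 1)] - 1), Inf)
    d_right <- ifelse(idx < nrow(ivc), ivc$start[pmin(idx + 1, nrow(ivc))] -
                        p0[sel], Inf)
    d <- pmin(d_left, d_right)
    d[inside] <- 0
    dist[sel] <- d
  }
  context <- ifelse(dist == 0, "island",
                    ifelse(dist >= 1 & dist <= shore_bp, "shore", "other"))
  data.frame(cpg_pos = cpg_pos, chrom = chrom, context = context,
             distance_to_island = dist, stringsAsFactors = FALSE)
}

#' Pearson chi-squared test on a contingency table
#'
#' A zero row or column margin is an error. Yates continuity correction is
#' applied only to 2x2 tables when `yates = "auto"` (the df = 2 context
#' tables are tested uncorrected; 2x2 expression tables corrected), or
#' forced with `TRUE`/`FALSE`.
#'
#' @param tab matrix of nonnegative counts.
#' @param yates `"auto"`, `TRUE` or `FALSE`.
#' @return list(statistic, df, p.value, corrected).
#' @export
pearson_chisq <- function(tab, yates = "auto") {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stopf("counts must be nonnegative")
  keep_r <- rowSums(tab) > 0
  keep_c <- colSums(tab) > 0
  if (!all(keep_r)) stopf("zero row margin at row(s): %s",
                          paste(which(!keep_r), collapse = ", "))
  if (!all(keep_c)) stopf("zero column margin at column(s): %s",
                          paste(which(!keep_c), collapse = ", "))
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stopf("need at least 2 rows and 2 columns")
  correct <- if (identical(yates, "auto"))
    nrow(tab) == 2 && ncol(tab) == 2 else isTRUE(yates)
  ct <- suppressWarnings(chisq.test(tab, correct = correct))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p.value = unname(ct$p.value), corrected = correct)
}

#' Context-by-sign summaries and cross-tissue tests for ageCGs
#'
#' Per tissue: the percentage of positive/negative ageCGs overall and the
#' context distribution within each sign. Per context: a sign x tissue
#' chi-squared test of whether the positive/negative split differs across
#' tissues (skipped with a notice when fewer than 2 tissues are present).
#'
#' @param results combined age-model table with columns `tissue`,
#'   `probe_id`, `slope`, `class`.
#' @param contexts context calls with `probe_id`, `context`.
#' @return list: `by_tissue` (tissue, n_agecg, pct_positive, pct_negative),
#'   `by_context` (tissue, context, sign, n, pct), `tests` (per-context
#'   chi-squared results or a notice).
#' @export
context_sign_summary <- function(results, contexts) {
  age <- results[!is.na(results$class) & results$class == "ageCG" &
                   !is.na(results$sign), , drop = FALSE]
  if (nrow(age) == 0) stopf("no ageCGs to summarize")
  age <- merge(age, contexts[, c("probe_id", "context")], by = "probe_id")
  by_tissue <- do.call(rbind, lapply(split(age, age$tissue), function(d)
    data.frame(tissue = d$tissue[1], n_agecg = nrow(d),
               pct_positive = 100 * mean(d$sign == "positive"),
               pct_negative = 100 * mean(d$sign == "negative"),
               stringsAsFactors = FALSE)))
  rownames(by_tissue) <- NULL
  cnt <- as.data.frame(table(tissue = age$tissue, context = age$context,
                             sign = age$sign), stringsAsFactors = FALSE)
  names(cnt)[names(cnt) == "Freq"] <- "n"
  tot <- tapply(cnt$n, list(cnt$tissue, cnt$sign), sum)
  cnt$pct <- 100 * cnt$n / tot[cbind(cnt$tissue, cnt$sign)]
  tests <- list()
  n_tissue <- length(unique(age$tissue))
  for (cc in unique(age$context)) {
    if (n_tissue < 2) {
      tests[[cc]] <- list(notice = "single tissue: cross-tissue test skipped")
      next
    }
    tab <- table(age$tissue[age$context == cc], age$sign[age$context == cc])
    tests[[cc]] <- tryCatch(pearson_chisq(tab),
                            error = function(e) list(notice = conditionMessage(e)))
  }
  list(by_tissue = by_tissue, by_context = cnt, tests = tests)
}

#' Box-Cox-transformed ANOVA of slope magnitudes
#'
#' Slope magnitudes `|slope|` are power-transformed with the Box-Cox
#' lambda maximizing the profile log-likelihood of an intercept-only model
#' over a grid, then analysed with a three-way fixed-effects ANOVA
#' (sequential type-I sums of squares) in the factor order
#' context, tissue, sign, with all interactions.
#'
#' @param slopes data frame with `slope`, `tissue`, `context`, `sign`.
#'   Zero-magnitude entries are dropped with a warning.
#' @param lambda_grid grid searched for lambda (default -2..2 step 0.01).
#' @return list: `lambda`, `table` (term, df, sumsq, F, p),
#'   `interaction_p` (the context:tissue:sign term).
#' @export
boxcox_anova <- function(slopes, lambda_grid = seq(-2, 2, by = 0.01)) {
  d <- slopes
  d$mag <- abs(d$slope)
  if (any(d$mag == 0)) {
    warnf("dropping %d zero-magnitude slope(s)", sum(d$mag == 0))
    d <- d[d$mag > 0, , drop = FALSE]
  }
  for (v in c("tissue", "context", "sign")) {
    d[[v]] <- factor(d[[v]])
    if (nlevels(d[[v]]) < 2) stopf("factor %s needs >= 2 levels", v)
  }
  fit0 <- lm(mag ~ 1, data = d, y = TRUE, qr = TRUE)
  bc <- MASS::boxcox(fit0, lambda = lambda_grid, plotit = FALSE)
  lambda <- bc$x[which.max(bc$y)]
  d$y <- if (abs(lambda) < 1e-12) log(d$mag) else (d$mag^lambda - 1) / lambda
  fit <- aov(y ~ context * tissue * sign, data = d)
  sm <- summary(fit)[[1]]
  tab <- data.frame(term = trimws(rownames(sm)), df = sm$Df,
                    sumsq = sm$`Sum Sq`, F = sm$`F value`,
                    p = sm$`Pr(>F)`, stringsAsFactors = FALSE)
  ip <- tab$p[tab$term == "context:tissue:sign"]
  list(lambda = lambda, table = tab,
       interaction_p = if (length(ip)) ip else NA_real_)
}
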