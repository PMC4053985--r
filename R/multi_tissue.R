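#' Overlap counts for every subset of tissue ageCG sets
#'
#' Exact intersection cardinality for every nonempty subset of the input
#' sets (ids drawn from a common universe).
#'
#' @param sets named list of id vectors.
#' @return data frame (subset, k, count), subset names joined with `"+"`.
#' @export
overlap_sets <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 1, !is.null(names(sets)))
  sets <- lapply(sets, unique)
  nm <- names(sets)
  out <- list()
  for (k in seq_along(sets)) {
    cmb <- combn(nm, k, simplify = FALSE)
    for (s in cmb) {
      out[[length(out) + 1]] <- data.frame(
        subset = paste(s, collapse = "+"), k = k,
        count = length(Reduce(intersect, sets[s])),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Permutation null for the all-tissue ageCG overlap
#'
#' Each replicate draws, for every tissue, a random set of the observed
#' size uniformly without replacement from the probe universe, and records
#' the size of the all-tissue intersection. The empirical p-value for an
#' observed overlap uses add-one smoothing,
#' `p = (1 + #{null >= observed}) / (1 + reps)`, so p < 1e-4 is
#' representable only with >= 10,000 replicates.
#'
#' @param sizes integer vector of per-tissue set sizes.
#' @param universe number of CpGs in the array universe.
#' @param reps permutation replicates (default 10000).
#' @param seed RNG seed.
#' @param observed optional observed all-tissue overlap.
#' @return list: `null` (length `reps`), `null_mean`, `null_max`,
#'   `expected` (analytic `N * prod(sizes/N)`), `p` (if `observed` given),
#'   `observed`, `reps`, `seed`.
#' @export
permutation_overlap <- function(sizes, universe, reps = 10000, seed = 1,
                                observed = NULL) {
  if (any(sizes > universe)) stopf("set size exceeds universe")
  if (reps < 1) stopf("reps must be >= 1")
  k <- length(sizes)
  null <- with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      cnt <- tabulate(unlist(lapply(sizes, function(n)
        sample.int(universe, n))), nbins = universe)
      sum(cnt == k)
    }, integer(1))
  })
  out <- list(null = null, null_mean = mean(null), null_max = max(null),
              expected = universe * prod(sizes / universe),
              reps = reps, seed = seed, observed = observed)
  if (!is.null(observed))
    out$p <- (1 + sum(null >= observed)) / (1 + reps)
  out
}

#' Gene-level unique and shared age-association classes
#'
#' For each gene and tissue the representative CpG is the mapped CpG with
#' the smallest age p-value (ties broken by probe id). A gene is
#' `unique-to-<tissue>` when its representative q is < 0.05 in that tissue
#' and > 0.5 (non-ageCG) in all other tissues; `shared-all` when q < 0.05
#' in every tissue; otherwise `neither`. Genes absent from any tissue's
#' tested set are reported unclassifiable.
#'
#' @param results_by_tissue named list of age-model tables (columns
#'   `probe_id`, `p`, `q`).
#' @param probe_gene map with `probe_id`, `gene` (`";"`-separated symbols
#'   allowed; a probe contributes to each gene).
#' @param age_q,nonage_q thresholds (defaults 0.05, 0.5).
#' @return data frame: gene, rep_probe_<tissue>, q_<tissue>, classifiable,
#'   class.
#' @export
gene_level_unique_shared <- function(results_by_tissue, probe_gene,
                                     age_q = 0.05, nonage_q = 0.5) {
  stopifnot(is.list(results_by_tissue), !is.null(names(results_by_tissue)))
  tissues <- names(results_by_tissue)
  map <- do.call(rbind, lapply(seq_len(nrow(probe_gene)), function(i) {
    if (is.na(probe_gene$gene[i])) return(NULL)
    gs <- strsplit(probe_gene$gene[i], ";", fixed = TRUE)[[1]]
    gs <- gs[gs != ""]
    if (length(gs) == 0) return(NULL)
    data.frame(probe_id = probe_gene$probe_id[i], gene = gs,
               stringsAsFactors = FALSE)
  }))
  if (is.null(map) || nrow(map) == 0) stopf("no probe-gene links")
  genes <- sort(unique(map$gene))
  qmat <- matrix(NA_real_, length(genes), length(tissues),
                 dimnames = list(genes, tissues))
  rep_probe <- matrix(NA_character_, length(genes), length(tissues),
                      dimnames = list(genes, tissues))
  for (tt in tissues) {
    res <- merge(map, results_by_tissue[[tt]][, c("probe_id", "p", "q")],
                 by = "probe_id")
    res <- res[!is.na(res$p), , drop = FALSE]
    res <- res[order(res$gene, res$p, res$probe_id), , drop = FALSE]
    first <- res[!duplicated(res$gene), , drop = FALSE]
    qmat[first$gene, tt] <- first$q
    rep_probe[first$gene, tt] <- first$probe_id
  }
  classifiable <- rowSums(is.na(qmat)) == 0
  cls <- rep("neither", length(genes))
  cls[!classifiable] <- NA_character_
  for (g in which(classifiable)) {
    qs <- qmat[g, ]
    if (all(qs < age_q)) {
      cls[g] <- "shared-all"
    } else {
      hit <- which(qs < age_q)
      if (length(hit) == 1 && all(qs[-hit] > nonage_q))
        cls[g] <- paste0("unique-", tissues[hit])
    }
  }
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (tt in tissues) {
    out[[paste0("rep_probe_", tt)]] <- rep_probe[, tt]
    out[[paste0("q_", tt)]] <- qmat[, tt]
  }
  out$classifiable <- classifiable
  out$class <- cls
  out
}

#' Expression call from FPKM
#'
#' expressed: FPKM > 0.25; non-expressed: FPKM < 0.05; indeterminate
#' between (excluded from enrichment tables).
#'
#' @param fpkm numeric vector.
#' @return character vector of calls.
#' @export
expression_call <- function(fpkm) {
  ifelse(is.na(fpkm), NA_character_,
         ifelse(fpkm > 0.25, "expressed",
                ifelse(fpkm < 0.05, "non-expressed", "indeterminate")))
}

#' Expression enrichment of a two-class gene or CpG partition
#'
#' Cross-tabulates a two-level item class (e.g. ageCG vs non-ageCG genes,
#' or unique vs shared) against expressed / non-expressed calls and tests
#' association with [pearson_chisq()] (Yates-corrected 2x2). Indeterminate
#' expression calls are excluded.
#'
#' @param item_class data frame with `gene` and `class` (2 levels used).
#' @param expr data frame with `gene` and either `call` or `fpkm`.
#' @param yates passed to [pearson_chisq()] (chisq method only).
#' @param method `"chisq"` (default) or `"fisher"` for small tables; both
#'   are offered because published small-table p-values are not always
#'   attributable to one of the two.
#' @return list(table, test); `test` carries a `notice` instead of a
#'   result when a margin is empty.
#' @export
expression_enrichment <- function(item_class, expr, yates = "auto",
                                  method = c("chisq", "fisher")) {
  method <- match.arg(method)
  if (!"call" %in% names(expr)) expr$call <- expression_call(expr$fpkm)
  d <- merge(item_class, expr[, c("gene", "call")], by = "gene")
  d <- d[!is.na(d$call) & d$call != "indeterminate", , drop = FALSE]
  tab <- table(class = d$class, expression = d$call)
  test <- tryCatch({
    if (method == "fisher") {
      ft <- stats::fisher.test(tab)
      list(p.value = ft$p.value, method = "fisher")
    } else pearson_chisq(tab, yates = yates)
  }, error = function(e) list(notice = conditionMessage(e)))
  list(table = tab, test = test)
}

#' Rank-sum comparison of expression between CpG/gene groups
#'
#' Two-sided Mann-Whitney U with normal approximation and tie correction,
#' restricted to nonzero expression values.
#'
#' @param x,y FPKM vectors for the two groups (e.g. genes of negative vs
#'   positive ageCGs). Zeros are excluded; an empty group after exclusion
#'   is an error.
#' @return list(U, p).
#' @export
ranksum_expression <- function(x, y) {
  x <- x[!is.na(x) & x != 0]
  y <- y[!is.na(y) & y != 0]
  if (length(x) == 0 || length(y) == 0)
    stopf("a group is empty after excluding zero expression")
  wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}
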