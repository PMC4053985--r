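tissue_names <- function(n) {
  base <- c("blood", "brain", "kidney", "muscle")
  if (n <= 4) base[seq_len(n)] else c(base, sprintf("tissue%d", 5:n))
}

## Rejection-sample positions (0-based) at distance > 2000 bp from every island.
sample_away_from_islands <- function(n, islands, chrom_len) {
  out <- numeric(0)
  guard <- 0
  while (length(out) < n) {
    cand <- floor(runif(2 * (n - length(out)) + 10, 0, chrom_len))
    if (nrow(islands) > 0) {
      ctx <- classify_context(cand + 1, islands)
      cand <- cand[ctx$context == "other"]
    }
    out <- c(out, cand)
    guard <- guard + 1
    if (guard > 200) stopf("cannot place probes away from islands")
  }
  out[seq_len(n)]
}

#' Simulate a two-channel methylation-array study with known truth
#'
#' Generates per-tissue cohorts, probe placement by CpG context, true age
#' effects (shared positive slopes in islands, tissue-specific negative
#' slopes outside), gender and beadchip batch effects, and raw two-channel
#' probe intensities whose beta estimate `B/(A+B)` is unbiased for the
#' target methylation after negative-control background subtraction.
#'
#' The intensity model draws a per-probe total scale `T`, then
#' `B = beta*T + background + noise` and `A = (1-beta)*T + background +
#' noise`, with negative-control probes drawn from the same background
#' distribution. Batch effects act additively on the beta scale
#' (`batch_offsets$beta_add`), additively on the A/B probe intensities
#' (`add_A`, `add_B`; not removed by background subtraction) and
#' multiplicatively on all intensities including controls (removed by the
#' beta ratio).
#'
#' @param config a [sim_config()].
#' @param annotation output of [simulate_annotation()].
#' @return list with `panel` (an [intensity_panel()]), `sample_sheet`
#'   (sample_id, tissue, age, gender, batch), `probes` (probe annotation:
#'   probe_id, chrom, cpg_pos, gene, snp_flag, multimap_flag), and `truth`
#'   (per-probe true slope/intercept/context, `shared` and
#'   `tissue_specific` flags, `target_tissue` for tissue-specific effects).
#' @export
simulate_array_study <- function(config, annotation) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(child_seed(config$seed, 2), {
    islands <- annotation$islands
    genes <- annotation$genes
    L <- annotation$chrom_len
    np <- config$n_probes
    tissues <- tissue_names(config$n_tissues)

    ## ---- sample sheet -------------------------------------------------
    ns <- config$n_samples_per_tissue
    sheet <- do.call(rbind, lapply(tissues, function(tt) {
      data.frame(sample_id = sprintf("%s_%02d", tt, seq_len(ns)),
                 tissue = tt,
                 age = round(runif(ns, config$age_range[1], config$age_range[2]), 1),
                 gender = sample(c("F", "M"), ns, replace = TRUE),
                 batch = sprintf("chip%d", rep_len(seq_len(config$n_batches), ns)),
                 stringsAsFactors = FALSE)
    }))
    rownames(sheet) <- NULL

    ## ---- true-effect clusters ----------------------------------------
    n_true <- round(config$frac_true * np)
    n_true_isl <- round(config$frac_true_island * n_true)
    n_true_neg <- n_true - n_true_isl
    em <- config$effect_model

    ## Genes anchored on islands (start coincides with an island start)
    ## host the shared positive clusters; island-free genes host the
    ## tissue-specific negative clusters.
    isl_genes <- genes[genes$start %in% islands$start, , drop = FALSE]
    far_genes <- genes[!points_in_intervals(genes$chrom, genes$start, islands) &
                         !(genes$start %in% islands$start), , drop = FALSE]

    make_clusters <- function(n_probes_total, host, place_fun, sign, mag_range) {
      if (n_probes_total == 0 || nrow(host) == 0)
        return(data.frame(pos0 = numeric(0), gene = character(0),
                          slope = numeric(0)))
      out <- list()
      left <- n_probes_total
      tries <- 0
      while (left > 0) {
        k <- min(left, sample(2:4, 1))
        g <- host[sample(nrow(host), 1), ]
        pos0 <- tryCatch(sort(place_fun(g, k)), error = function(e) NULL)
        if (is.null(pos0)) {  # host gene unusable (e.g. inside a shore)
          tries <- tries + 1
          if (tries > 50 * n_probes_total)
            stopf("cannot place effect clusters in the available genes")
          next
        }
        base <- runif(1, mag_range[1], mag_range[2])
        step <- config$slope_jitter_sd_per_kb *
          sqrt(pmax(diff(pos0), 1) / 1000)
        mag <- pmax(5e-4, base + c(0, cumsum(rnorm(k - 1, 0, step))))
        out[[length(out) + 1]] <-
          data.frame(pos0 = pos0, gene = g$name, slope = sign * mag)
        left <- left - k
      }
      do.call(rbind, out)
    }

    place_in_island_part <- function(g, k) {
      isl <- islands[islands$start == g$start, ][1, ]
      hi <- min(isl$end, g$end) - 1
      floor(runif(k, isl$start, hi + 1))
    }
    place_in_gene_far <- function(g, k) {
      cand <- numeric(0)
      guard <- 0
      while (length(cand) < k) {
        p <- floor(runif(4 * k, g$start, g$end))
        ctx <- classify_context(p + 1, islands)
        cand <- c(cand, p[ctx$context == "other"])
        guard <- guard + 1
        if (guard > 20) stopf("gene %s too close to islands", g$name)
      }
      cand[seq_len(k)]
    }

    pos_cl <- make_clusters(n_true_isl, isl_genes, place_in_island_part,
                            +1, em$pos_slope)
    neg_cl <- make_clusters(n_true_neg, far_genes, place_in_gene_far,
                            -1, em$neg_slope)
    neg_cl$target_tissue <- if (nrow(neg_cl) > 0)
      sample(tissues, nrow(neg_cl), replace = TRUE) else character(0)
    ## a cluster belongs to one tissue
    if (nrow(neg_cl) > 0)
      neg_cl$target_tissue <- ave(neg_cl$target_tissue, neg_cl$gene,
                                  FUN = function(x) rep(x[1], length(x)))
    pos_cl$target_tissue <- rep(NA_character_, nrow(pos_cl))

    true_df <- rbind(pos_cl, neg_cl)
    n_true <- nrow(true_df)

    ## ---- null probes by context fractions ----------------------------
    n_isl <- max(0, round(config$frac_island * np) - nrow(pos_cl))
    n_sho <- round(config$frac_shore * np)
    n_oth <- max(0, np - n_true - n_isl - n_sho)

    pos_isl <- if (n_isl > 0 && nrow(islands) > 0) {
      idx <- sample(nrow(islands), n_isl, replace = TRUE)
      floor(runif(n_isl, islands$start[idx], islands$end[idx]))
    } else numeric(0)
    pos_sho <- if (n_sho > 0 && nrow(islands) > 0) {
      idx <- sample(nrow(islands), n_sho, replace = TRUE)
      side <- sample(c(-1, 1), n_sho, replace = TRUE)
      off <- floor(runif(n_sho, 1, 2001))
      ifelse(side < 0, islands$start[idx] - off, islands$end[idx] - 1 + off)
    } else numeric(0)
    pos_oth <- sample_away_from_islands(n_sho - length(pos_sho) + n_oth +
                                          n_isl - length(pos_isl),
                                        islands, L)

    pos0 <- c(true_df$pos0, pos_isl, pos_sho, pos_oth)
    pos0 <- pmin(pmax(pos0, 0), L - 1)
    slope <- c(true_df$slope, rep(0, length(pos0) - n_true))
    target_tissue <- c(true_df$target_tissue,
                       rep(NA_character_, length(pos0) - n_true))
    cluster_gene <- c(true_df$gene, rep(NA_character_, length(pos0) - n_true))

    ord <- order(pos0)
    pos0 <- pos0[ord]; slope <- slope[ord]
    target_tissue <- target_tissue[ord]; cluster_gene <- cluster_gene[ord]
    np <- length(pos0)
    probe_id <- sprintf("cg%05d", seq_len(np))

    ## context from the island set itself
    ctx <- classify_context(pos0 + 1, islands)$context

    ## gene affiliation: containing gene, else cluster host gene
    gene_of <- rep(NA_character_, np)
    for (i in seq_len(nrow(genes))) {
      hit <- pos0 >= genes$start[i] & pos0 < genes$end[i] & is.na(gene_of)
      gene_of[hit] <- genes$name[i]
    }
    gene_of[!is.na(cluster_gene)] <- cluster_gene[!is.na(cluster_gene)]
    gene_of[is.na(gene_of)] <- ""

    snp_flag <- runif(np) < config$frac_snp
    multimap_flag <- runif(np) < config$frac_multimap

    probes <- data.frame(probe_id = probe_id, chrom = "chrS",
                         cpg_pos = pos0 + 1, gene = gene_of,
                         snp_flag = snp_flag, multimap_flag = multimap_flag,
                         stringsAsFactors = FALSE)

    ## ---- intercepts ---------------------------------------------------
    icept <- numeric(np)
    rng <- list(island = em$intercept_island, shore = em$intercept_shore,
                other = em$intercept_other)
    for (cc in names(rng)) {
      sel <- ctx == cc
      icept[sel] <- runif(sum(sel), rng[[cc]][1], rng[[cc]][2])
    }
    amax <- config$age_range[2]
    neg <- slope < 0; posv <- slope > 0
    icept[neg] <- pmax(icept[neg], abs(slope[neg]) * amax + 0.05)
    icept[posv] <- pmin(icept[posv], 0.95 - slope[posv] * amax)

    gender_probes <- runif(np) < 0.05

    truth <- data.frame(probe_id = probe_id, context = ctx,
                        gene = gene_of, cpg_pos = pos0 + 1,
                        true_slope = slope, true_intercept = icept,
                        shared = slope > 0, tissue_specific = slope < 0,
                        target_tissue = target_tissue,
                        gender_effect = gender_probes,
                        stringsAsFactors = FALSE)

    ## ---- target beta and intensities ----------------------------------
    nsamp <- nrow(sheet)
    batch_idx <- as.integer(sub("chip", "", sheet$batch))
    bo <- config$batch_offsets
    slope_mat <- outer(slope, rep(1, nsamp))
    ts <- !is.na(target_tissue)
    if (any(ts)) {
      off_tissue <- outer(target_tissue[ts], sheet$tissue, "!=")
      slope_mat[ts, ][off_tissue] <- 0
    }
    beta_target <- outer(icept, rep(1, nsamp)) +
      slope_mat * outer(rep(1, np), sheet$age) +
      config$gender_effect * outer(gender_probes, sheet$gender == "M") +
      outer(rep(1, np), bo$beta_add[batch_idx]) +
      matrix(rnorm(np * nsamp, 0, config$noise_sd), np, nsamp)
    beta_target <- clip01(beta_target)

    it <- config$intensity
    Tp <- rlnorm(np, log(it$total_mean), it$total_cv)
    keep <- matrix(runif(np * nsamp) >= it$dropout, np, nsamp)
    ## per-sample background level, shared with the negative controls
    bg_level <- it$bg_mean * exp(rnorm(nsamp, 0, it$bg_cv %||% 0))
    bg <- function() {
      m <- matrix(rnorm(np * nsamp, 0, it$bg_sd), np, nsamp)
      m <- sweep(m, 2, bg_level, "+")
      m[m < 0] <- 0
      m
    }
    B <- beta_target * Tp * keep + bg()
    A <- (1 - beta_target) * Tp * keep + bg()
    multv <- bo$mult[batch_idx]
    B <- sweep(B, 2, multv, "*")
    A <- sweep(A, 2, multv, "*")
    B <- sweep(B, 2, bo$add_B[batch_idx], "+")
    A <- sweep(A, 2, bo$add_A[batch_idx], "+")
    dimnames(A) <- dimnames(B) <- list(probe_id, sheet$sample_id)

    channel <- sample(c("green", "red"), np, replace = TRUE)
    negctrl <- lapply(c(green = "green", red = "red"), function(ch) {
      m <- matrix(rnorm(config$n_negctrl * nsamp, 0, it$bg_sd),
                  config$n_negctrl, nsamp)
      m <- sweep(m, 2, bg_level, "+")
      m[m < 0] <- 0
      m <- sweep(m, 2, multv, "*")
      colnames(m) <- sheet$sample_id
      m
    })

    panel <- intensity_panel(A = A, B = B, channel = channel,
                             negctrl = negctrl, batch = sheet$batch)
    list(panel = panel, sample_sheet = sheet, probes = probes, truth = truth)
  })
}

#' Simulate per-gene per-tissue FPKM expression values
#'
#' Baseline expression is log-normal; genes hosting tissue-specific
#' negative age effects are boosted in their target tissue (negative
#' ageCGs sit near genes with higher tissue-specific expression), and a
#' configurable fraction of genes is silent (FPKM < 0.05) in all tissues.
#'
#' @param annotation output of [simulate_annotation()].
#' @param truth truth table from [simulate_array_study()].
#' @param config a [sim_config()].
#' @param frac_silent fraction of genes set silent everywhere.
#' @param boost multiplicative expression boost in the target tissue of
#'   genes with tissue-specific negative effects.
#' @return long data frame (gene, tissue, fpkm).
#' @export
simulate_fpkm <- function(annotation, truth, config, frac_silent = 0.3,
                          boost = 8) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(child_seed(config$seed, 3), {
    genes <- annotation$genes$name
    if (length(genes) == 0) stopf("annotation contains no genes")
    tissues <- tissue_names(config$n_tissues)
    neg_map <- unique(truth[truth$tissue_specific & truth$gene != "",
                            c("gene", "target_tissue")])
    protected <- unique(neg_map$gene)
    silent_pool <- setdiff(genes, protected)
    n_silent <- min(round(frac_silent * length(genes)), length(silent_pool))
    silent <- sample(silent_pool, n_silent)
    out <- expand.grid(gene = genes, tissue = tissues,
                       stringsAsFactors = FALSE)
    out$fpkm <- rlnorm(nrow(out), log(5), 1.5)
    out$fpkm[out$gene %in% silent] <- runif(sum(out$gene %in% silent), 0, 0.04)
    hit <- match(paste(out$gene, out$tissue),
                 paste(neg_map$gene, neg_map$target_tissue))
    out$fpkm[!is.na(hit)] <- out$fpkm[!is.na(hit)] * boost
    out
  })
}
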