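#' Simulate target regions for capture bisulfite sequencing
#'
#' Random ACGT sequences placed disjointly on the synthetic chromosome;
#' CpGs arise at random-sequence density (roughly one per 16 bp).
#'
#' @param config a [sim_config()].
#' @return data frame (target_id, chrom, start, end, seq); 0-based
#'   half-open coordinates, `nchar(seq) == end - start`.
#' @export
simulate_bisseq_targets <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  bs <- config$bisseq
  with_seed(child_seed(config$seed, 4), {
    ends <- place_disjoint(bs$n_targets, bs$target_len, bs$target_len,
                           config$chrom_len)
    seqs <- vapply(seq_len(bs$n_targets), function(i)
      paste(sample(c("A", "C", "G", "T"), bs$target_len, replace = TRUE),
            collapse = ""), character(1))
    data.frame(target_id = sprintf("TGT%02d", seq_len(bs$n_targets)),
               chrom = "chrS", start = ends[, "start"],
               end = ends[, "start"] + bs$target_len, seq = seqs,
               stringsAsFactors = FALSE)
  })
}

## True methylation surface: smooth positional baseline + linear age term
## + spatially correlated per-sample deviations, clipped to [0, 100].
bisseq_m_surface <- function(bs, local_pos, ages, span = bs$target_len) {
  m0 <- bs$m_mid + bs$m_amp * sin(2 * pi * 1.5 * local_pos / span)
  det <- outer(rep(1, length(ages)), m0) +
    bs$beta_age_true * outer(ages - 60, rep(1, length(local_pos)))
  if (bs$sigma_dev > 0 && length(local_pos) > 1) {
    gaps <- diff(local_pos)
    dev <- t(vapply(seq_along(ages), function(i) {
      e <- numeric(length(local_pos))
      e[1] <- rnorm(1, 0, bs$sigma_dev)
      for (j in seq_along(gaps)) {
        r <- bs$phi_true^gaps[j]
        e[j + 1] <- r * e[j] + rnorm(1, 0, bs$sigma_dev * sqrt(1 - r^2))
      }
      e
    }, numeric(length(local_pos))))
    det <- det + dev
  } else if (bs$sigma_dev > 0) {
    det <- det + matrix(rnorm(length(ages), 0, bs$sigma_dev), ncol = 1)
  }
  det[which(det < 0)] <- 0
  det[which(det > 100)] <- 100
  det
}

#' Simulate targeted bisulfite-sequencing reads with known truth
#'
#' Reads are drawn from each target at uniform starts on the forward
#' strand. At reference CpG cytosines the C is retained (methylated) with
#' probability `m(pos, age)/100`, otherwise converted to T; non-CpG
#' cytosines convert to T except for conversion failures; sequencing
#' errors and a configurable fraction of sub-phred-30 base qualities are
#' then applied. The truth methylation surface combines a smooth
#' positional baseline, a linear age effect (`beta_age_true` percentage
#' points/year, centered at age 60), and per-sample deviations with AR(1)
#' spatial correlation `phi_true^distance` along the target.
#'
#' @param config a [sim_config()]; see the `bisseq` element.
#' @param targets optional target table from [simulate_bisseq_targets()];
#'   generated from `config` when `NULL`. Targets without a CpG are
#'   skipped with a warning.
#' @param sample_ages optional named numeric vector of ages; defaults to a
#'   validation cohort of `n_young` young (35-47 y) and `n_old` old
#'   (74-86 y) samples.
#' @return list with `reads` (read_id, sample_id, mate, seq, qual),
#'   `targets`, and `truth` (list: `ages`, and per-target local/genomic CpG
#'   positions with the realized per-sample methylation matrix `m`).
#' @export
simulate_bisseq <- function(config, targets = NULL, sample_ages = NULL) {
  stopifnot(inherits(config, "sim_config"))
  bs <- config$bisseq
  if (is.null(targets)) targets <- simulate_bisseq_targets(config)
  with_seed(child_seed(config$seed, 5), {
    if (is.null(sample_ages)) {
      sample_ages <- c(round(runif(bs$n_young, 35, 47), 1),
                       round(runif(bs$n_old, 74, 86), 1))
      names(sample_ages) <- c(sprintf("young_%02d", seq_len(bs$n_young)),
                              sprintf("old_%02d", seq_len(bs$n_old)))
    }
    ages <- sample_ages
    w <- bs$read_len
    truth <- list(ages = ages, targets = list())
    reads <- list()
    for (ti in seq_len(nrow(targets))) {
      tg <- targets[ti, ]
      conv <- convert_reference(tg$seq)
      cpg <- conv$cpg_index
      if (length(cpg) == 0) {
        warnf("target %s has no CpG; skipped", tg$target_id)
        next
      }
      m <- bisseq_m_surface(bs, cpg, ages, span = nchar(tg$seq))
      dimnames(m) <- list(names(ages), NULL)
      truth$targets[[tg$target_id]] <-
        list(local_pos = cpg, genomic_pos = tg$start + cpg, m = m)
      seqc <- strsplit(tg$seq, "")[[1]]
      is_c <- seqc == "C"
      is_cpg_c <- rep(FALSE, length(seqc)); is_cpg_c[cpg] <- TRUE
      w <- min(bs$read_len, nchar(tg$seq))  # reads cannot exceed the target
      n_reads <- max(1L, round(bs$depth_mean * nchar(tg$seq) / w))
      max_start <- nchar(tg$seq) - w + 1
      bases <- c("A", "C", "G", "T")
      for (si in seq_along(ages)) {
        starts <- sample.int(max_start, n_reads, replace = TRUE)
        rs <- character(n_reads); rq <- character(n_reads)
        for (ri in seq_len(n_reads)) {
          idx <- starts[ri]:(starts[ri] + w - 1)
          b <- seqc[idx]
          ccpg <- which(is_cpg_c[idx])
          if (length(ccpg)) {
            meth <- runif(length(ccpg)) < m[si, match(idx[ccpg], cpg)] / 100
            b[ccpg[!meth]] <- "T"
          }
          cnon <- which(is_c[idx] & !is_cpg_c[idx])
          if (length(cnon)) {
            convd <- runif(length(cnon)) >= bs$conversion_failure_rate
            b[cnon[convd]] <- "T"
          }
          if (bs$base_error_rate > 0) {
            err <- which(runif(w) < bs$base_error_rate)
            if (length(err))
              b[err] <- vapply(b[err], function(x)
                sample(setdiff(bases, x), 1), character(1))
          }
          q <- ifelse(runif(w) < bs$frac_lowq,
                      sample(20:29, w, replace = TRUE),
                      sample(33:40, w, replace = TRUE))
          rs[ri] <- paste(b, collapse = "")
          rq[ri] <- intToUtf8(q + 33L)
        }
        reads[[length(reads) + 1]] <- data.frame(
          read_id = sprintf("%s|%s|r%05d", names(ages)[si], tg$target_id,
                            seq_len(n_reads)),
          sample_id = names(ages)[si], mate = "fwd", seq = rs, qual = rq,
          stringsAsFactors = FALSE)
      }
    }
    list(reads = do.call(rbind, reads), targets = targets, truth = truth)
  })
}

#' Simulate per-CpG percent methylation for regional-model studies
#'
#' Direct generator for the regional mixed model's input (bypassing read
#' simulation): percent methylation at `n_cpgs` positions for `n_samples`
#' subjects with a linear age effect, a per-sample random intercept, and
#' AR(1)-correlated residuals whose correlation at 100 bp separation is
#' `phi100`. Ages default to a young (35-47 y) / old (74-86 y) validation
#' cohort split.
#'
#' @param n_samples,n_cpgs design size.
#' @param beta_age age effect, percentage points per year (centered at 60).
#' @param phi100 residual correlation at 100 bp separation.
#' @param sd_subject,sd_resid random-intercept and residual sd (percent).
#' @param span target length in bp over which CpG positions are drawn.
#' @param base methylation at age 60 (percent).
#' @param ages optional ages (length `n_samples`).
#' @return data frame with columns `sample`, `age`, `pos`, `pct`.
#' @export
simulate_regional_pct <- function(n_samples = 19, n_cpgs = 30,
                                  beta_age = 0.5, phi100 = 0.5,
                                  sd_subject = 3, sd_resid = 5,
                                  span = 600, base = 50, ages = NULL) {
  pos <- sort(sample.int(span, n_cpgs))
  if (is.null(ages))
    ages <- c(runif(ceiling(n_samples / 2), 35, 47),
              runif(floor(n_samples / 2), 74, 86))
  phi1 <- phi100^(1 / 100)
  rows <- lapply(seq_len(n_samples), function(i) {
    e <- numeric(n_cpgs)
    e[1] <- rnorm(1, 0, sd_resid)
    if (n_cpgs > 1) for (j in 2:n_cpgs) {
      r <- phi1^(pos[j] - pos[j - 1])
      e[j] <- r * e[j - 1] + rnorm(1, 0, sd_resid * sqrt(1 - r^2))
    }
    data.frame(sample = sprintf("s%02d", i), age = ages[i], pos = pos,
               pct = pmin(100, pmax(0, base + beta_age * (ages[i] - 60) +
                                      rnorm(1, 0, sd_subject) + e)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
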