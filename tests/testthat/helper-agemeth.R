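## Small study conditions used across unit tests (not the default
## acceptance-scale configuration).
tiny_config <- function(seed = 1, ...) {
  args <- list(seed = seed, n_tissues = 2, n_samples_per_tissue = 12,
               n_probes = 200, n_negctrl = 50, chrom_len = 2e6,
               n_islands = 20, n_genes = 40, n_ctcf = 20, n_lads = 4)
  args <- utils::modifyList(args, list(...))
  do.call(sim_config, args)
}

## Deterministic two-probe, two-sample panel for preprocessing tests.
## negctrl values are identical across samples unless overridden.
toy_panel <- function(A, B, negctrl_green = c(90, 100, 200),
                      negctrl_red = c(90, 100, 200),
                      channel = NULL, batch = NULL) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (is.null(rownames(A)))
    dimnames(A) <- dimnames(B) <-
      list(sprintf("cg%03d", seq_len(nrow(A))),
           sprintf("s%02d", seq_len(ncol(A))))
  ng <- matrix(rep(negctrl_green, ncol(A)), ncol = ncol(A))
  nr <- matrix(rep(negctrl_red, ncol(A)), ncol = ncol(A))
  colnames(ng) <- colnames(nr) <- colnames(A)
  intensity_panel(A = A, B = B,
                  channel = channel %||% rep("green", nrow(A)),
                  negctrl = list(green = ng, red = nr),
                  batch = batch %||% rep("chip1", ncol(A)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Independent normal-equations OLS oracle (never shares code with the
## package's lm.fit-based path).
ols_oracle <- function(y, X) {
  drop(solve(t(X) %*% X, t(X) %*% y))
}

## Direct generator for regional-model data: percent methylation at
## n_cpgs positions for n_samples subjects, with a linear age effect,
## subject random intercepts, and AR(1)-correlated residuals whose
## correlation at 100 bp separation is phi100.
sim_regional_data <- function(n_samples = 19, n_cpgs = 30, beta_age = 0.5,
                              phi100 = 0.5, sd_subject = 3, sd_resid = 5,
                              span = 600, base = 50, ages = NULL) {
  pos <- sort(sample.int(span, n_cpgs))
  ages <- ages %||% c(runif(ceiling(n_samples / 2), 35, 47),
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
               pct = base + beta_age * (ages[i] - 60) +
                 rnorm(1, 0, sd_subject) + e,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

## Mapped-read row constructor for pileup tests.
mapped_read <- function(sample_id, target_id, offset, seq, qual,
                        read_id = NULL, mate = "fwd") {
  data.frame(read_id = read_id %||% sprintf("r%04d", sample.int(9999, 1)),
             sample_id = sample_id, mate = mate, seq = seq, qual = qual,
             target_id = target_id, offset = offset,
             stringsAsFactors = FALSE)
}
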