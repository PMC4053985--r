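test_that("generators are deterministic under a fixed seed", {
  cfg <- tiny_config(seed = 42)
  a1 <- simulate_annotation(cfg)
  a2 <- simulate_annotation(cfg)
  expect_identical(a1, a2)
  s1 <- simulate_array_study(cfg, a1)
  s2 <- simulate_array_study(cfg, a1)
  expect_identical(s1, s2)
  f1 <- simulate_fpkm(a1, s1$truth, cfg)
  f2 <- simulate_fpkm(a1, s1$truth, cfg)
  expect_identical(f1, f2)
  bcfg <- tiny_config(seed = 42, bisseq = list(n_targets = 1,
                                               target_len = 200,
                                               depth_mean = 5))
  b1 <- simulate_bisseq(bcfg)
  b2 <- simulate_bisseq(bcfg)
  expect_identical(b1, b2)
})

test_that("annotation satisfies its structural postconditions", {
  cfg <- tiny_config(seed = 3)
  ann <- simulate_annotation(cfg)
  expect_true(intervals_ok <- all(ann$islands$start < ann$islands$end))
  expect_true(agemeth:::intervals_disjoint(ann$islands))
  expect_true(agemeth:::intervals_disjoint(ann$lads))
  expect_true(all(ann$genes$strand %in% c("+", "-")))
  seg <- ann$segmentation
  seg <- seg[order(seg$start), ]
  expect_equal(sum(seg$end - seg$start), ann$chrom_len)
  expect_true(all(seg$start[-1] == seg$end[-nrow(seg)]))  # exact tiling
  expect_error(simulate_annotation(tiny_config(chrom_len = 1e4)),
               "too short")
})

test_that("no islands means every probe is context 'other'", {
  cfg <- tiny_config(seed = 5, n_islands = 0, frac_island = 0,
                     frac_shore = 0, frac_true_island = 0)
  ann <- simulate_annotation(cfg)
  st <- simulate_array_study(cfg, ann)
  expect_true(all(st$truth$context == "other"))
})

test_that("noise-free intensities reproduce the target beta exactly", {
  cfg <- tiny_config(
    seed = 9, noise_sd = 0, gender_effect = 0,
    n_batches = 1,
    intensity = list(total_mean = 4000, total_cv = 0.3, bg_mean = 200,
                     bg_sd = 0, dropout = 0))
  ann <- simulate_annotation(cfg)
  st <- simulate_array_study(cfg, ann)
  beta <- beta_from_panel(subtract_background(st$panel))
  sheet <- st$sample_sheet
  expected <- outer(st$truth$true_intercept, rep(1, nrow(sheet)))
  slope <- st$truth$true_slope
  tt <- st$truth$target_tissue
  for (j in seq_len(nrow(sheet))) {
    s <- ifelse(slope != 0 & !is.na(tt) & tt != sheet$tissue[j], 0, slope)
    expected[, j] <- expected[, j] + s * sheet$age[j]
  }
  expect_true(all(abs(beta - expected) < 1e-8))
  ## a 0.002/year slope implies a 0.1 beta difference over 50 years
  expect_equal(0.002 * 50, 0.1)
  p <- which(st$truth$true_slope > 0)[1]
  expect_false(is.na(p))
  d_beta <- (expected[p, ] - st$truth$true_intercept[p]) / sheet$age
  expect_equal(unname(d_beta[1]), st$truth$true_slope[p], tolerance = 1e-10)
})

test_that("simulated values respect their bounds", {
  cfg <- tiny_config(seed = 8)
  ann <- simulate_annotation(cfg)
  st <- simulate_array_study(cfg, ann)
  expect_true(all(st$panel$A >= 0) && all(st$panel$B >= 0))
  expect_true(all(st$truth$true_intercept >= 0 &
                    st$truth$true_intercept <= 1))
  bcfg <- tiny_config(seed = 8, bisseq = list(n_targets = 2,
                                              target_len = 300,
                                              depth_mean = 10))
  sim <- simulate_bisseq(bcfg)
  for (tg in sim$truth$targets)
    expect_true(all(tg$m >= 0 & tg$m <= 100))
})

test_that("batch offsets shift raw beta and ComBat removes the shift", {
  cfg <- tiny_config(seed = 21, n_tissues = 1, n_samples_per_tissue = 30,
                     n_probes = 150, n_batches = 2,
                     batch_offsets = list(beta_add = c(0, 0),
                                          add_A = c(0, 500),
                                          add_B = c(0, 0),
                                          mult = c(1, 1)))
  ann <- simulate_annotation(cfg)
  st <- simulate_array_study(cfg, ann)
  beta <- beta_from_panel(subtract_background(st$panel))
  b2 <- st$sample_sheet$batch == "chip2"
  raw_diff <- rowMeans(beta[, b2], na.rm = TRUE) -
    rowMeans(beta[, !b2], na.rm = TRUE)
  ## +500 on channel A inflates the denominator: beta drops in batch 2
  expect_lt(mean(raw_diff, na.rm = TRUE), -0.02)
  norm <- combat_normalize(beta, st$sample_sheet$batch)
  post_diff <- rowMeans(norm[, b2], na.rm = TRUE) -
    rowMeans(norm[, !b2], na.rm = TRUE)
  expect_lt(mean(abs(post_diff), na.rm = TRUE), 0.01)
})

test_that("fpkm generator marks silent genes and boosts negative-ageCG genes", {
  cfg <- tiny_config(seed = 13, frac_true = 0)
  ann <- simulate_annotation(cfg)
  st <- simulate_array_study(cfg, ann)
  fp <- simulate_fpkm(ann, st$truth, cfg, frac_silent = 1)
  expect_true(all(fp$fpkm < 0.05))

  cfg2 <- tiny_config(seed = 14, frac_true = 0.2, frac_true_island = 0)
  ann2 <- simulate_annotation(cfg2)
  st2 <- simulate_array_study(cfg2, ann2)
  fp2 <- simulate_fpkm(ann2, st2$truth, cfg2)
  neg_genes <- unique(st2$truth$gene[st2$truth$tissue_specific])
  other <- fp2[!(fp2$gene %in% neg_genes), ]
  linked <- merge(
    fp2, unique(st2$truth[st2$truth$tissue_specific,
                          c("gene", "target_tissue")]),
    by.x = c("gene", "tissue"), by.y = c("gene", "target_tissue"))
  rs <- ranksum_expression(linked$fpkm, other$fpkm)
  expect_lt(rs$p, 0.05)
  expect_gt(median(linked$fpkm), median(other$fpkm))
})

test_that("bisulfite reads reflect the methylation surface at the extremes", {
  base <- list(n_targets = 2, target_len = 250, depth_mean = 30,
               base_error_rate = 0, conversion_failure_rate = 0,
               frac_lowq = 0, m_amp = 0, sigma_dev = 0, beta_age_true = 0)
  call_pcts <- function(cfg) {
    sim <- simulate_bisseq(cfg)
    mp <- map_reads(sim$reads, sim$targets)
    calls <- call_methylation(dedupe(mp$mapped), sim$targets)
    calls$pct[!is.na(calls$pct)]
  }
  p100 <- call_pcts(tiny_config(seed = 2, bisseq = c(base, list(m_mid = 100))))
  expect_gt(length(p100), 0)
  expect_true(all(p100 == 100))
  p0 <- call_pcts(tiny_config(seed = 2, bisseq = c(base, list(m_mid = 0))))
  expect_gt(length(p0), 0)
  expect_true(all(p0 == 0))
})

test_that("a target without CpGs is skipped with a warning", {
  cfg <- tiny_config(seed = 4, bisseq = list(n_targets = 1, target_len = 60,
                                             depth_mean = 5))
  tg <- data.frame(target_id = c("noCG", "hasCG"), chrom = "chrS",
                   start = c(0, 1000), end = c(60, 1060),
                   seq = c(strrep("AT", 30),
                           paste0(strrep("AT", 14), "CG", strrep("TA", 15))),
                   stringsAsFactors = FALSE)
  expect_warning(sim <- simulate_bisseq(cfg, targets = tg),
                 "no CpG")
  expect_false("noCG" %in% names(sim$truth$targets))
  expect_true("hasCG" %in% names(sim$truth$targets))
})
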