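test_that("reference conversion indexes CpGs and converts every C", {
  r <- convert_reference("ACGT")
  expect_equal(r$converted, "ATGT")
  expect_equal(r$cpg_index, 2L)
  expect_equal(convert_reference("TTTT")$cpg_index, integer(0))
  r2 <- convert_reference("CCGG")
  expect_equal(r2$converted, "TTGG")
  expect_equal(r2$cpg_index, 2L)  # only the C of CG is indexed
  expect_error(convert_reference("ACXT"), "offset 3")
})

test_that("read conversion handles mates as specified", {
  fwd <- convert_reads("ACGA", "IIII", "fwd")
  expect_equal(fwd$seq, "ATGA")
  rev <- convert_reads("AAGC", "IJKL", "rev")
  expect_equal(rev$seq, "GTTT")       # revcomp GCTT then C->T
  expect_equal(rev$qual, "LKJI")
  expect_equal(convert_reads("TTTT", "IIII", "fwd")$seq, "TTTT")
})

test_that("mapping is exact, unique and forward-only", {
  tg <- data.frame(target_id = "T1", chrom = "chrS", start = 0,
                   seq = paste0("AAACAGATTTCCGGGTTACGATACCAGGTA",
                                "TTTTTTTTTTTTTTTTTTTT"))
  reads <- data.frame(
    read_id = c("u1", "amb", "mm"),
    sample_id = "s1", mate = "fwd",
    seq = c("ACAGATTTCC", "TTTTTTTTTT", "ACAGATTACC"),
    qual = strrep("I", 10), stringsAsFactors = FALSE)
  mp <- map_reads(reads, tg)
  expect_equal(mp$mapped$read_id, "u1")
  expect_equal(mp$mapped$offset, 3L)
  expect_equal(mp$n_ambiguous, 1)   # poly-T hits many offsets
  expect_equal(mp$n_unmapped, 1)    # one mismatch: exact-match policy
  ## no reverse-orientation mapping: the revcomp of a target substring
  ## does not map as a fwd read
  rc <- data.frame(read_id = "rc1", sample_id = "s1", mate = "fwd",
                   seq = agemeth:::revcomp_chr("ACAGATTTCC"),
                   qual = strrep("I", 10), stringsAsFactors = FALSE)
  expect_equal(map_reads(rc, tg)$n_unmapped, 1)
})

test_that("deduplication keeps the highest-quality read per position", {
  reads <- rbind(
    mapped_read("s1", "T1", 5, "ACGT", "IIII", read_id = "a"),   # Q40
    mapped_read("s1", "T1", 5, "ACGT", "5555", read_id = "b"),   # Q20
    mapped_read("s1", "T1", 5, "ACGT", "!!!!", read_id = "c"),   # Q0
    mapped_read("s1", "T1", 9, "ACGT", "IIII", read_id = "d"),
    mapped_read("s2", "T1", 5, "ACGT", "IIII", read_id = "e"))
  dd <- dedupe(reads)
  expect_equal(sort(dd$read_id), c("a", "d", "e"))
  expect_identical(dedupe(dd)[order(dedupe(dd)$read_id), ],
                   dd[order(dd$read_id), ])  # idempotent
  ## quality tie broken by read id
  tie <- rbind(mapped_read("s1", "T1", 5, "ACGT", "IIII", read_id = "z"),
               mapped_read("s1", "T1", 5, "ACGT", "IIII", read_id = "y"))
  expect_equal(dedupe(tie)$read_id, "y")
})

test_that("methylation calls respect depth and quality thresholds", {
  ## target with one CpG at position 3 (C of "CG")
  tg <- data.frame(target_id = "T1", chrom = "chrS", start = 100,
                   seq = "AACGTT", stringsAsFactors = FALSE)
  q40 <- strrep("I", 6)
  mk <- function(n, base, qual = q40) {
    do.call(rbind, lapply(seq_len(n), function(i)
      mapped_read("s1", "T1", 1,
                  paste0("AA", base, "GTT"), qual,
                  read_id = sprintf("%s%03d", base, i))))
  }
  ## 12 C + 8 T at quality 40: depth 20, pct 60
  calls <- call_methylation(rbind(mk(12, "C"), mk(8, "T")), tg)
  expect_equal(calls$n_meth, 12)
  expect_equal(calls$n_unmeth, 8)
  expect_equal(calls$depth, 20)
  expect_equal(calls$pct, 60)
  expect_equal(calls$pos, 103)  # genomic coordinate: start + local pos
  ## 10 C + 9 T: depth 19, counts kept, pct missing
  c19 <- call_methylation(rbind(mk(10, "C"), mk(9, "T")), tg)
  expect_equal(c19$depth, 19)
  expect_true(is.na(c19$pct))
  ## a phred-29 C is filtered out
  q29 <- paste0("II", rawToChar(as.raw(29 + 33)), "III")
  c29 <- call_methylation(rbind(mk(12, "C"), mk(8, "T"),
                                mk(1, "C", qual = q29)), tg)
  expect_equal(c29$n_meth, 12)
  ## non-C/T bases at the CpG are ignored
  cn <- call_methylation(rbind(mk(12, "C"), mk(8, "T"), mk(2, "A")), tg)
  expect_equal(cn$depth, 20)
})

test_that("calls are invariant to read order", {
  tg <- data.frame(target_id = "T1", chrom = "chrS", start = 0,
                   seq = "AACGTTACGT", stringsAsFactors = FALSE)
  set.seed(31)
  reads <- do.call(rbind, lapply(1:30, function(i)
    mapped_read("s1", "T1", sample(1:3, 1),
                substr("AACGTTACGT", o <- sample(1:3, 1), o + 5),
                strrep("I", 6), read_id = sprintf("r%03d", i))))
  reads$seq <- substr("AACGTTACGT", reads$offset, reads$offset + 5)
  c1 <- call_methylation(reads, tg)
  c2 <- call_methylation(reads[sample(nrow(reads)), ], tg)
  expect_identical(c1, c2)
})

test_that("young-old deltas use group medians per CpG", {
  calls <- data.frame(
    sample_id = rep(c("y1", "y2", "y3", "o1", "o2"), each = 1),
    target_id = "T1", chrom = "chrS", pos = 10,
    n_meth = 10, n_unmeth = 10, depth = 20,
    pct = c(38, 40, 44, 50, 60))
  d <- delta_young_old(calls, young = c("y1", "y2", "y3"),
                       old = c("o1", "o2"))
  expect_equal(d$delta, 40 - 55)
  ## identical groups give zero
  calls2 <- calls; calls2$pct <- 42
  expect_equal(delta_young_old(calls2, c("y1", "y2"), c("o1", "o2"))$delta, 0)
  ## a fully missing group yields a missing delta
  calls3 <- calls; calls3$pct[4:5] <- NA
  expect_true(is.na(delta_young_old(calls3, c("y1", "y2", "y3"),
                                    c("o1", "o2"))$delta))
  expect_error(delta_young_old(calls, character(0), "o1"), "nonempty")
})

test_that("Bland-Altman limits match the closed form", {
  b <- bland_altman(c(10, 20, 30), c(10, 20, 30))
  expect_equal(c(b$mean_diff, b$loa_low, b$loa_high), c(0, 0, 0))
  b5 <- bland_altman(c(15, 25, 35), c(10, 20, 30))
  expect_equal(c(b5$mean_diff, b5$loa_low, b5$loa_high), c(5, 5, 5))
  b2 <- bland_altman(c(10, 30), c(10, 20))
  expect_equal(b2$mean_diff, 5)
  expect_equal(b2$loa_low, 5 - 1.96 * sd(c(0, 10)))
  expect_equal(b2$loa_high, 5 + 1.96 * sd(c(0, 10)))
  expect_equal(b2$loa_high, 18.859293, tolerance = 1e-6)
  expect_equal(b2$loa_low, -8.859293, tolerance = 1e-6)
  expect_error(bland_altman(1, 2), ">= 2")
})

test_that("platform concordance computes per-sample r and pooled fractions", {
  bis <- expand.grid(sample_id = c("s1", "s2"), pos = c(10, 20, 30, 40))
  bis$chrom <- "chrS"
  bis$pct <- c(10, 15, 30, 35, 50, 55, 70, 75)
  arr <- bis; names(arr)[names(arr) == "pct"] <- "beta"
  arr$beta <- bis$pct / 100
  pc <- platform_concordance(bis, arr)
  expect_true(all(pc$per_sample$r == 1))
  expect_equal(pc$frac_lt10, 1)
  expect_equal(pc$frac_lt15, 1)
  arr2 <- arr; arr2$beta <- (bis$pct + 20) / 100
  pc2 <- platform_concordance(bis, arr2)
  expect_true(all(abs(pc2$per_sample$r - 1) < 1e-12))
  expect_equal(pc2$frac_lt10, 0)
  expect_equal(pc2$frac_lt15, 0)
  ## samples with too few shared CpGs are skipped with a notice
  bis3 <- bis[bis$sample_id == "s1" | bis$pos == 10, ]
  pc3 <- platform_concordance(bis3, arr)
  expect_equal(pc3$skipped, "s2")
})

test_that("error-free simulated reads give exact realized-fraction calls", {
  cfg <- tiny_config(seed = 33, bisseq = list(
    n_targets = 2, target_len = 220, depth_mean = 40,
    base_error_rate = 0, conversion_failure_rate = 0, frac_lowq = 0,
    sigma_dev = 3))
  sim <- simulate_bisseq(cfg)
  mp <- map_reads(sim$reads, sim$targets)
  dd <- dedupe(mp$mapped)
  calls <- call_methylation(dd, sim$targets)
  ## independent pileup from the deduplicated reads themselves
  for (k in sample(nrow(calls), 25)) {
    row <- calls[k, ]
    local <- row$pos - sim$targets$start[match(row$target_id,
                                               sim$targets$target_id)]
    sub <- dd[dd$sample_id == row$sample_id & dd$target_id == row$target_id, ]
    cover <- sub[sub$offset <= local &
                   local <= sub$offset + nchar(sub$seq) - 1, ]
    base <- substr(cover$seq, local - cover$offset + 1,
                   local - cover$offset + 1)
    expect_equal(row$n_meth, sum(base == "C"))
    expect_equal(row$n_unmeth, sum(base == "T"))
    if (!is.na(row$pct))
      expect_equal(row$pct, 100 * sum(base == "C") /
                     (sum(base == "C") + sum(base == "T")))
  }
})
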