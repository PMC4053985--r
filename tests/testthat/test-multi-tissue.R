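test_that("overlap_sets enumerates subset intersections exactly", {
  sets <- list(t1 = c("A", "B"), t2 = c("B", "C"), t3 = "B", t4 = c("B", "D"))
  ov <- overlap_sets(sets)
  expect_equal(ov$count[ov$subset == "t1+t2+t3+t4"], 1)
  expect_equal(ov$count[ov$subset == "t1"], 2)
  expect_equal(ov$count[ov$subset == "t1+t2"], 1)
  ## identical sets: every subset overlap equals the set size
  ident <- overlap_sets(list(a = 1:7, b = 1:7, c = 1:7))
  expect_true(all(ident$count == 7))
  ## disjoint sets: every multi-set overlap is zero
  disj <- overlap_sets(list(a = 1:3, b = 4:6))
  expect_equal(disj$count[disj$k == 2], 0)
})

test_that("overlap_sets agrees with brute-force membership testing", {
  set.seed(21)
  for (rep in 1:10) {
    sets <- lapply(1:3, function(i) sample.int(30, sample(5:15, 1)))
    names(sets) <- c("x", "y", "z")
    ov <- overlap_sets(sets)
    universe <- 1:30
    brute <- sum(universe %in% sets$x & universe %in% sets$y &
                   universe %in% sets$z)
    expect_equal(ov$count[ov$subset == "x+y+z"], brute)
  }
})

test_that("permutation_overlap is reproducible and matches its expectation", {
  r1 <- permutation_overlap(c(50, 60, 70, 80), universe = 500, reps = 2000,
                            seed = 99)
  r2 <- permutation_overlap(c(50, 60, 70, 80), universe = 500, reps = 2000,
                            seed = 99)
  expect_identical(r1$null, r2$null)
  expect_equal(r1$expected, 500 * prod(c(50, 60, 70, 80) / 500))
  mc_se <- sd(r1$null) / sqrt(r1$reps)
  expect_lte(abs(r1$null_mean - r1$expected), 3 * mc_se)
  ## saturated sets overlap completely in every replicate
  full <- permutation_overlap(c(10, 10), universe = 10, reps = 5, seed = 1)
  expect_true(all(full$null == 10))
  expect_error(permutation_overlap(c(11, 5), universe = 10),
               "exceeds")
  ## add-one smoothed empirical p
  robs <- permutation_overlap(c(5, 5), universe = 100, reps = 200, seed = 2,
                              observed = 5)
  expect_equal(robs$p, (1 + sum(robs$null >= 5)) / 201)
})

test_that("gene-level unique/shared classes follow the q rules", {
  mk <- function(q) data.frame(probe_id = "p1", p = q / 2, q = q)
  res <- list(blood = mk(0.01), brain = mk(0.6), kidney = mk(0.7),
              muscle = mk(0.9))
  map <- data.frame(probe_id = "p1", gene = "G1")
  out <- gene_level_unique_shared(res, map)
  expect_equal(out$class, "unique-blood")
  res$brain <- mk(0.3)  # intermediate elsewhere: neither
  expect_equal(gene_level_unique_shared(res, map)$class, "neither")
  res <- list(blood = mk(0.01), brain = mk(0.02), kidney = mk(0.03),
              muscle = mk(0.04))
  expect_equal(gene_level_unique_shared(res, map)$class, "shared-all")
  ## gene untested in one tissue: unclassifiable
  res$muscle <- data.frame(probe_id = "p2", p = 0.5, q = 0.9)
  out2 <- gene_level_unique_shared(res, map)
  expect_false(out2$classifiable)
  expect_true(is.na(out2$class))
})

test_that("the representative CpG is the smallest p with probe-id tie-break", {
  res <- list(
    t1 = data.frame(probe_id = c("p2", "p1", "p3"),
                    p = c(0.001, 0.001, 0.5), q = c(0.01, 0.02, 0.6)),
    t2 = data.frame(probe_id = c("p1", "p2", "p3"),
                    p = c(0.9, 0.8, 0.7), q = c(0.95, 0.9, 0.85)))
  map <- data.frame(probe_id = c("p1", "p2", "p3"), gene = "G1")
  out <- gene_level_unique_shared(res, map)
  expect_equal(out$rep_probe_t1, "p1")  # tie on p broken by probe id
  expect_equal(out$q_t1, 0.02)
  expect_equal(out$rep_probe_t2, "p3")
})

test_that("classes are mutually exclusive and exhaustive for tested genes", {
  set.seed(22)
  tissues <- c("t1", "t2", "t3", "t4")
  for (rep in 1:20) {
    q <- runif(4)
    res <- lapply(seq_along(tissues), function(i)
      data.frame(probe_id = "p1", p = q[i] / 2, q = q[i]))
    names(res) <- tissues
    cls <- gene_level_unique_shared(
      res, data.frame(probe_id = "p1", gene = "G"))$class
    expect_true(cls %in% c("shared-all", "neither",
                           paste0("unique-", tissues)))
    manual <- if (all(q < 0.05)) "shared-all" else {
      hit <- which(q < 0.05)
      if (length(hit) == 1 && all(q[-hit] > 0.5))
        paste0("unique-", tissues[hit]) else "neither"
    }
    expect_equal(cls, manual)
  }
})

test_that("expression calls use the stated FPKM thresholds", {
  expect_equal(expression_call(c(0.3, 0.04, 0.1, 0.25, 0.05, NA)),
               c("expressed", "non-expressed", "indeterminate",
                 "indeterminate", "indeterminate", NA))
})

test_that("expression enrichment cross-tabulates and tests a 2x2", {
  genes <- sprintf("G%03d", 1:60)
  cls <- data.frame(gene = genes,
                    class = rep(c("ageCG", "nonageCG"), each = 30))
  expr <- data.frame(gene = genes,
                     fpkm = c(rep(0.01, 25), rep(1, 5),
                              rep(1, 25), rep(0.01, 5)))
  out <- expression_enrichment(cls, expr)
  counts <- matrix(as.numeric(out$table), 2,
                   dimnames = unname(dimnames(out$table)))
  expect_equal(counts, matrix(c(5, 25, 25, 5), 2,
                              dimnames = list(c("ageCG", "nonageCG"),
                                              c("expressed", "non-expressed"))))
  expect_lt(out$test$p.value, 1e-5)
  ## indeterminate calls are excluded from the margins
  expr$fpkm[1] <- 0.1
  out2 <- expression_enrichment(cls, expr)
  expect_equal(sum(out2$table), 59)
})

test_that("rank-sum comparison matches an exact enumeration oracle", {
  r <- ranksum_expression(c(1, 2, 3), c(10, 20, 30))
  expect_equal(r$U, 0)
  expect_lt(r$p, 0.1)
  set.seed(23)
  for (rep in 1:10) {
    x <- runif(sample(4:9, 1), 0.1, 5)
    y <- runif(sample(4:9, 1), 0.1, 5)
    got <- ranksum_expression(x, y)
    U_brute <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
    expect_equal(unname(got$U), U_brute)
  }
  ## identical groups: p near 1
  expect_gt(ranksum_expression(1:20, 1:20)$p, 0.9)
  expect_error(ranksum_expression(c(0, 0), c(1, 2)), "empty")
})

test_that("rank-sum detects a one-SD shift at n = 200 per group", {
  set.seed(24)
  hits <- vapply(1:100, function(i) {
    x <- rlnorm(200, 0, 1)
    y <- rlnorm(200, 1, 1)
    ranksum_expression(x, y)$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("the exact-test option reproduces published unique/shared cells", {
  ## kidney and muscle unique-vs-shared expression tables
  kidney <- matrix(c(82, 22, 17, 13), nrow = 2, byrow = TRUE)
  muscle <- matrix(c(84, 11, 11, 15), nrow = 2, byrow = TRUE)
  expect_equal(signif(stats::fisher.test(kidney)$p.value, 2), 0.019)
  expect_equal(signif(stats::fisher.test(muscle)$p.value, 3), 3.40e-6)
  ## the wiring through expression_enrichment
  cls <- data.frame(gene = sprintf("G%02d", 1:40),
                    class = rep(c("unique", "shared"), each = 20))
  expr <- data.frame(gene = sprintf("G%02d", 1:40),
                     fpkm = rep(c(1, 0.01, 1, 0.01), c(15, 5, 5, 15)))
  out <- expression_enrichment(cls, expr, method = "fisher")
  expect_equal(out$test$method, "fisher")
  expect_equal(out$test$p.value,
               stats::fisher.test(matrix(c(15, 5, 5, 15), 2))$p.value)
})
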