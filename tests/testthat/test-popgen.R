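test_that("presence statistics match a brute-force column scan", {
  gt <- randomPlacementGT(60, 25, seed = 7)
  # add het calls on some diploid carriers
  set.seed(8)
  het <- which(gt == 2L & runif(length(gt)) < 0.4)
  gt[het] <- 1L
  panel <- panelFromGT(gt)
  ps <- presenceStats(panel)
  for (i in sample(nrow(gt), 15)) {
    carriers <- sum(gt[i, ] > 0)
    expect_equal(ps$n_strains[ps$variant_id == rownames(gt)[i]], carriers)
    expect_equal(ps$allele_frequency[ps$variant_id == rownames(gt)[i]],
                 carriers / 25)
    expect_equal(ps$het_fraction[ps$variant_id == rownames(gt)[i]],
                 sum(gt[i, ] == 1L) / carriers)
    expect_equal(ps$is_singleton[ps$variant_id == rownames(gt)[i]],
                 carriers == 1L)
  }
  # all-het variant
  gt2 <- rbind(gt, allhet = 0L)
  gt2["allhet", 1:4] <- 1L
  ps2 <- presenceStats(panelFromGT(gt2))
  expect_equal(ps2$het_fraction[ps2$variant_id == "allhet"], 1)
  # absent variant excluded with a warning
  gt3 <- rbind(gt, gone = 0L)
  expect_warning(ps3 <- presenceStats(panelFromGT(gt3)), "absent")
  expect_false("gone" %in% ps3$variant_id)
})

test_that("Jaccard similarity is exact set arithmetic with its invariants", {
  expect_equal(jaccardSimilarity(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccardSimilarity(c("a"), c("b")), 0)
  expect_equal(jaccardSimilarity(c("s1", "s2"), c("s2", "s3")), 1 / 3)
  expect_error(jaccardSimilarity(character(), "a"), "empty")
  # symmetry and the identity bound on random sets
  set.seed(1)
  pool <- sprintf("s%02d", 1:20)
  for (i in 1:50) {
    A <- sample(pool, sample(1:10, 1))
    B <- sample(pool, sample(1:10, 1))
    j1 <- jaccardSimilarity(A, B)
    expect_equal(j1, jaccardSimilarity(B, A))
    expect_lte(j1, 1)
    if (j1 == 1) expect_setequal(A, B)
  }
  # matrix form agrees with the scalar definition
  gt <- randomPlacementGT(12, 15, seed = 3)
  panel <- panelFromGT(gt)
  J <- pairwiseJaccard(panel)
  for (i in 1:11) for (j in (i + 1):12) {
    A <- colnames(gt)[gt[i, ] > 0]; B <- colnames(gt)[gt[j, ] > 0]
    expect_equal(J[i, j], jaccardSimilarity(A, B))
  }
})

test_that("control matching is greedy-optimal with the documented tie rules", {
  # exact-frequency zero-Jaccard controls available: all deltas are zero
  gt <- matrix(0L, 6, 12,
               dimnames = list(c("f1", "f2", "c1", "c2", "c3", "c4"),
                               sprintf("s%02d", 1:12)))
  gt["f1", 1:2] <- 2L; gt["f2", 3] <- 2L
  gt["c1", 4:5] <- 2L; gt["c2", 6] <- 2L
  gt["c3", 7:8] <- 2L; gt["c4", 9] <- 2L
  panel <- panelFromGT(gt)
  mc <- matchControls(c("f1", "f2"), c("c1", "c2", "c3", "c4"), panel,
                      seed = 1)
  expect_equal(nrow(mc$pairs), 2)
  expect_true(all(mc$pairs$delta_af == 0))
  expect_length(mc$unmatched, 0)

  # equal |dAF|: the lower-Jaccard candidate wins
  gt2 <- matrix(0L, 3, 10,
                dimnames = list(c("f", "hi", "lo"), sprintf("s%02d", 1:10)))
  gt2["f", 1:4] <- 2L
  gt2["hi", 1:4] <- 2L     # Jaccard 1 with focal
  gt2["lo", 5:8] <- 2L     # Jaccard 0 with focal
  mc2 <- matchControls("f", c("hi", "lo"), panelFromGT(gt2), seed = 1)
  expect_equal(mc2$pairs$control, "lo")

  # candidate pool exhaustion reports unmatched focal variants
  mc3 <- matchControls(c("f1", "f2"), "c1", panel, seed = 1)
  expect_equal(nrow(mc3$pairs), 1)
  expect_length(mc3$unmatched, 1)
})

test_that("every chosen control is optimal at its selection step (step-wise audit)", {
  af <- function(gt) rowSums(gt > 0) / ncol(gt)
  for (rep_i in 1:5) {
    gt <- randomPlacementGT(120, 30, seed = 100 + rep_i)
    panel <- panelFromGT(gt)
    focal <- rownames(gt)[1:15]
    cands <- rownames(gt)[16:120]
    mc <- matchControls(focal, cands, panel, seed = rep_i)
    freq <- af(gt)
    ord <- focal[order(-freq[focal], focal)]
    avail <- cands
    for (f in ord) {
      chosen <- mc$pairs$control[mc$pairs$focal == f]
      if (!length(chosen)) next
      d <- abs(freq[avail] - freq[f])
      expect_equal(unname(abs(freq[chosen] - freq[f])), min(d))
      tied <- avail[d == min(d)]
      jac <- vapply(tied, function(v)
        jaccardSimilarity(colnames(gt)[gt[f, ] > 0],
                          colnames(gt)[gt[v, ] > 0]), numeric(1))
      expect_equal(unname(jaccardSimilarity(
        colnames(gt)[gt[f, ] > 0], colnames(gt)[gt[chosen, ] > 0])),
        min(jac))
      avail <- setdiff(avail, chosen)
    }
    expect_false(anyDuplicated(mc$pairs$control) > 0)
  }
})

test_that("co-occurrence test reduces to co-occurrence frequency for singletons", {
  gt <- matrix(0L, 4, 10,
               dimnames = list(paste0("v", 1:4), sprintf("s%02d", 1:10)))
  gt["v1", 1] <- 2L; gt["v2", 1] <- 2L   # same strain: J = 1
  gt["v3", 2] <- 2L; gt["v4", 3] <- 2L   # different strains: J = 0
  panel <- panelFromGT(gt)
  J <- pairwiseJaccard(panel)
  expect_equal(J["v1", "v2"], 1)
  expect_equal(J["v3", "v4"], 0)
  res <- cooccurrenceTest(c("v1", "v2"), c("v3", "v4"), panel,
                          nBoot = 200, seed = 1)
  expect_equal(res$mean_jaccard_x, 1)
  expect_equal(res$mean_jaccard_y, 0)

  # identical sets: difference 0 and p near 1
  gt2 <- randomPlacementGT(10, 20, seed = 5)
  p2 <- panelFromGT(gt2)
  res2 <- cooccurrenceTest(rownames(gt2), rownames(gt2), p2,
                           nBoot = 500, seed = 2)
  expect_equal(res2$difference, 0)
  expect_gt(res2$p_value, 0.5)
})

test_that("singleton counts per strain match a brute-force double loop", {
  gt <- randomPlacementGT(80, 15, seed = 9)
  panel <- panelFromGT(gt)
  counts <- singletonsPerStrain(panel)
  oracle <- integer(15)
  for (j in 1:15) for (i in 1:80)
    if (gt[i, j] > 0 && sum(gt[i, ] > 0) == 1) oracle[j] <- oracle[j] + 1L
  expect_equal(unname(counts), oracle)
  # one singleton per strain
  gt1 <- diag(2L, 8); rownames(gt1) <- paste0("v", 1:8)
  colnames(gt1) <- paste0("s", 1:8)
  expect_true(all(singletonsPerStrain(panelFromGT(gt1)) == 1L))
})

test_that("strain-age comparison uses carrier singleton counts and the rank-sum test", {
  # strain j carries j-1 background singletons, so strain age is the index
  n <- 8
  n_bg <- sum(1:(n - 1))
  gt <- matrix(0L, n_bg + 6, n,
               dimnames = list(sprintf("v%03d", seq_len(n_bg + 6)),
                               sprintf("s%02d", 1:n)))
  k <- 1L
  for (j in 2:n) for (x in 1:(j - 1)) { gt[k, j] <- 2L; k <- k + 1L }
  # set A: singletons in young strains 1..3; set B: in old strains 6..8
  a_ids <- character(3); b_ids <- character(3)
  for (i in 1:3) { gt[n_bg + i, i] <- 2L; a_ids[i] <- rownames(gt)[n_bg + i] }
  for (i in 1:3) { gt[n_bg + 3 + i, 5 + i] <- 2L
                   b_ids[i] <- rownames(gt)[n_bg + 3 + i] }
  panel <- panelFromGT(gt)
  res <- suppressWarnings(strainAgeComparison(a_ids, b_ids, panel))
  expect_lt(res$median_a, res$median_b)
  # statistic equals the textbook rank-sum computation
  nsing <- singletonsPerStrain(panel)
  xa <- nsing[sprintf("s%02d", 1:3)]
  xb <- nsing[sprintf("s%02d", 6:8)]
  ranks <- rank(c(xa, xb))
  W_oracle <- sum(ranks[1:3]) - 3 * 4 / 2
  expect_equal(unname(res$W), W_oracle)
  # identical sets give p near 1
  same <- suppressWarnings(strainAgeComparison(a_ids, a_ids, panel))
  expect_gt(same$p, 0.99)
  # ploidy stratification returns the extra strata
  strat <- suppressWarnings(strainAgeComparison(a_ids, b_ids, panel,
                                                stratifyPloidy = TRUE))
  expect_setequal(strat$stratum, c("all", "haploid", "diploid"))
})
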