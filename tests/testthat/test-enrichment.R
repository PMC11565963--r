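# small deterministic panel for enrichment tests
enrichmentToy <- function() {
  strains <- sprintf("s%02d", 1:12)
  gt <- matrix(0L, 8, 12, dimnames = list(paste0("v", 1:8), strains))
  gt["v1", 1] <- 2L            # focal private to s01
  gt["v2", 1:6] <- 2L
  gt["v3", 7:12] <- 2L
  gt["v4", c(2, 5, 9)] <- 2L
  gt["v5", 4] <- 2L            # control private to s04
  gt["v6", 1:6] <- 2L
  gt["v7", 7:12] <- 2L
  gt["v8", c(3, 6, 10)] <- 2L
  panelFromGT(gt,
              clade = rep(c("c1", "c2", "c3"), each = 4),
              clade_class = rep(c("domesticated", "wild", "other"), each = 4),
              ecology = rep(c("industrial", "natural"), 6))
}

test_that("per-strain enrichment counts presence-set membership", {
  panel <- enrichmentToy()
  pairs <- data.frame(focal = c("v1", "v2", "v3", "v4"),
                      control = c("v5", "v6", "v7", "v8"))
  er <- perStrainEnrichment(pairs$focal, pairs, panel)
  # control set = focal set gives diff 0 everywhere
  self_pairs <- data.frame(focal = pairs$focal, control = pairs$focal)
  er0 <- perStrainEnrichment(pairs$focal, self_pairs, panel)
  expect_true(all(er0$diff == 0))
  # private focal in s01, private control in s04
  only <- perStrainEnrichment("v1", data.frame(focal = "v1", control = "v5"),
                              panel)
  expect_equal(only$diff[only$strain == "s01"], 1)
  expect_equal(only$diff[only$strain == "s04"], -1)
  expect_true(all(only$diff[!only$strain %in% c("s01", "s04")] == 0))
  # unmatched focal variants are excluded with a warning
  expect_warning(perStrainEnrichment(c("v1", "v2"),
                                     data.frame(focal = "v1",
                                                control = "v5"), panel),
                 "unmatched")
})

test_that("group comparison equals an independent rank-sum computation and flags small groups", {
  panel <- enrichmentToy()
  er <- data.frame(strain = colnames(panel),
                   clade = strainData(panel)$clade,
                   clade_class = strainData(panel)$clade_class,
                   ecology_class = strainData(panel)$ecology_class,
                   ploidy = 2L,
                   n_focal = 0L, n_control = 0L,
                   diff = c(3, 2, 4, 1, 5, 2, -1, 0, -2, 1, 0, -1))
  gc <- groupComparison(er, "clade_class")
  row <- gc[gc$group_a == "domesticated" & gc$group_b == "wild", ]
  a <- er$diff[er$clade_class == "domesticated"]
  b <- er$diff[er$clade_class == "wild"]
  ranks <- rank(c(a, b))
  expect_equal(unname(row$W), sum(ranks[1:4]) - 4 * 5 / 2)
  wt <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(row$p, wt$p.value)
  # identical distributions: p near 1
  er$diff <- rep(c(1, 2, 0, 1), 3)
  gci <- groupComparison(er, "clade_class")
  expect_true(all(gci$p > 0.5))
  # undersized group is skipped, not an error
  er2 <- er[-(5:7), ]
  gc2 <- groupComparison(er2, "clade_class", minSize = 4L)
  expect_true(any(gc2$skipped))
  expect_true(all(is.na(gc2$p[gc2$skipped])))
})

test_that("frequency sweep keeps pairs fixed, nests variant sets, and flags empty thresholds", {
  set.seed(77)
  gt <- randomPlacementGT(160, 40, seed = 77)
  panel <- panelFromGT(gt,
                       clade = rep(c("c1", "c2"), each = 20),
                       clade_class = rep(c("domesticated", "wild"), each = 20),
                       ecology = rep("natural", 40))
  focal <- rownames(gt)[1:30]
  mc <- matchControls(focal, rownames(gt)[31:160], panel, seed = 1)
  sw <- frequencySweep(focal, mc, panel)
  s <- sw$sweep
  expect_true(all(diff(s$threshold) < 0))
  # nesting: kept focal counts are non-increasing as thresholds drop
  expect_true(all(diff(s$n_focal_kept) <= 0))
  # top threshold covers the maximum carrier count: matches unfiltered
  er_full <- suppressWarnings(perStrainEnrichment(mc$pairs$focal, mc, panel))
  top <- s[1, ]
  expect_equal(top$mean_diff_domesticated,
               mean(er_full$diff[er_full$clade_class == "domesticated"]))
  # threshold 1 keeps only singletons
  ps <- presenceStats(panel)
  ns <- setNames(ps$n_strains, ps$variant_id)
  sw1 <- frequencySweep(focal, mc, panel, thresholds = 1)
  kept <- mc$pairs$focal[ns[mc$pairs$focal] <= 1 & ns[mc$pairs$control] <= 1]
  if (length(kept) >= 2) {
    expect_equal(sw1$sweep$n_focal_kept, sum(ns[focal] <= 1))
  } else {
    expect_true(sw1$sweep$flagged)
  }
})

test_that("planted domestication bias yields positive enrichment in domesticated strains", {
  cfg <- populationSimConfig(n_strains = 120L, n_variants = 260L,
    clade_spec = data.frame(clade = c("d1", "d2", "w1", "w2", "o1"),
                            clade_class = c("domesticated", "domesticated",
                                            "wild", "wild", "other"),
                            size = c(35L, 25L, 20L, 15L, 25L)),
    planted_beneficial = 30L, bias_strength = 0.9, seed = 19L)
  panel <- simulatePopulation(cfg)
  rd <- SummarizedExperiment::rowData(panel)
  present <- rowSums(genotypes(panel) > 0) > 0
  focal <- rownames(panel)[rd$planted_beneficial & present]
  cands <- rownames(panel)[!rd$planted_beneficial & present]
  mc <- matchControls(focal, cands, panel, seed = 3)
  er <- suppressWarnings(perStrainEnrichment(mc$pairs$focal, mc, panel))
  expect_gt(mean(er$diff[er$clade_class == "domesticated"]),
            mean(er$diff[er$clade_class == "wild"]))
  expect_gt(mean(er$diff[er$clade_class == "domesticated"]), 0)
})

test_that("ecology mixed model matches the balanced-design GLS oracle", {
  # balanced two-clade toy: with ecology balanced within clades the GLS /
  # REML fixed effect equals the plain difference of ecology means
  set.seed(5)
  d <- expand.grid(rep = 1:10, ecology_class = c("industrial", "natural"),
                   clade = c("cA", "cB"), stringsAsFactors = FALSE)
  beta <- 0.9
  clade_eff <- c(cA = 0.4, cB = -0.4)
  d$diff <- beta * (d$ecology_class == "industrial") +
    clade_eff[d$clade] + rnorm(nrow(d), 0, 0.6)
  d$strain <- sprintf("s%02d", seq_len(nrow(d)))
  d$clade_class <- "domesticated"
  res <- ecologyMixedModel(d)
  oracle <- mean(d$diff[d$ecology_class == "industrial"]) -
    mean(d$diff[d$ecology_class == "natural"])
  expect_equal(res$estimate, oracle, tolerance = 1e-6)
  expect_equal(res$method, "lmer REML + Satterthwaite")
  expect_true(res$p < 0.05)
  # requires both ecology classes
  expect_error(ecologyMixedModel(d[d$ecology_class == "natural", ]),
               "industrial")
})

test_that("exchangeable focal/control sets give near-zero mean enrichment", {
  diffs <- vapply(1:30, function(i) {
    gt <- randomPlacementGT(120, 30, seed = 900 + i)
    panel <- panelFromGT(gt)
    ids <- sample(rownames(gt))
    focal <- ids[1:25]
    mc <- matchControls(focal, ids[26:120], panel, seed = i)
    er <- suppressWarnings(perStrainEnrichment(mc$pairs$focal, mc, panel))
    mean(er$diff)
  }, numeric(1))
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 4 * se + 0.02)
})
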