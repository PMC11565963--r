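simulateAndFit <- function(design, trueS = NULL, engine = "variational",
                           removal = TRUE, config = modelConfig()) {
  sim <- simulateCompetition(design, trueS = trueS)
  be <- if (removal) removeOutlierBarcodes(sim$counts) else sim$counts
  fit <- fitFitness(aggregateCounts(be), config = config, engine = engine)
  list(sim = sim, fit = fit)
}

test_that("two-edit low-noise data recover s = (0.1, 0) and cover zero for the null edit", {
  des <- competitionDesign(n_edits = 2L, barcodes_per_edit = 3L,
                           n_neutral_barcodes = 5L, n_replicates = 2L,
                           n_timepoints = 5L, tau = 1,
                           bottleneck_cells = Inf,
                           reads_per_timepoint = 2e8, seed = 4L)
  r <- simulateAndFit(des, trueS = c(edit_0001 = 0.1, edit_0002 = 0))
  hf <- hyperfitness(r$fit)
  e1 <- hf[hf$edit_id == "edit_0001", ]
  e2 <- hf[hf$edit_id == "edit_0002", ]
  expect_lt(abs(e1$mean - 0.1), 0.005)
  expect_equal(e1$classification, "beneficial")
  expect_true(e2$lower <= 0 && e2$upper >= 0)
})

test_that("the variational fit is deterministic and anchored on the neutral set", {
  des <- tinyDesign(seed = 6L)
  a <- simulateAndFit(des)
  b <- simulateAndFit(des)
  expect_identical(hyperfitness(a$fit), hyperfitness(b$fit))
  expect_identical(meanFitness(a$fit), meanFitness(b$fit))
  # anchors are pinned to zero
  hf <- hyperfitness(a$fit)
  expect_true(all(hf$mean[hf$neutral_anchor] == 0))
  expect_true(all(hf$classification[hf$neutral_anchor] == "neutral"))
  expect_true(all(vapply(a$fit@diagnostics, `[[`, TRUE, "converged")))
})

test_that("adding a constant to every edit's fitness shifts estimates by that constant", {
  # relative-fitness identifiability: the anchors fix the gauge, so the
  # posterior tracks the shift exactly (within posterior uncertainty)
  des <- competitionDesign(n_edits = 30L, barcodes_per_edit = 5L,
                           n_neutral_barcodes = 15L, n_replicates = 2L,
                           n_timepoints = 5L, bottleneck_cells = 5e6,
                           reads_per_timepoint = 2e6, seed = 13L)
  set.seed(99)
  s0 <- rnorm(30, 0, 0.05)
  names(s0) <- sprintf("edit_%04d", 1:30)
  c0 <- 0.02
  fit_a <- simulateAndFit(des, trueS = s0)$fit
  fit_b <- simulateAndFit(des, trueS = s0 + c0)$fit
  ha <- hyperfitness(fit_a); hb <- hyperfitness(fit_b)
  sel <- !ha$neutral_anchor
  shift <- hb$mean[sel] - ha$mean[sel]
  tol <- 3 * sqrt(ha$sd[sel]^2 + hb$sd[sel]^2)
  expect_true(all(abs(shift - c0) < pmax(tol, 0.01)))
})

test_that("missing timepoints are dropped, not imputed", {
  des <- tinyDesign(seed = 15L)
  sim <- simulateCompetition(des)
  # lose the last two timepoints of one replicate (contamination scenario)
  be <- sim$counts
  cd <- SummarizedExperiment::colData(be)
  drop_cols <- which(cd$replicate == "R2" & cd$timepoint >= 3)
  m <- SummarizedExperiment::assay(be, "counts")
  m[, drop_cols] <- NA_real_
  SummarizedExperiment::assays(be)$counts <- m
  fit <- fitFitness(aggregateCounts(removeOutlierBarcodes(be)))
  ts <- trueS(sim$truth)
  hf <- hyperfitness(fit)
  mm <- merge(hf[!hf$neutral_anchor, ], ts, by = c("edit_id", "condition"))
  expect_gt(cor(mm$mean, mm$s), 0.95)
})

test_that("the MCMC engine agrees with the variational engine on recovery", {
  des <- competitionDesign(n_edits = 25L, barcodes_per_edit = 4L,
                           n_neutral_barcodes = 10L, n_replicates = 2L,
                           n_timepoints = 5L, bottleneck_cells = 2e6,
                           reads_per_timepoint = 1e6, seed = 23L)
  cfg <- modelConfig(seed = 2L)
  sim <- simulateCompetition(des)
  agg <- aggregateCounts(removeOutlierBarcodes(sim$counts))
  fit_vi <- fitFitness(agg, config = cfg)
  fit_mc <- fitFitness(agg, config = cfg, engine = "mcmc")
  ts <- trueS(sim$truth)
  hv <- hyperfitness(fit_vi); hm <- hyperfitness(fit_mc)
  sel <- !hv$neutral_anchor
  mv <- merge(hv[sel, ], ts, by = c("edit_id", "condition"))
  mm <- merge(hm[sel, ], ts, by = c("edit_id", "condition"))
  expect_gt(cor(mv$mean, mv$s), 0.95)
  expect_gt(cor(mm$mean, mm$s), 0.95)
  expect_lt(max(abs(hv$mean[sel] - hm$mean[sel])), 0.01)
  expect_lt(max(fit_mc@diagnostics[["1D"]]$split_rhat), 1.2)
  # MCMC is reproducible under the same seed
  fit_mc2 <- fitFitness(agg, config = cfg, engine = "mcmc")
  expect_identical(hyperfitness(fit_mc), hyperfitness(fit_mc2))
})

test_that("classification follows the credible-interval rule and focal flags count conditions", {
  hf <- data.frame(
    edit_id = rep(c("e1", "e2", "e3"), each = 2),
    condition = rep(c("1D", "3D"), 3),
    mean = c(0.005, 0.02, 0.025, 0.002, -0.03, -0.02),
    sd = c(0.01, 0.01, 0.005, 0.01, 0.005, 0.005) / 1.959964,
    lower = NA_real_, upper = NA_real_,
    classification = NA_character_,
    neutral_anchor = FALSE, stringsAsFactors = FALSE)
  fit <- new("FitnessFit", hyperfitness = hf,
             replicateFitness = data.frame(), meanFitness = data.frame(),
             intervalMass = 0.95, engine = "variational",
             diagnostics = list(), config = list())
  fit <- classify(fit, 0.95)
  h <- hyperfitness(fit)
  # e1/1D: interval (-0.005, 0.015) -> neutral; e1/3D: (0.01, 0.03) -> beneficial
  expect_equal(h$classification[h$edit_id == "e1"], c("neutral", "beneficial"))
  # e2/1D: (0.02, 0.03) beneficial; e2/3D: neutral
  expect_equal(h$classification[h$edit_id == "e2"], c("beneficial", "neutral"))
  # e3: deleterious in both
  expect_equal(h$classification[h$edit_id == "e3"],
               c("deleterious", "deleterious"))
  fs <- focalSets(fit)
  expect_equal(fs$n_conditions_non_neutral[fs$edit_id == "e1"], 1L)
  expect_equal(fs$n_conditions_non_neutral[fs$edit_id == "e3"], 2L)
  expect_true(fs$non_neutral_2plus[fs$edit_id == "e3"])
  expect_false(fs$non_neutral_2plus[fs$edit_id == "e1"])
  expect_true(fs$beneficial_any[fs$edit_id == "e1"])
  expect_false(fs$beneficial_any[fs$edit_id == "e3"])
  # widening the interval turns borderline calls neutral
  h99 <- hyperfitness(classify(fit, 0.99999))
  expect_equal(h99$classification[h99$edit_id == "e1" & h99$condition == "3D"],
               "neutral")
})

test_that("replicate concordance hits +1/-1 for identical and rank-reversed estimates", {
  edits <- sprintf("e%02d", 1:10)
  vals <- seq(0.01, 0.1, length.out = 10)
  mk <- function(r2) {
    hf <- data.frame(edit_id = edits, condition = "1D", mean = vals,
                     sd = 1e-4, lower = vals - 1e-3, upper = vals + 1e-3,
                     classification = "beneficial", neutral_anchor = FALSE)
    rf <- rbind(
      data.frame(edit_id = edits, condition = "1D", replicate = "R1",
                 mean = vals, sd = 1e-4),
      data.frame(edit_id = edits, condition = "1D", replicate = "R2",
                 mean = r2, sd = 1e-4))
    new("FitnessFit", hyperfitness = hf, replicateFitness = rf,
        meanFitness = data.frame(), intervalMass = 0.95,
        engine = "variational", diagnostics = list(), config = list())
  }
  expect_equal(replicateConcordance(mk(vals))$rho, 1)
  expect_equal(replicateConcordance(mk(rev(vals)))$rho, -1)
  # fewer than 3 non-neutral edits: flagged NA
  few <- mk(vals)
  few@hyperfitness$classification[3:10] <- "neutral"
  rc <- replicateConcordance(few)
  expect_true(rc$insufficient)
  expect_true(is.na(rc$rho))
})
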