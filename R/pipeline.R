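#' Pipeline configuration
#'
#' Binds the simulation designs, model configuration and analysis
#' thresholds into one reproducible unit. Defaults follow the screen's
#' analysis constants: common variants occur in more than 10 strains, the
#' focal set is non-neutral in at least 2 conditions, strong effects exceed
#' twice the mean absolute fitness, 1000 bootstrap replicates.
#'
#' @param outdir output directory for all stage artifacts.
#' @param design a [CompetitionDesign-class] for the competition stage.
#' @param popConfig a [PopulationSimConfig-class] for the population stage.
#' @param model a [modelConfig()].
#' @param intervalMass credible mass for classification.
#' @param nBoot bootstrap replicates for the co-occurrence test.
#' @param commonStrainCount strain-count threshold defining common variants.
#' @param focalConditionCount conditions required for the focal set.
#' @param strongEffectMultiplier multiplier of mean |fitness| defining
#'   strong effects.
#' @param focalSet `"beneficial_any"` (default, used by the enrichment
#'   stage) or `"non_neutral_2plus"`.
#' @param seed global seed; stage seeds derive from it.
#' @return list of class `screenfit_pipeline_config`.
#' @export
pipelineConfig <- function(outdir = tempfile("screenfit_run_"),
                           design = competitionDesign(),
                           popConfig = populationSimConfig(),
                           model = modelConfig(),
                           intervalMass = 0.95, nBoot = 1000L,
                           commonStrainCount = 10L,
                           focalConditionCount = 2L,
                           strongEffectMultiplier = 2,
                           focalSet = c("beneficial_any", "non_neutral_2plus"),
                           seed = 1L) {
  focalSet <- match.arg(focalSet)
  stopifnot(commonStrainCount > 0, focalConditionCount > 0,
            strongEffectMultiplier > 0, nBoot > 0)
  design@seed <- as.integer(seed)
  popConfig@seed <- as.integer(seed) + 1L
  model$seed <- as.integer(seed) + 2L
  model$interval_mass <- intervalMass
  structure(list(outdir = outdir, design = design, popConfig = popConfig,
                 model = model, intervalMass = intervalMass,
                 nBoot = as.integer(nBoot),
                 commonStrainCount = as.integer(commonStrainCount),
                 focalConditionCount = as.integer(focalConditionCount),
                 strongEffectMultiplier = strongEffectMultiplier,
                 focalSet = focalSet, seed = as.integer(seed)),
            class = "screenfit_pipeline_config")
}

## hash of the semantically meaningful configuration fields
configHash <- function(cfg) {
  x <- cfg[setdiff(names(cfg), "outdir")]
  x$design <- attributes(x$design)
  x$popConfig <- attributes(x$popConfig)
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(json, f)
  unname(tools::md5sum(f))
}

#' Validate the cross-file consistency of a pipeline input bundle
#'
#' Checks, before any compute: every barcode maps to exactly one edit; VCF
#' samples are all present in the strain metadata; tree tips match the
#' metadata strains. All failures are enumerated, not just the first.
#'
#' @param countsPath counts TSV (barcode_id, edit_id, replicate, condition,
#'   timepoint, reads).
#' @param vcfPath genotype VCF.
#' @param metadataPath strain-metadata TSV.
#' @param treePath rooted newick.
#' @return character vector of error messages (empty when consistent).
#' @export
validateInputs <- function(countsPath = NULL, vcfPath = NULL,
                           metadataPath = NULL, treePath = NULL) {
  errors <- character()
  for (p in c(countsPath, vcfPath, metadataPath, treePath))
    if (!is.null(p) && !file.exists(p))
      errors <- c(errors, paste("missing input file:", p))
  if (length(errors)) return(errors)
  if (!is.null(countsPath)) {
    tab <- readTsv(countsPath)
    map <- unique(tab[, c("barcode_id", "edit_id")])
    dup <- unique(map$barcode_id[duplicated(map$barcode_id)])
    if (length(dup))
      errors <- c(errors, paste("barcode mapped to two edits:",
                                paste(dup, collapse = ", ")))
  }
  meta <- NULL
  if (!is.null(metadataPath)) meta <- readStrainMetadata(metadataPath)
  if (!is.null(vcfPath) && !is.null(meta)) {
    v <- readGenotypeVcf(vcfPath)
    missing <- setdiff(colnames(v$gt), meta$strain)
    if (length(missing))
      errors <- c(errors, paste("VCF sample(s) absent from metadata:",
                                paste(missing, collapse = ", ")))
  }
  if (!is.null(treePath) && !is.null(meta)) {
    tree <- readStrainTree(treePath)
    if (!setequal(tree$tip.label, meta$strain))
      errors <- c(errors, "tree tips do not match metadata strains")
  }
  errors
}

stagePaths <- function(outdir) {
  list(counts = file.path(outdir, "counts.tsv"),
       design = file.path(outdir, "edit_design.tsv"),
       truth = file.path(outdir, "truth.json"),
       fitness = file.path(outdir, "fitness.tsv"),
       mean_fitness = file.path(outdir, "mean_fitness.tsv"),
       diagnostics = file.path(outdir, "diagnostics.json"),
       vcf = file.path(outdir, "population.vcf"),
       metadata = file.path(outdir, "strain_metadata.tsv"),
       tree = file.path(outdir, "strain_tree.nwk"),
       variant_stats = file.path(outdir, "variant_stats.tsv"),
       matched_pairs = file.path(outdir, "matched_pairs.tsv"),
       cooccurrence = file.path(outdir, "cooccurrence.json"),
       enrichment = file.path(outdir, "enrichment.tsv"),
       sweep = file.path(outdir, "sweep.tsv"),
       mixed_model = file.path(outdir, "mixed_model.json"),
       summary = file.path(outdir, "summary.tsv"),
       manifest = file.path(outdir, "manifest.json"))
}

## Map edit ids of the competition to variant ids of the panel by index:
## edit_0001 <-> var_00001 etc. (the synthetic bundle's pairing).
editToVariant <- function(edit_ids, panel) {
  idx <- as.integer(sub("^edit_", "", edit_ids))
  vs <- rownames(panel)[idx]
  stats::setNames(vs, edit_ids)
}

#' Run the full synthetic-bundle pipeline
#'
#' Stages, in dependency order: (1) simulate the competition and write
#' counts/design/truth; (2) outlier-barcode removal, aggregation,
#' hierarchical fit and classification; (3) simulate the population panel
#' and write VCF/metadata/tree plus per-variant statistics; (4) match the
#' focal set (per `cfg$focalSet`, edits paired to panel variants by index)
#' to neutral controls; (5) co-occurrence bootstrap test; (6) per-strain
#' enrichment, clade-class comparison, frequency sweep and ecology mixed
#' model; (7) summary tables and the run manifest.
#'
#' A stage whose outputs already exist under an identical configuration
#' hash is skipped, so deleting one intermediate regenerates only the
#' stages downstream of it. Every seed derives from `cfg$seed`.
#'
#' @param cfg a [pipelineConfig()].
#' @param force rerun all stages even when outputs exist.
#' @return the run manifest (list), invisibly; all artifacts are under
#'   `cfg$outdir`.
#' @export
runPipeline <- function(cfg, force = FALSE) {
  stopifnot(inherits(cfg, "screenfit_pipeline_config"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  p <- stagePaths(cfg$outdir)
  hash <- configHash(cfg)
  old_manifest <- if (file.exists(p$manifest))
    jsonlite::read_json(p$manifest, simplifyVector = TRUE) else NULL
  reuse_ok <- !force && !is.null(old_manifest) &&
    identical(old_manifest$config_hash, as.character(hash))
  stages <- list()
  log <- list()
  upstream_ran <- FALSE

  needs <- function(files) !reuse_ok || upstream_ran ||
    !all(file.exists(unlist(files)))

  ## stage 1: competition simulation
  if (needs(p[c("counts", "design", "truth")])) {
    sim <- simulateCompetition(cfg$design)
    writeBarcodeCounts(sim$counts, p$counts)
    writeEditDesign(sim$counts, p$design)
    writeTruth(sim$truth, p$truth)
    stages$simulate_competition <- "ran"
    upstream_ran <- TRUE
    log$simulate_competition <- list(barcodes = nrow(sim$counts),
                                     seed = cfg$design@seed)
  } else stages$simulate_competition <- "skipped"

  ## stage 2: fitness inference
  if (needs(p[c("fitness", "mean_fitness", "diagnostics")])) {
    counts <- readBarcodeCounts(p$counts, p$design)
    metadata(counts)$design <- cfg$design
    masked <- removeOutlierBarcodes(counts)
    agg <- aggregateCounts(masked)
    fit <- fitFitness(agg, config = cfg$model)
    fit <- classify(fit, cfg$intervalMass)
    writeFitnessTable(fit, p$fitness)
    writeTsv(meanFitness(fit), p$mean_fitness)
    diag <- lapply(fit@diagnostics, function(d)
      d[setdiff(names(d), "phi_samples")])
    jsonlite::write_json(diag, p$diagnostics, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
    stages$fit_fitness <- "ran"
    upstream_ran <- TRUE
    log$fit_fitness <- list(
      edits_in = nrow(agg),
      removed_barcodes = nrow(removedBarcodes(masked)),
      converged = all(vapply(fit@diagnostics, `[[`, TRUE, "converged")))
  } else stages$fit_fitness <- "skipped"

  ## stage 3: population simulation + per-variant statistics
  if (needs(p[c("vcf", "metadata", "tree", "variant_stats")])) {
    panel <- simulatePopulation(cfg$popConfig)
    panel <- addSingletonCounts(panel)
    writeGenotypeVcf(panel, p$vcf)
    writeStrainMetadata(panel, p$metadata)
    writeStrainTree(strainTree(panel), p$tree)
    writeTsv(presenceStats(panel), p$variant_stats)
    stages$simulate_population <- "ran"
    upstream_ran <- TRUE
    log$simulate_population <- list(strains = ncol(panel),
                                    variants = nrow(panel),
                                    seed = cfg$popConfig@seed)
  } else stages$simulate_population <- "skipped"

  ## reload shared inputs for downstream stages
  fitness <- readFitnessTable(p$fitness)
  v <- readGenotypeVcf(p$vcf)
  meta <- readStrainMetadata(p$metadata)
  tree <- readStrainTree(p$tree)
  panel <- makeGenotypePanel(v$gt, meta, tree)
  fake_fit <- new("FitnessFit", hyperfitness = fitness,
                  replicateFitness = data.frame(),
                  meanFitness = data.frame(),
                  intervalMass = cfg$intervalMass, engine = "variational",
                  diagnostics = list(), config = list())
  fs <- focalSets(fake_fit)
  fs <- fs[!fs$neutral_anchor, ]
  focal_edits <- fs$edit_id[fs[[cfg$focalSet]]]
  neutral_edits <- fs$edit_id[fs$n_conditions_non_neutral == 0]
  e2v <- editToVariant(fs$edit_id, panel)
  present <- rownames(panel)[rowSums(assay(panel, "GT") > 0) > 0]
  focal_v <- intersect(unname(e2v[focal_edits]), present)
  cand_v <- intersect(unname(e2v[neutral_edits]), present)

  ## stage 4: matching
  if (needs(p["matched_pairs"])) {
    mc <- matchControls(focal_v, cand_v, panel, seed = cfg$seed + 3L)
    writeTsv(mc$pairs, p$matched_pairs)
    stages$match_controls <- "ran"
    upstream_ran <- TRUE
    log$match_controls <- list(focal = length(focal_v),
                               matched = nrow(mc$pairs),
                               unmatched = length(mc$unmatched))
  } else stages$match_controls <- "skipped"
  pairs <- readTsv(p$matched_pairs)

  ## stage 5: co-occurrence
  if (needs(p["cooccurrence"])) {
    res <- if (nrow(pairs) >= 2)
      cooccurrenceTest(pairs$focal, pairs$control, panel,
                       nBoot = cfg$nBoot, seed = cfg$seed + 4L)
    else list(error = "fewer than 2 matched pairs")
    jsonlite::write_json(res, p$cooccurrence, auto_unbox = TRUE, digits = NA)
    stages$cooccurrence <- "ran"
    upstream_ran <- TRUE
  } else stages$cooccurrence <- "skipped"

  ## stage 6: enrichment + sweep + mixed model
  if (needs(p[c("enrichment", "sweep", "mixed_model")])) {
    er <- suppressWarnings(perStrainEnrichment(pairs$focal, pairs, panel))
    writeTsv(er, p$enrichment)
    sw <- frequencySweep(pairs$focal, pairs, panel)
    writeTsv(sw$sweep, p$sweep)
    mm <- tryCatch(ecologyMixedModel(er), error = function(e)
      list(error = conditionMessage(e)))
    jsonlite::write_json(mm, p$mixed_model, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
    stages$enrichment <- "ran"
    upstream_ran <- TRUE
  } else stages$enrichment <- "skipped"

  ## stage 7: summary + manifest
  if (needs(p["summary"])) {
    summ <- summarizeScreen(fitness, panel = panel, e2v = e2v,
                            commonStrainCount = cfg$commonStrainCount,
                            focalConditionCount = cfg$focalConditionCount,
                            strongEffectMultiplier = cfg$strongEffectMultiplier)
    writeTsv(summ, p$summary)
    stages$summary <- "ran"
  } else stages$summary <- "skipped"

  inputs <- unlist(p[c("counts", "design", "vcf", "metadata", "tree")])
  manifest <- list(
    package_version = as.character(utils::packageVersion("screenfit")),
    config_hash = as.character(hash),
    seed = cfg$seed,
    stage_seeds = list(competition = cfg$design@seed,
                       population = cfg$popConfig@seed,
                       model = cfg$model$seed,
                       matching = cfg$seed + 3L,
                       cooccurrence = cfg$seed + 4L),
    stages = stages,
    outputs = lapply(p[setdiff(names(p), "manifest")], basename),
    checksums = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    log = log)
  jsonlite::write_json(manifest, p$manifest, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(manifest)
}

#' Summary tables of a classified screen
#'
#' Deterministic aggregation of the fitness table: neutral / beneficial /
#' deleterious counts per condition, focal-set sizes, and — when a genotype
#' panel is supplied — the share of focal variants that are common (carried
#' by more than `commonStrainCount` strains) and the share of common focal
#' variants with strong effects (|fitness| above `strongEffectMultiplier`
#' times the mean |fitness| over all non-anchor measurements).
#'
#' @param fitness fitness table (data.frame, as written by
#'   [writeFitnessTable()]) or a [FitnessFit-class].
#' @param panel optional [GenotypePanel-class].
#' @param e2v optional named map edit_id -> variant_id (default: by index).
#' @param commonStrainCount,focalConditionCount,strongEffectMultiplier
#'   analysis thresholds.
#' @return data.frame of (metric, condition, value) rows.
#' @export
summarizeScreen <- function(fitness, panel = NULL, e2v = NULL,
                            commonStrainCount = 10L,
                            focalConditionCount = 2L,
                            strongEffectMultiplier = 2) {
  if (is(fitness, "FitnessFit")) fitness <- hyperfitness(fitness)
  hf <- fitness[!fitness$neutral_anchor, , drop = FALSE]
  rows <- list()
  add <- function(metric, condition, value)
    rows[[length(rows) + 1L]] <<- data.frame(
      metric = metric, condition = condition, value = value,
      stringsAsFactors = FALSE)
  for (cond in unique(hf$condition)) {
    sub <- hf[hf$condition == cond, ]
    for (cl in c("neutral", "beneficial", "deleterious"))
      add(paste0("n_", cl), cond, sum(sub$classification == cl))
  }
  byEdit <- split(hf, hf$edit_id)
  nn_cond <- vapply(byEdit, function(d)
    sum(d$classification != "neutral"), integer(1))
  add("n_edits", "all", length(byEdit))
  add("n_non_neutral_any", "all", sum(nn_cond >= 1L))
  add("n_focal_set", "all", sum(nn_cond >= focalConditionCount))
  if (!is.null(panel)) {
    edit_ids <- names(byEdit)
    if (is.null(e2v)) e2v <- editToVariant(edit_ids, panel)
    ps <- presenceStats(panel)
    nstr <- stats::setNames(ps$n_strains, ps$variant_id)[e2v[edit_ids]]
    focal <- nn_cond >= focalConditionCount & !is.na(nstr)
    common <- focal & nstr > commonStrainCount
    add("n_focal_common", "all", sum(common))
    add("fraction_focal_common", "all",
        if (any(focal)) sum(common) / sum(focal) else NA_real_)
    maxabs <- vapply(byEdit, function(d) max(abs(d$mean)), numeric(1))
    thr <- strongEffectMultiplier * mean(abs(hf$mean))
    add("fraction_common_strong", "all",
        if (any(common)) mean(maxabs[common] > thr) else NA_real_)
  }
  do.call(rbind, rows)
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Recognised top-level keys: `outdir`, `seed`, `interval_mass`, `n_boot`,
#' `common_strain_count`, `focal_condition_count`,
#' `strong_effect_multiplier`, `focal_set`, plus nested `design`,
#' `population` and `model` blocks whose entries are passed to
#' [competitionDesign()], [populationSimConfig()] and [modelConfig()].
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return a [pipelineConfig()].
#' @export
readPipelineConfig <- function(path) {
  x <- if (tolower(tools::file_ext(path)) == "json")
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  design <- do.call(competitionDesign, as.list(x$design %||% list()))
  popcfg <- do.call(populationSimConfig, as.list(x$population %||% list()))
  model <- do.call(modelConfig, as.list(x$model %||% list()))
  pipelineConfig(
    outdir = x$outdir %||% tempfile("screenfit_run_"),
    design = design, popConfig = popcfg, model = model,
    intervalMass = x$interval_mass %||% 0.95,
    nBoot = x$n_boot %||% 1000L,
    commonStrainCount = x$common_strain_count %||% 10L,
    focalConditionCount = x$focal_condition_count %||% 2L,
    strongEffectMultiplier = x$strong_effect_multiplier %||% 2,
    focalSet = x$focal_set %||% "beneficial_any",
    seed = x$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
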