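#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   colData rowData<- colData<- assays<- assay<-
NULL

#' BarcodeExperiment: barcode read counts from a pooled competition
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding one
#' `counts` assay of sequencing reads with rows = barcodes and columns =
#' samples (one per replicate x condition x timepoint). `rowData` carries
#' `barcode_id`, `edit_id` and the logical `neutral` flag marking
#' non-editing anchor barcodes; `colData` carries `replicate`, `condition`
#' and the 0-based `timepoint` index.
#'
#' Counts may be `NA` for missing timepoints (e.g. a lost sample) or for
#' barcode/stream combinations masked by [removeOutlierBarcodes()].
#'
#' @export
setClass("BarcodeExperiment", contains = "SummarizedExperiment")

setValidity("BarcodeExperiment", function(object) {
  msg <- character()
  rd <- rowData(object)
  cd <- colData(object)
  need_rd <- c("barcode_id", "edit_id", "neutral")
  need_cd <- c("replicate", "condition", "timepoint")
  if (!all(need_rd %in% colnames(rd)))
    return(paste("rowData must contain", paste(need_rd, collapse = ", ")))
  if (!all(need_cd %in% colnames(cd)))
    return(paste("colData must contain", paste(need_cd, collapse = ", ")))
  if (!"counts" %in% names(assays(object)))
    return("assay 'counts' is required")
  if (anyDuplicated(rd$barcode_id))
    msg <- c(msg, "barcode_id values must be unique (one edit per barcode)")
  if (!any(rd$neutral))
    msg <- c(msg, "at least one neutral (non-editing) barcode is required")
  cnt <- assay(object, "counts")
  if (any(cnt < 0, na.rm = TRUE))
    msg <- c(msg, "counts must be non-negative")
  ## timepoints must form a contiguous 0..T-1 index in every stream
  stream <- paste(cd$replicate, cd$condition, sep = "\r")
  for (s in unique(stream)) {
    tp <- sort(unique(cd$timepoint[stream == s]))
    if (!identical(as.integer(tp), seq_along(tp) - 1L)) {
      msg <- c(msg, sprintf("timepoints of stream '%s' are not contiguous 0..T-1",
                            gsub("\r", "/", s)))
      break
    }
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' GenotypePanel: variant-by-strain genotype matrix with strain metadata
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass with a single
#' `GT` assay coded 0 (absent), 1 (heterozygous) or 2 (homozygous
#' alternate / present in a haploid). Rows are variants, columns are
#' strains. `colData` holds the strain metadata (`clade`, `clade_class`,
#' `ecology_class`, `ploidy` and, once computed, `n_singletons`); an
#' optional rooted `phylo` tree over the strains lives in
#' `metadata(x)$tree`.
#'
#' @export
setClass("GenotypePanel", contains = "SummarizedExperiment")

setValidity("GenotypePanel", function(object) {
  msg <- character()
  if (!"GT" %in% names(assays(object)))
    return("assay 'GT' is required")
  gt <- assay(object, "GT")
  ok <- gt %in% c(0L, 1L, 2L) | is.na(gt)
  if (!all(ok))
    msg <- c(msg, "GT values must be 0 (absent), 1 (het) or 2 (hom/present)")
  cd <- colData(object)
  need <- c("clade", "clade_class", "ecology_class", "ploidy")
  if (!all(need %in% colnames(cd)))
    return(paste("colData must contain", paste(need, collapse = ", ")))
  if (!all(cd$clade_class %in% c("domesticated", "wild", "other")))
    msg <- c(msg, "clade_class must be domesticated/wild/other")
  if (!all(cd$ecology_class %in% c("industrial", "natural", "other")))
    msg <- c(msg, "ecology_class must be industrial/natural/other")
  hap <- which(cd$ploidy == 1L)
  if (length(hap) && any(gt[, hap, drop = FALSE] == 1L, na.rm = TRUE))
    msg <- c(msg, "haploid strains cannot carry heterozygous calls")
  tree <- metadata(object)$tree
  if (!is.null(tree)) {
    if (!inherits(tree, "phylo"))
      msg <- c(msg, "metadata tree must be a 'phylo' object")
    else if (!setequal(tree$tip.label, colnames(object)))
      msg <- c(msg, "tree tips must match strain names")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Design of a serial-dilution pooled competition experiment
#'
#' Parameters of the generative model used by [simulateCompetition()].
#' Defaults describe the canonical desk-scale design: 300 edits with 10
#' barcodes each, 30 single-barcode neutral anchors, 3 replicates, 7
#' samplings spaced tau = 4.3 generations apart, a 1e7-cell transfer
#' bottleneck and 5e6 reads per sequenced timepoint.
#'
#' @slot n_edits number of editing edits.
#' @slot barcodes_per_edit barcodes per editing edit.
#' @slot n_neutral_barcodes non-editing anchor barcodes (one per anchor
#'   "edit").
#' @slot n_replicates technical replicates per condition.
#' @slot conditions condition labels.
#' @slot n_timepoints sequenced timepoints (initial sample plus transfers).
#' @slot tau generations between consecutive samplings.
#' @slot bottleneck_cells cells transferred at each dilution.
#' @slot reads_per_timepoint sequencing depth per sample.
#' @slot outlier_rate probability that an editing edit harbours one
#'   hitchhiker barcode.
#' @slot outlier_effect extra per-generation fitness of a hitchhiker.
#' @slot p0 probability that a drawn true selection coefficient is exactly 0.
#' @slot s_range interval of the uniform component of drawn coefficients.
#' @slot seed integer seed.
#' @export
setClass("CompetitionDesign", representation(
  n_edits = "integer", barcodes_per_edit = "integer",
  n_neutral_barcodes = "integer", n_replicates = "integer",
  conditions = "character", n_timepoints = "integer", tau = "numeric",
  bottleneck_cells = "numeric", reads_per_timepoint = "numeric",
  outlier_rate = "numeric", outlier_effect = "numeric",
  p0 = "numeric", s_range = "numeric", seed = "integer"))

setValidity("CompetitionDesign", function(object) {
  msg <- character()
  cnt <- c(object@n_edits, object@barcodes_per_edit, object@n_neutral_barcodes,
           object@n_replicates, object@n_timepoints)
  if (any(cnt < 1L)) msg <- c(msg, "all counts must be >= 1")
  if (object@n_timepoints < 3L) msg <- c(msg, "n_timepoints must be >= 3")
  if (object@tau <= 0) msg <- c(msg, "tau must be > 0")
  if (object@outlier_rate < 0 || object@outlier_rate > 1)
    msg <- c(msg, "outlier_rate must lie in [0, 1]")
  if (object@bottleneck_cells < 1 || object@reads_per_timepoint < 1)
    msg <- c(msg, "bottleneck_cells and reads_per_timepoint must be >= 1")
  if (object@p0 < 0 || object@p0 > 1) msg <- c(msg, "p0 must lie in [0, 1]")
  if (length(object@s_range) != 2L || diff(object@s_range) < 0)
    msg <- c(msg, "s_range must be an increasing length-2 interval")
  if (!length(object@conditions)) msg <- c(msg, "at least one condition")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Ground truth attached to a simulated competition
#'
#' @slot trueS data.frame (edit_id, condition, s) of true per-generation
#'   selection coefficients; neutral anchors are exactly 0.
#' @slot outlierBarcodes barcode ids carrying an extra hitchhiker effect.
#' @slot trueMeanFitness data.frame (condition, replicate, t, sbar) of the
#'   realized population mean fitness governing each transition t -> t+1.
#' @slot seed integer seed used by the simulator.
#' @export
setClass("SimulationTruth", representation(
  trueS = "data.frame", outlierBarcodes = "character",
  trueMeanFitness = "data.frame", seed = "integer"))

setValidity("SimulationTruth", function(object) {
  if (!all(c("edit_id", "condition", "s") %in% colnames(object@trueS)))
    return("trueS needs columns edit_id, condition, s")
  TRUE
})

#' Configuration of the clade-structured population simulator
#'
#' @slot n_strains number of strains (tips of the simulated tree).
#' @slot n_variants number of variants placed on the tree.
#' @slot clade_spec data.frame (clade, clade_class, size); sizes sum to
#'   `n_strains`.
#' @slot ecology_probs 3x3 matrix of P(ecology | clade_class); rows
#'   domesticated/wild/other, columns industrial/natural/other.
#' @slot planted_beneficial number of variants biased toward
#'   domesticated-clade branches.
#' @slot bias_strength probability in [0, 1] that a planted variant is
#'   forced onto a domesticated-clade branch (1 = always).
#' @slot singleton_skew probability that a variant is placed uniformly on a
#'   terminal branch rather than length-weighted on any branch; controls the
#'   singleton excess of the site-frequency spectrum.
#' @slot ploidy_fraction_haploid proportion of haploid strains.
#' @slot het_prob probability that a diploid carrier is heterozygous.
#' @slot seed integer seed.
#' @export
setClass("PopulationSimConfig", representation(
  n_strains = "integer", n_variants = "integer", clade_spec = "data.frame",
  ecology_probs = "matrix", planted_beneficial = "integer",
  bias_strength = "numeric", singleton_skew = "numeric",
  ploidy_fraction_haploid = "numeric", het_prob = "numeric", seed = "integer"))

setValidity("PopulationSimConfig", function(object) {
  msg <- character()
  cs <- object@clade_spec
  if (!all(c("clade", "clade_class", "size") %in% colnames(cs)))
    return("clade_spec needs columns clade, clade_class, size")
  if (sum(cs$size) != object@n_strains)
    msg <- c(msg, "clade sizes must sum to n_strains")
  if (!all(cs$clade_class %in% c("domesticated", "wild", "other")))
    msg <- c(msg, "clade_class must be domesticated/wild/other")
  if (any(cs$size < 2L))
    msg <- c(msg, "every clade needs >= 2 strains (a clade is a subtree)")
  if (object@bias_strength < 0 || object@bias_strength > 1)
    msg <- c(msg, "bias_strength must lie in [0, 1]")
  if (object@singleton_skew < 0 || object@singleton_skew > 1)
    msg <- c(msg, "singleton_skew must lie in [0, 1]")
  if (object@planted_beneficial > object@n_variants)
    msg <- c(msg, "planted_beneficial cannot exceed n_variants")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Posterior fitness estimates for a pooled screen
#'
#' Returned by [fitFitness()]. The per-edit, per-condition hyperfitness
#' summaries live in `hyperfitness`; per-replicate fitness summaries in
#' `replicateFitness`; the population mean-fitness series in `meanFitness`;
#' engine diagnostics (convergence flag, objective trace or split-chain
#' statistics) in `diagnostics`.
#'
#' @slot hyperfitness data.frame: edit_id, condition, mean, sd, lower,
#'   upper, classification, neutral_anchor.
#' @slot replicateFitness data.frame: edit_id, condition, replicate, mean, sd.
#' @slot meanFitness data.frame: condition, replicate, t, mean, sd.
#' @slot intervalMass central credible mass used for classification.
#' @slot engine "variational" or "mcmc".
#' @slot diagnostics list of per-condition diagnostics.
#' @slot config list of model configuration used.
#' @export
setClass("FitnessFit", representation(
  hyperfitness = "data.frame", replicateFitness = "data.frame",
  meanFitness = "data.frame", intervalMass = "numeric",
  engine = "character", diagnostics = "list", config = "list"))

setMethod("show", "BarcodeExperiment", function(object) {
  cd <- colData(object)
  cat("BarcodeExperiment:", nrow(object), "barcodes (",
      length(unique(rowData(object)$edit_id)), "edits,",
      sum(rowData(object)$neutral), "neutral anchors )\n")
  cat("  conditions:", paste(unique(cd$condition), collapse = ", "),
      "| replicates:", length(unique(cd$replicate)),
      "| timepoints:", length(unique(cd$timepoint)), "\n")
  rb <- metadata(object)$removed_barcodes
  if (!is.null(rb) && nrow(rb))
    cat("  outlier-masked barcode/stream pairs:", nrow(rb), "\n")
})

setMethod("show", "GenotypePanel", function(object) {
  cat("GenotypePanel:", nrow(object), "variants x", ncol(object), "strains\n")
  cat("  clade classes:",
      paste(names(table(colData(object)$clade_class)), collapse = "/"),
      if (!is.null(metadata(object)$tree)) "| rooted tree attached" else "",
      "\n")
})

setMethod("show", "FitnessFit", function(object) {
  hf <- object@hyperfitness[!object@hyperfitness$neutral_anchor, ]
  cat("FitnessFit (", object@engine, " engine, ",
      format(object@intervalMass), " credible mass)\n", sep = "")
  tab <- table(hf$condition, hf$classification)
  print(tab)
  invisible(object)
})

setMethod("show", "SimulationTruth", function(object) {
  cat("SimulationTruth:", nrow(object@trueS), "edit/condition coefficients,",
      length(object@outlierBarcodes), "outlier barcodes, seed",
      object@seed, "\n")
})

setMethod("show", "CompetitionDesign", function(object) {
  cat("CompetitionDesign:", object@n_edits, "edits x",
      object@barcodes_per_edit, "barcodes +", object@n_neutral_barcodes,
      "neutral anchors;", object@n_replicates, "replicates x",
      length(object@conditions), "conditions x", object@n_timepoints,
      "timepoints (tau =", object@tau, ")\n")
})
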