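#' Create a competition design
#'
#' Defaults are the canonical desk-scale study conditions: 300 editing
#' edits with 10 barcodes each, 30 single-barcode non-editing neutral
#' anchors, 3 technical replicates, 7 sequenced timepoints spaced 4.3
#' generations apart, a 1e7-cell transfer bottleneck and 5e6 reads per
#' timepoint. True coefficients, when not supplied, are drawn from a
#' point mass at zero (probability `p0`) mixed with Uniform(`s_range`).
#'
#' @param n_edits,barcodes_per_edit,n_neutral_barcodes,n_replicates counts.
#' @param conditions condition labels; the four-condition layout of the
#'   serial-dilution screen is `c("1D","2D","3D","5D")`.
#' @param n_timepoints sequenced samplings (initial pool plus transfers).
#' @param tau generations between consecutive samplings.
#' @param bottleneck_cells cells transferred at each dilution (`Inf` for
#'   the drift-free limit).
#' @param reads_per_timepoint sequencing depth (`Inf` for the noise-free
#'   limit, in which case "reads" are exact frequencies).
#' @param outlier_rate,outlier_effect hitchhiker-barcode model: each
#'   editing edit independently harbours one hitchhiker barcode with
#'   probability `outlier_rate`, whose lineage gains `outlier_effect`
#'   per-generation fitness.
#' @param p0,s_range mixture used to draw true selection coefficients.
#' @param seed integer seed.
#' @return A [CompetitionDesign-class].
#' @export
competitionDesign <- function(n_edits = 300L, barcodes_per_edit = 10L,
                              n_neutral_barcodes = 30L, n_replicates = 3L,
                              conditions = "1D", n_timepoints = 7L,
                              tau = 4.3, bottleneck_cells = 1e7,
                              reads_per_timepoint = 5e6,
                              outlier_rate = 0, outlier_effect = 0.1,
                              p0 = 0.2, s_range = c(-0.15, 0.15),
                              seed = 1L) {
  new("CompetitionDesign",
      n_edits = as.integer(n_edits),
      barcodes_per_edit = as.integer(barcodes_per_edit),
      n_neutral_barcodes = as.integer(n_neutral_barcodes),
      n_replicates = as.integer(n_replicates),
      conditions = as.character(conditions),
      n_timepoints = as.integer(n_timepoints),
      tau = as.numeric(tau),
      bottleneck_cells = as.numeric(bottleneck_cells),
      reads_per_timepoint = as.numeric(reads_per_timepoint),
      outlier_rate = as.numeric(outlier_rate),
      outlier_effect = as.numeric(outlier_effect),
      p0 = as.numeric(p0), s_range = as.numeric(s_range),
      seed = as.integer(seed))
}

#' Deterministic frequency propagation
#'
#' Exact multiplicative dynamics of relative frequencies under constant
#' per-generation selection: each sampling interval of `tau` generations
#' updates `f` to `f * exp(s * tau)` renormalized to sum to one, which for
#' two genotypes reduces to the logistic closed form. The realized
#' population mean fitness at the start of each interval, `sum(f * s)`, is
#' returned alongside.
#'
#' @param f0 initial frequencies (will be normalized).
#' @param s per-lineage selection coefficients (per generation).
#' @param tau generations per interval.
#' @param n_timepoints number of sampled states (including the initial one).
#' @return list with `freq` (lineages x timepoints matrix, columns summing
#'   to 1) and `mean_fitness` (length `n_timepoints - 1`).
#' @export
propagateFrequencies <- function(f0, s, tau, n_timepoints) {
  stopifnot(length(f0) == length(s), all(f0 >= 0), sum(f0) > 0, tau > 0,
            n_timepoints >= 1)
  f <- f0 / sum(f0)
  freq <- matrix(NA_real_, nrow = length(f), ncol = n_timepoints)
  freq[, 1] <- f
  sbar <- numeric(max(n_timepoints - 1L, 0L))
  g <- exp(s * tau)
  for (t in seq_len(n_timepoints - 1L)) {
    sbar[t] <- sum(f * s)
    f <- f * g
    tot <- sum(f)
    if (!is.finite(tot) || tot <= 0)
      stop("all lineages extinct at cycle ", t)
    f <- f / tot
    freq[, t + 1L] <- f
  }
  list(freq = freq, mean_fitness = sbar)
}

## Draw per-edit true selection coefficients from the design's mixture.
drawTrueS <- function(design) {
  edits <- sprintf("edit_%04d", seq_len(design@n_edits))
  out <- expand.grid(edit_id = edits, condition = design@conditions,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(out)
  zero <- stats::runif(n) < design@p0
  s <- stats::runif(n, design@s_range[1], design@s_range[2])
  s[zero] <- 0
  out$s <- s
  out
}

## Normalize a user-supplied truth (named vector or data.frame) to the
## long (edit_id, condition, s) layout.
normalizeTrueS <- function(trueS, design) {
  edits <- sprintf("edit_%04d", seq_len(design@n_edits))
  if (is.data.frame(trueS)) {
    stopifnot(all(c("edit_id", "condition", "s") %in% colnames(trueS)))
    return(trueS)
  }
  if (is.null(names(trueS))) {
    stopifnot(length(trueS) == design@n_edits)
    names(trueS) <- edits
  }
  out <- expand.grid(edit_id = names(trueS), condition = design@conditions,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$s <- trueS[out$edit_id]
  rownames(out) <- NULL
  out
}

#' Simulate a serial-dilution pooled competition
#'
#' Generative model matching the fitness-inference assumptions: within each
#' replicate/condition stream, lineage frequencies are propagated
#' deterministically over `tau` generations per cycle
#' ([propagateFrequencies()]), then passed through a multinomial transfer
#' bottleneck of `bottleneck_cells`, and independently through a multinomial
#' sequencing draw of `reads_per_timepoint` reads at every sampled
#' timepoint. Barcodes of the same edit share its selection coefficient,
#' except hitchhiker outlier barcodes which gain `outlier_effect`. Neutral
#' anchors are single-barcode edits with s = 0 exactly.
#'
#' One RNG stream is used per (replicate, condition), so adding replicates
#' or conditions does not perturb existing ones.
#'
#' @param design a [CompetitionDesign-class].
#' @param trueS optional truth: either a data.frame (edit_id, condition, s)
#'   or a numeric vector of length `n_edits` (recycled across conditions).
#'   If omitted, coefficients are drawn from the design's mixture.
#' @param outlierSeed separate seed for hitchhiker selection (defaults to
#'   the design seed), used by [injectOutliers()].
#' @return list with `counts` (a [BarcodeExperiment-class], design stored in
#'   its metadata) and `truth` (a [SimulationTruth-class]).
#' @export
simulateCompetition <- function(design, trueS = NULL, outlierSeed = NULL) {
  stopifnot(is(design, "CompetitionDesign"))
  validObject(design)
  set.seed(design@seed)
  truth_s <- if (is.null(trueS)) drawTrueS(design)
             else normalizeTrueS(trueS, design)

  edits <- sprintf("edit_%04d", seq_len(design@n_edits))
  neutral <- sprintf("neutral_%03d", seq_len(design@n_neutral_barcodes))
  ## neutral anchors enter the truth with s = 0 in every condition
  truth_s <- rbind(truth_s,
                   expand.grid(edit_id = neutral,
                               condition = design@conditions, s = 0,
                               KEEP.OUT.ATTRS = FALSE,
                               stringsAsFactors = FALSE))

  bc_edit <- c(rep(edits, each = design@barcodes_per_edit), neutral)
  bc_id <- c(sprintf("%s.bc%02d", rep(edits, each = design@barcodes_per_edit),
                     seq_len(design@barcodes_per_edit)),
             sprintf("%s.bc01", neutral))
  B <- length(bc_id)

  n_streams <- design@n_replicates * length(design@conditions)
  stream_seeds <- sample.int(.Machine$integer.max - 1L, n_streams)

  ## hitchhiker selection: one barcode per affected editing edit
  set.seed(if (is.null(outlierSeed)) design@seed else as.integer(outlierSeed))
  hit_edit <- edits[stats::runif(design@n_edits) < design@outlier_rate]
  out_bc <- character()
  if (length(hit_edit) && design@barcodes_per_edit >= 1L) {
    pick <- sample.int(design@barcodes_per_edit, length(hit_edit),
                       replace = TRUE)
    out_bc <- sprintf("%s.bc%02d", hit_edit, pick)
  }

  reps <- sprintf("R%d", seq_len(design@n_replicates))
  T <- design@n_timepoints
  long <- vector("list", n_streams)
  sbar_rows <- vector("list", n_streams)
  k <- 0L
  for (cond in design@conditions) {
    s_edit <- truth_s$s[truth_s$condition == cond]
    names(s_edit) <- truth_s$edit_id[truth_s$condition == cond]
    s_bc <- unname(s_edit[bc_edit])
    s_bc[match(out_bc, bc_id)] <- s_bc[match(out_bc, bc_id)] +
      design@outlier_effect
    for (rep_i in reps) {
      k <- k + 1L
      set.seed(stream_seeds[k])
      f <- rep(1 / B, B)
      reads <- matrix(NA_real_, nrow = B, ncol = T)
      sbar <- numeric(T - 1L)
      g <- exp(s_bc * design@tau)
      for (t in seq_len(T)) {
        reads[, t] <- if (is.finite(design@reads_per_timepoint))
          stats::rmultinom(1, design@reads_per_timepoint, f) else f
        if (t < T) {
          sbar[t] <- sum(f * s_bc)
          f <- f * g
          tot <- sum(f)
          if (!is.finite(tot) || tot <= 0)
            stop("all lineages extinct in ", rep_i, "/", cond,
                 " at cycle ", t)
          f <- f / tot
          if (is.finite(design@bottleneck_cells)) {
            cells <- stats::rmultinom(1, design@bottleneck_cells, f)[, 1]
            if (!any(cells > 0))
              stop("all lineages extinct in ", rep_i, "/", cond,
                   " at cycle ", t)
            f <- cells / sum(cells)
          }
        }
      }
      long[[k]] <- data.frame(
        barcode_id = rep(bc_id, times = T),
        edit_id = rep(bc_edit, times = T),
        replicate = rep_i, condition = cond,
        timepoint = rep(seq_len(T) - 1L, each = B),
        reads = as.vector(reads), stringsAsFactors = FALSE)
      sbar_rows[[k]] <- data.frame(condition = cond, replicate = rep_i,
                                   t = seq_len(T - 1L) - 1L, sbar = sbar,
                                   stringsAsFactors = FALSE)
    }
  }
  counts <- BarcodeExperiment(do.call(rbind, long), neutralEdits = neutral)
  metadata(counts)$design <- design
  truth <- new("SimulationTruth", trueS = truth_s,
               outlierBarcodes = out_bc,
               trueMeanFitness = do.call(rbind, sbar_rows),
               seed = design@seed)
  list(counts = counts, truth = truth)
}

#' Re-simulate a competition with hitchhiker outlier barcodes injected
#'
#' Selects, for each editing edit independently with probability `rate`,
#' one barcode whose lineage is re-simulated with its edit's selection
#' coefficient plus `effect`; the truth object is updated with the flagged
#' barcodes. With `rate = 0` the returned table is identical to the input
#' (same stream seeds and truth); with `effect = 0` the counts are
#' re-sampled but distributionally unchanged.
#'
#' @param x a [BarcodeExperiment-class] produced by [simulateCompetition()]
#'   (its design is taken from the metadata).
#' @param truth the matching [SimulationTruth-class].
#' @param rate probability in `[0, 1]` that an edit harbours a hitchhiker.
#' @param effect added per-generation fitness of a hitchhiker lineage.
#' @param seed seed for the hitchhiker selection (default: the truth seed).
#' @return list with updated `counts` and `truth`.
#' @export
injectOutliers <- function(x, truth, rate, effect, seed = NULL) {
  stopifnot(is(x, "BarcodeExperiment"), is(truth, "SimulationTruth"),
            rate >= 0, rate <= 1)
  design <- metadata(x)$design
  if (is.null(design))
    stop("injectOutliers needs a simulated BarcodeExperiment with its design")
  if (rate == 0) return(list(counts = x, truth = truth))
  design@outlier_rate <- as.numeric(rate)
  design@outlier_effect <- as.numeric(effect)
  edits <- unique(truth@trueS[!grepl("^neutral_", truth@trueS$edit_id),
                              c("edit_id", "condition", "s")])
  simulateCompetition(design, trueS = edits,
                      outlierSeed = if (is.null(seed)) truth@seed else seed)
}

#' Simulate a protein C-alpha trace
#'
#' Self-avoiding random walk in 3D with the realistic 3.8 Angstrom
#' consecutive C-alpha spacing; non-consecutive residues are kept at least
#' 3.8 Angstrom apart. A synthetic fixture for packing-density code.
#'
#' @param n_residues chain length.
#' @param seed integer seed.
#' @param spacing consecutive C-alpha distance in Angstrom.
#' @return data.frame (chain, residue, x, y, z).
#' @export
simulateStructure <- function(n_residues, seed = 1L, spacing = 3.8) {
  stopifnot(n_residues >= 1)
  set.seed(as.integer(seed))
  repeat {
    xyz <- matrix(0, nrow = n_residues, ncol = 3)
    ok <- TRUE
    for (i in seq_len(n_residues - 1L)) {
      placed <- FALSE
      for (try in seq_len(200L)) {
        u <- stats::rnorm(3)
        cand <- xyz[i, ] + spacing * u / sqrt(sum(u^2))
        if (i == 1L) { placed <- TRUE }
        else {
          prev <- xyz[seq_len(i - 1L), , drop = FALSE]
          d2 <- rowSums((prev - matrix(cand, nrow(prev), 3, byrow = TRUE))^2)
          placed <- all(d2 >= (spacing - 1e-9)^2)
        }
        if (placed) { xyz[i + 1L, ] <- cand; break }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) break
  }
  data.frame(chain = "A", residue = seq_len(n_residues),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
}
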