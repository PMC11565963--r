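#' Construct a BarcodeExperiment
#'
#' Builds the count container from a long table of reads, as produced by the
#' simulator or read from a counts TSV (see [readBarcodeCounts()]).
#'
#' @param counts data.frame with columns `barcode_id`, `edit_id`,
#'   `replicate`, `condition`, `timepoint` (0-based integer) and `reads`.
#' @param neutralEdits character vector of edit ids whose barcodes are
#'   non-editing neutral anchors.
#' @return A [BarcodeExperiment-class].
#' @examples
#' tab <- data.frame(
#'   barcode_id = rep(c("b1", "b2", "n1"), each = 3),
#'   edit_id    = rep(c("e1", "e1", "neutral_1"), each = 3),
#'   replicate  = "R1", condition = "1D", timepoint = rep(0:2, 3),
#'   reads      = c(10, 20, 40, 10, 20, 40, 10, 10, 10))
#' be <- BarcodeExperiment(tab, neutralEdits = "neutral_1")
#' @export
BarcodeExperiment <- function(counts, neutralEdits = character()) {
  need <- c("barcode_id", "edit_id", "replicate", "condition",
            "timepoint", "reads")
  if (!all(need %in% colnames(counts)))
    stop("counts must have columns ", paste(need, collapse = ", "))
  counts$barcode_id <- as.character(counts$barcode_id)
  counts$edit_id <- as.character(counts$edit_id)
  map <- unique(counts[, c("barcode_id", "edit_id")])
  if (anyDuplicated(map$barcode_id)) {
    bad <- map$barcode_id[duplicated(map$barcode_id)]
    stop("barcode(s) mapped to more than one edit: ",
         paste(unique(bad), collapse = ", "))
  }
  samp_key <- paste(counts$replicate, counts$condition, counts$timepoint,
                    sep = "\r")
  samples <- unique(data.frame(
    replicate = as.character(counts$replicate),
    condition = as.character(counts$condition),
    timepoint = as.integer(counts$timepoint),
    key = samp_key, stringsAsFactors = FALSE))
  samples <- samples[order(samples$condition, samples$replicate,
                           samples$timepoint), ]
  barcodes <- map$barcode_id
  mat <- matrix(NA_real_, nrow = length(barcodes), ncol = nrow(samples),
                dimnames = list(barcodes, NULL))
  ri <- match(counts$barcode_id, barcodes)
  ci <- match(samp_key, samples$key)
  mat[cbind(ri, ci)] <- counts$reads
  rd <- DataFrame(barcode_id = barcodes,
                  edit_id = map$edit_id,
                  neutral = map$edit_id %in% neutralEdits,
                  row.names = barcodes)
  cd <- DataFrame(replicate = samples$replicate,
                  condition = samples$condition,
                  timepoint = samples$timepoint)
  se <- SummarizedExperiment(assays = SimpleList(counts = mat),
                             rowData = rd, colData = cd)
  new("BarcodeExperiment", se)
}

#' Accessors for BarcodeExperiment
#'
#' `barcodeIds()`/`editIds()` return the per-row identifiers, `isNeutral()`
#' the per-row anchor flag, `neutralEdits()` the ids of neutral anchor
#' edits, and `removedBarcodes()` the log of barcode/stream pairs masked by
#' [removeOutlierBarcodes()] (NULL if removal has not run).
#'
#' @param x a [BarcodeExperiment-class].
#' @name BarcodeExperiment-accessors
NULL

#' @rdname BarcodeExperiment-accessors
#' @export
setMethod("barcodeIds", "BarcodeExperiment",
          function(x) rowData(x)$barcode_id)

#' @rdname BarcodeExperiment-accessors
#' @export
setMethod("editIds", "BarcodeExperiment",
          function(x) rowData(x)$edit_id)

#' @rdname BarcodeExperiment-accessors
#' @export
setMethod("isNeutral", "BarcodeExperiment",
          function(x) rowData(x)$neutral)

#' @rdname BarcodeExperiment-accessors
#' @export
setMethod("neutralEdits", "BarcodeExperiment",
          function(x) unique(rowData(x)$edit_id[rowData(x)$neutral]))

#' @rdname BarcodeExperiment-accessors
#' @export
setMethod("removedBarcodes", "BarcodeExperiment",
          function(x) metadata(x)$removed_barcodes)

#' Long-format view of a BarcodeExperiment
#'
#' @param x a [BarcodeExperiment-class].
#' @param dropNA drop rows whose reads are `NA` (missing or masked).
#' @return data.frame with columns barcode_id, edit_id, replicate,
#'   condition, timepoint, reads.
#' @export
asCountsTable <- function(x, dropNA = TRUE) {
  stopifnot(is(x, "BarcodeExperiment"))
  cd <- colData(x)
  rd <- rowData(x)
  mat <- assay(x, "counts")
  out <- data.frame(
    barcode_id = rep(rd$barcode_id, times = ncol(mat)),
    edit_id    = rep(rd$edit_id, times = ncol(mat)),
    replicate  = rep(cd$replicate, each = nrow(mat)),
    condition  = rep(cd$condition, each = nrow(mat)),
    timepoint  = rep(cd$timepoint, each = nrow(mat)),
    reads      = as.vector(mat),
    stringsAsFactors = FALSE)
  if (dropNA) out <- out[!is.na(out$reads), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Accessors for SimulationTruth ------------------------------------------

#' Accessors for SimulationTruth
#'
#' @param x a [SimulationTruth-class].
#' @name SimulationTruth-accessors
NULL

#' @rdname SimulationTruth-accessors
#' @export
setMethod("trueS", "SimulationTruth", function(x) x@trueS)

#' @rdname SimulationTruth-accessors
#' @export
setMethod("trueMeanFitness", "SimulationTruth", function(x) x@trueMeanFitness)

#' @rdname SimulationTruth-accessors
#' @export
setMethod("outlierBarcodes", "SimulationTruth", function(x) x@outlierBarcodes)

## Accessors for FitnessFit ------------------------------------------------

#' Accessors for FitnessFit
#'
#' @param x a [FitnessFit-class].
#' @name FitnessFit-accessors
NULL

#' @rdname FitnessFit-accessors
#' @export
setMethod("hyperfitness", "FitnessFit", function(x) x@hyperfitness)

#' @rdname FitnessFit-accessors
#' @export
setMethod("replicateFitness", "FitnessFit", function(x) x@replicateFitness)

#' @rdname FitnessFit-accessors
#' @export
setMethod("meanFitness", "FitnessFit", function(x) x@meanFitness)
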