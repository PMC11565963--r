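#' Remove the putative hitchhiker barcode of every edit
#'
#' Spontaneous mutants with strong positive fitness can dominate the reads
#' of one barcode lineage while leaving the edit's other barcodes
#' untouched. As a guard, for every editing edit with at least two
#' barcodes, the barcode with the highest total read count is discarded.
#' By default the rule is applied independently within each
#' replicate/condition stream (totals summed over that stream's
#' timepoints); with `perStream = FALSE` a single barcode per edit is
#' removed globally. Ties are broken toward the lexicographically smallest
#' barcode id. Neutral anchors and single-barcode edits are untouched.
#'
#' Removed barcode/stream pairs are masked as `NA` in the counts assay and
#' logged in `removedBarcodes()`.
#'
#' @param x a [BarcodeExperiment-class].
#' @param perStream apply the rule per replicate/condition stream (default)
#'   or once globally.
#' @return The masked [BarcodeExperiment-class].
#' @export
removeOutlierBarcodes <- function(x, perStream = TRUE) {
  stopifnot(is(x, "BarcodeExperiment"))
  mat <- assay(x, "counts")
  rd <- rowData(x)
  cd <- colData(x)
  editable <- !rd$neutral
  stream <- paste(cd$replicate, cd$condition, sep = "\r")
  streams <- if (perStream) unique(stream) else "global"
  log_rows <- list()
  for (s in streams) {
    cols <- if (perStream) which(stream == s) else seq_len(ncol(mat))
    tot <- rowSums(mat[, cols, drop = FALSE], na.rm = TRUE)
    for (e in unique(rd$edit_id[editable])) {
      idx <- which(rd$edit_id == e & editable)
      if (length(idx) < 2L) next
      present <- idx[!apply(is.na(mat[idx, cols, drop = FALSE]), 1, all)]
      if (length(present) < 2L) next
      m <- max(tot[present])
      drop <- present[tot[present] == m]
      drop <- drop[order(rd$barcode_id[drop])][1]
      mat[drop, cols] <- NA_real_
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        edit_id = e, barcode_id = rd$barcode_id[drop],
        replicate = if (perStream) cd$replicate[cols[1]] else NA_character_,
        condition = if (perStream) cd$condition[cols[1]] else NA_character_,
        total_reads = m, stringsAsFactors = FALSE)
    }
  }
  assays(x)$counts <- mat
  metadata(x)$removed_barcodes <-
    if (length(log_rows)) do.call(rbind, log_rows)
    else data.frame(edit_id = character(), barcode_id = character(),
                    replicate = character(), condition = character(),
                    total_reads = numeric())
  validObject(x)
  x
}

#' Aggregate barcode counts to edit-level counts
#'
#' Reads of an edit's retained barcodes are summed within each sample.
#' Samples whose entire column is missing (e.g. a lost timepoint) stay
#' `NA`; barcodes masked by [removeOutlierBarcodes()] are simply excluded
#' from the sum. Edits with zero reads at every observed timepoint are
#' retained and flagged in `rowData()$all_zero`.
#'
#' @param x a [BarcodeExperiment-class] (outlier removal already applied,
#'   or deliberately skipped).
#' @return A [SummarizedExperiment::SummarizedExperiment] with rows =
#'   edits, assay `counts`, rowData columns `edit_id`, `neutral`,
#'   `n_barcodes`, `all_zero`, and the original colData.
#' @export
aggregateCounts <- function(x) {
  stopifnot(is(x, "BarcodeExperiment"))
  mat <- assay(x, "counts")
  rd <- rowData(x)
  edits <- unique(rd$edit_id)
  grp <- factor(rd$edit_id, levels = edits)
  agg <- rowsum(ifelse(is.na(mat), 0, mat), grp, reorder = FALSE)
  ## a sample column that is NA for every barcode of an edit stays missing
  n_na <- rowsum((is.na(mat)) + 0, grp, reorder = FALSE)
  n_bc <- as.vector(table(grp)[edits])
  agg[n_na == n_bc] <- NA_real_
  all_zero <- apply(agg, 1, function(r) all(is.na(r) | r == 0))
  if (any(all_zero))
    warning(sum(all_zero), " edit(s) have zero reads at every timepoint: ",
            paste(utils::head(edits[all_zero], 5), collapse = ", "))
  rd2 <- DataFrame(edit_id = edits,
                   neutral = rd$neutral[match(edits, rd$edit_id)],
                   n_barcodes = n_bc, all_zero = all_zero,
                   row.names = edits)
  SummarizedExperiment(assays = SimpleList(counts = agg),
                       rowData = rd2, colData = colData(x),
                       metadata = as.list(metadata(x)))
}

#' Naive frequency trajectories
#'
#' The plug-in estimate f_t(j) = r_t(j) / sum_k r_t(k), computed per
#' sample with optional pseudocount stabilization of zero reads:
#' (r + pc) / sum(r + pc). Frequencies sum to one within every observed
#' sample.
#'
#' @param agg aggregated counts from [aggregateCounts()] (or a
#'   [BarcodeExperiment-class] for barcode-level frequencies).
#' @param pseudocount added to every read count before normalization.
#' @return The same object with an added `freq` assay.
#' @export
naiveFrequencies <- function(agg, pseudocount = 0) {
  stopifnot(is(agg, "SummarizedExperiment"), pseudocount >= 0)
  mat <- assay(agg, "counts") + pseudocount
  tot <- colSums(mat, na.rm = TRUE)
  obs <- colSums(!is.na(mat)) > 0
  bad <- which(obs & tot <= 0)
  if (length(bad)) {
    cd <- colData(agg)
    stop("all-zero timepoint(s): ",
         paste(sprintf("(%s, %s, t=%d)", cd$replicate[bad],
                       cd$condition[bad], cd$timepoint[bad]),
               collapse = ", "))
  }
  assays(agg)$freq <- sweep(mat, 2, tot, "/")
  agg
}
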