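## File formats: tab-separated with header, UTF-8, '.' for missing values;
## minimal GT-only VCF; rooted newick with branch lengths; truth/diagnostics
## as JSON.

writeTsv <- function(df, path) {
  df2 <- df
  for (j in seq_along(df2))
    if (is.numeric(df2[[j]]) || is.character(df2[[j]]))
      df2[[j]][is.na(df2[[j]])] <- if (is.character(df2[[j]])) "." else NA
  utils::write.table(df2, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".", fileEncoding = "UTF-8")
  invisible(path)
}

readTsv <- function(path, colClasses = NA) {
  utils::read.delim(path, sep = "\t", na.strings = ".",
                    stringsAsFactors = FALSE, colClasses = colClasses,
                    fileEncoding = "UTF-8")
}

#' Write / read a barcode counts table
#'
#' Long TSV with columns barcode_id, edit_id, replicate, condition,
#' timepoint, reads. The neutral-anchor flag travels in the companion
#' edit-design table ([writeEditDesign()]), or is inferred from edit ids
#' prefixed `neutral_` when no design table is given.
#'
#' @param x a [BarcodeExperiment-class].
#' @param path output TSV path.
#' @export
writeBarcodeCounts <- function(x, path) {
  writeTsv(asCountsTable(x, dropNA = TRUE), path)
}

#' @rdname writeBarcodeCounts
#' @param designPath optional edit-design TSV naming neutral edits.
#' @return `readBarcodeCounts()` returns a [BarcodeExperiment-class].
#' @export
readBarcodeCounts <- function(path, designPath = NULL) {
  tab <- readTsv(path)
  neutral <- if (!is.null(designPath)) {
    des <- readTsv(designPath)
    stopifnot(all(c("edit_id", "neutral") %in% colnames(des)))
    des$edit_id[as.logical(des$neutral)]
  } else unique(grep("^neutral_", tab$edit_id, value = TRUE))
  BarcodeExperiment(tab, neutralEdits = neutral)
}

#' Write the edit-design table
#'
#' @param x a [BarcodeExperiment-class].
#' @param path output TSV path.
#' @export
writeEditDesign <- function(x, path) {
  rd <- rowData(x)
  des <- unique(data.frame(edit_id = rd$edit_id, neutral = rd$neutral,
                           stringsAsFactors = FALSE))
  writeTsv(des[order(des$edit_id), ], path)
}

#' Write / read the fitness table
#'
#' @param fit a [FitnessFit-class] (writer) or TSV path (reader).
#' @param path output TSV path.
#' @export
writeFitnessTable <- function(fit, path) {
  stopifnot(is(fit, "FitnessFit"))
  writeTsv(hyperfitness(fit), path)
}

#' @rdname writeFitnessTable
#' @export
readFitnessTable <- function(path) {
  tab <- readTsv(path)
  tab$neutral_anchor <- as.logical(tab$neutral_anchor)
  tab
}

#' Write / read simulation truth as JSON
#'
#' @param truth a [SimulationTruth-class].
#' @param path JSON path.
#' @export
writeTruth <- function(truth, path) {
  jsonlite::write_json(
    list(true_s = truth@trueS, outlier_barcodes = truth@outlierBarcodes,
         true_mean_fitness = truth@trueMeanFitness, seed = truth@seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("SimulationTruth",
      trueS = as.data.frame(x$true_s),
      outlierBarcodes = as.character(unlist(x$outlier_barcodes)),
      trueMeanFitness = as.data.frame(x$true_mean_fitness),
      seed = as.integer(x$seed))
}

#' Write / read strain metadata
#'
#' @param panel a [GenotypePanel-class].
#' @param path TSV path.
#' @export
writeStrainMetadata <- function(panel, path) {
  cd <- as.data.frame(colData(panel))
  cd <- cbind(strain = rownames(cd), cd)
  rownames(cd) <- NULL
  writeTsv(cd, path)
}

#' @rdname writeStrainMetadata
#' @export
readStrainMetadata <- function(path) readTsv(path)

#' Write a minimal GT-only VCF
#'
#' One record per variant; diploid strains are written as 0/0, 0/1 or 1/1,
#' haploid strains as 0 or 1. (Plain-text VCF; readable by any VCF parser.)
#'
#' @param panel a [GenotypePanel-class].
#' @param path output `.vcf` path.
#' @export
writeGenotypeVcf <- function(panel, path) {
  gt <- assay(panel, "GT")
  ploidy <- colData(panel)$ploidy
  n <- ncol(gt)
  code <- function(g, hap) {
    if (hap) c(`0` = "0", `1` = ".", `2` = "1")[as.character(g)]
    else c(`0` = "0/0", `1` = "0/1", `2` = "1/1")[as.character(g)]
  }
  body <- vapply(seq_len(nrow(gt)), function(i) {
    cells <- vapply(seq_len(n), function(j)
      code(gt[i, j], ploidy[j] == 1L), character(1))
    paste(c("1", i, rownames(gt)[i], "A", "T", ".", "PASS", ".", "GT",
            cells), collapse = "\t")
  }, character(1))
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", colnames(gt)), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read genotypes from a GT-only VCF
#'
#' Parses GT fields: `0/0` (or `0|0`) -> 0, `0/1` -> 1, `1/1` -> 2;
#' haploid calls `0`/`1` -> 0/2.
#'
#' @param path `.vcf` path.
#' @return list: `gt` integer matrix (variants x strains) and `ploidy`
#'   integer vector inferred from the GT arity.
#' @export
readGenotypeVcf <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop("no #CHROM header line in ", path)
  cols <- strsplit(lines[hdr], "\t")[[1]]
  strains <- cols[-(1:9)]
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  gt <- matrix(NA_integer_, nrow = length(body), ncol = length(strains))
  ids <- character(length(body))
  ploidy <- rep(NA_integer_, length(strains))
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9 + length(strains))
      stop("VCF parse failure at line ", hdr + i, ": expected ",
           9 + length(strains), " fields, got ", length(f))
    if (f[9] != "GT") stop("line ", hdr + i, ": FORMAT must be GT")
    ids[i] <- f[3]
    calls <- f[-(1:9)]
    dip <- grepl("[/|]", calls)
    ploidy_i <- ifelse(dip, 2L, 1L)
    if (all(is.na(ploidy))) ploidy <- ploidy_i
    alt <- vapply(strsplit(calls, "[/|]"), function(a)
      sum(a == "1"), integer(1))
    g <- ifelse(dip, alt, ifelse(alt > 0L, 2L, 0L))
    g[calls %in% c(".", "./.", ".|.")] <- NA_integer_
    gt[i, ] <- g
  }
  rownames(gt) <- ids
  colnames(gt) <- strains
  list(gt = gt, ploidy = ploidy)
}

#' Assemble a GenotypePanel from its parts
#'
#' @param gt integer variant-by-strain matrix (0/1/2).
#' @param strainData data.frame with strain metadata (rownames or `strain`
#'   column matching `colnames(gt)`); needs clade, clade_class,
#'   ecology_class, ploidy.
#' @param tree optional rooted `phylo` over the strains.
#' @return A [GenotypePanel-class].
#' @export
makeGenotypePanel <- function(gt, strainData, tree = NULL) {
  if ("strain" %in% colnames(strainData)) {
    rownames(strainData) <- strainData$strain
    strainData$strain <- NULL
  }
  stopifnot(setequal(rownames(strainData), colnames(gt)))
  strainData <- strainData[colnames(gt), , drop = FALSE]
  se <- SummarizedExperiment(
    assays = SimpleList(GT = gt),
    rowData = DataFrame(variant_id = rownames(gt), row.names = rownames(gt)),
    colData = as(strainData, "DataFrame"))
  panel <- new("GenotypePanel", se)
  if (!is.null(tree)) metadata(panel)$tree <- tree
  panel
}

#' Write / read the strain tree (newick)
#'
#' @param tree a rooted `phylo`.
#' @param path `.nwk` path.
#' @export
writeStrainTree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname writeStrainTree
#' @export
readStrainTree <- function(path) ape::read.tree(path)
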