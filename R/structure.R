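#' Packing density from C-alpha coordinates
#'
#' For each residue, the number of other residues whose C-alpha lies within
#' `radius` Angstrom (inclusive) of its own — a contact-number measure of
#' how densely packed the residue is in the tertiary structure. Residues
#' with missing coordinates are excluded from both the counted and the
#' counting sets and reported, so they never bias neighbours downward.
#'
#' @param coords data.frame with columns `chain`, `residue`, `x`, `y`, `z`
#'   (one C-alpha per residue), e.g. from [simulateStructure()] or
#'   [readCaCoordinates()].
#' @param radius neighbour cutoff in Angstrom (default 10).
#' @return data.frame: chain, residue, packing_density; excluded residues
#'   are attached as the `"excluded"` attribute.
#' @export
packingDensity <- function(coords, radius = 10) {
  stopifnot(all(c("chain", "residue", "x", "y", "z") %in% colnames(coords)),
            radius > 0, nrow(coords) >= 1)
  key <- paste(coords$chain, coords$residue)
  if (anyDuplicated(key)) stop("one C-alpha per residue required")
  ok <- stats::complete.cases(coords[, c("x", "y", "z")])
  excluded <- coords[!ok, c("chain", "residue"), drop = FALSE]
  if (nrow(excluded))
    message(nrow(excluded), " residue(s) without C-alpha excluded")
  xyz <- as.matrix(coords[ok, c("x", "y", "z")])
  n <- nrow(xyz)
  counts <- if (n >= 2) {
    d <- as.matrix(stats::dist(xyz))
    as.integer(rowSums(d <= radius) - 1L)  # self always within radius
  } else integer(n)
  out <- data.frame(chain = coords$chain[ok], residue = coords$residue[ok],
                    packing_density = counts, stringsAsFactors = FALSE)
  attr(out, "excluded") <- excluded
  out
}

#' Read C-alpha coordinates from PDB or mmCIF
#'
#' Thin extraction layer over `bio3d`: keeps one C-alpha per residue.
#'
#' @param file path to a `.pdb` or `.cif` file.
#' @return data.frame: chain, residue, x, y, z.
#' @export
readCaCoordinates <- function(file) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("reading structure files requires the bio3d package")
  ext <- tolower(tools::file_ext(file))
  pdb <- if (ext == "cif") bio3d::read.cif(file) else bio3d::read.pdb(file)
  ca <- pdb$atom[pdb$atom$elety == "CA", , drop = FALSE]
  ca <- ca[!duplicated(paste(ca$chain, ca$resno)), , drop = FALSE]
  data.frame(chain = ca$chain, residue = ca$resno,
             x = ca$x, y = ca$y, z = ca$z, stringsAsFactors = FALSE)
}

#' Apply threshold flags to a variant annotation table
#'
#' Derives `sift_strong` (SIFT strictly below 0.05, the conventional
#' strong-impact cutoff) and `destabilizing` (ddG strictly above 2
#' kcal/mol). Missing scores yield `NA` flags, never `FALSE`.
#'
#' @param annot data.frame with (at least) numeric columns `sift` and
#'   `ddg`; other columns pass through.
#' @return the table with `sift_strong` and `destabilizing` added.
#' @export
annotateFlags <- function(annot) {
  stopifnot(all(c("sift", "ddg") %in% colnames(annot)))
  bad <- !is.na(annot$sift) & (annot$sift < 0 | annot$sift > 1)
  if (any(bad))
    stop("SIFT score(s) outside [0, 1] at row(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  annot$sift_strong <- annot$sift < 0.05
  annot$destabilizing <- annot$ddg > 2
  annot
}

#' Compare annotation properties between non-neutral and neutral variants
#'
#' For each numeric property, a Wilcoxon rank-sum test of non-neutral vs
#' neutral variants (protein-level properties restricted to missense
#' variants); for each logical flag, a Fisher's exact test with odds ratio.
#' Strata with fewer than 2 variants per class are skipped with a warning.
#'
#' @param annot annotation table with `variant_id`, `consequence`
#'   (missense/synonymous/other) and property columns.
#' @param nonNeutral character vector of non-neutral variant ids (or a
#'   logical vector along `annot`).
#' @param properties named list mapping property column -> "numeric" or
#'   "flag"; default: packing_density, rsa, sift, ddg numeric;
#'   sift_strong, destabilizing flags.
#' @param missenseOnly properties tested within missense variants only
#'   (default: the protein-level ones).
#' @return data.frame: property, test, n_non_neutral, n_neutral, estimate,
#'   p, skipped.
#' @export
propertyComparison <- function(annot, nonNeutral,
                               properties = NULL, missenseOnly = NULL) {
  if (is.null(properties))
    properties <- list(sift = "numeric", ddg = "numeric",
                       rsa = "numeric", packing_density = "numeric",
                       sift_strong = "flag", destabilizing = "flag")
  properties <- properties[names(properties) %in% colnames(annot)]
  if (is.null(missenseOnly))
    missenseOnly <- intersect(names(properties),
                              c("sift", "ddg", "rsa", "packing_density",
                                "sift_strong", "destabilizing"))
  nn <- if (is.logical(nonNeutral)) nonNeutral
        else annot$variant_id %in% nonNeutral
  out <- list()
  for (prop in names(properties)) {
    d <- annot
    keep <- nn
    if (prop %in% missenseOnly) {
      sel <- d$consequence == "missense"
      d <- d[sel, , drop = FALSE]
      keep <- nn[sel]
    }
    x <- d[[prop]][keep]
    y <- d[[prop]][!keep]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    skipped <- length(x) < 2L || length(y) < 2L
    if (skipped) {
      warning("property '", prop, "' skipped: empty stratum")
      out[[prop]] <- data.frame(property = prop, test = NA_character_,
                                n_non_neutral = length(x),
                                n_neutral = length(y), estimate = NA_real_,
                                p = NA_real_, skipped = TRUE)
      next
    }
    if (properties[[prop]] == "numeric") {
      wt <- stats::wilcox.test(x, y, exact = FALSE)
      est <- stats::median(x) - stats::median(y)
      test <- "wilcoxon"
      p <- wt$p.value
    } else {
      tab <- matrix(c(sum(x), sum(!x), sum(y), sum(!y)), 2, 2)
      ft <- stats::fisher.test(tab)
      est <- unname(ft$estimate)
      test <- "fisher"
      p <- ft$p.value
    }
    out[[prop]] <- data.frame(property = prop, test = test,
                              n_non_neutral = length(x),
                              n_neutral = length(y), estimate = est, p = p,
                              skipped = FALSE, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Map a coding variant position to its protein residue
#'
#' Converts a 1-based genomic position to a 1-based residue index via the
#' CDS coordinates of a gene model: residue = ceiling(cds_position / 3).
#' Positions outside the CDS return `NA` with a message.
#'
#' @param position 1-based genomic position(s).
#' @param geneModel list or one-row data.frame with `protein`, `cds_start`,
#'   `cds_end` and `strand` ("+" or "-").
#' @return data.frame: position, protein, residue (NA outside the CDS).
#' @export
mapVariantToResidue <- function(position, geneModel) {
  stopifnot(all(c("protein", "cds_start", "cds_end", "strand") %in%
                names(geneModel)))
  cds_pos <- if (geneModel$strand == "+")
    position - geneModel$cds_start + 1L
  else geneModel$cds_end - position + 1L
  len <- geneModel$cds_end - geneModel$cds_start + 1L
  outside <- cds_pos < 1L | cds_pos > len
  if (any(outside))
    message(sum(outside), " position(s) outside the CDS of ",
            geneModel$protein)
  residue <- ifelse(outside, NA_integer_, (cds_pos + 2L) %/% 3L)
  data.frame(position = position,
             protein = ifelse(outside, NA_character_, geneModel$protein),
             residue = as.integer(residue), stringsAsFactors = FALSE)
}
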