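#' Per-variant presence statistics
#'
#' Allele frequency is the carrier-strain fraction (the convention used by
#' all downstream matching and threshold rules); dosage-based frequency
#' (alt alleles / total alleles, respecting ploidy) is available via
#' `mode = "dosage"`. Heterozygous fraction is the share of carriers scored
#' het; haploid carriers count as non-het. Variants absent from every
#' strain are excluded and reported via a warning.
#'
#' @param panel a [GenotypePanel-class].
#' @param mode `"carrier"` (default) or `"dosage"` allele frequency.
#' @return data.frame: variant_id, n_strains, allele_frequency,
#'   is_singleton, het_fraction.
#' @export
presenceStats <- function(panel, mode = c("carrier", "dosage")) {
  mode <- match.arg(mode)
  stopifnot(is(panel, "GenotypePanel"))
  gt <- assay(panel, "GT")
  carriers <- gt > 0L
  n <- rowSums(carriers, na.rm = TRUE)
  absent <- n == 0L
  if (any(absent)) {
    warning(sum(absent), " variant(s) absent from all strains excluded: ",
            paste(utils::head(rownames(gt)[absent], 5), collapse = ", "))
    gt <- gt[!absent, , drop = FALSE]
    carriers <- carriers[!absent, , drop = FALSE]
    n <- n[!absent]
  }
  if (mode == "carrier") {
    af <- n / ncol(gt)
  } else {
    ploidy <- colData(panel)$ploidy
    dose <- sweep(gt, 2, ifelse(ploidy == 1L, 2L, 1L), "*")  # hap present=2 -> 1 allele of 1
    dose[, ploidy == 1L] <- gt[, ploidy == 1L] / 2 * 2       # haploid: 0/2 -> 0/1
    dose[, ploidy == 1L] <- ifelse(gt[, ploidy == 1L] > 0, 1, 0)
    af <- rowSums(dose, na.rm = TRUE) / sum(ploidy)
  }
  het <- rowSums(gt == 1L, na.rm = TRUE)
  data.frame(variant_id = rownames(gt), n_strains = n,
             allele_frequency = af, is_singleton = n == 1L,
             het_fraction = het / n, stringsAsFactors = FALSE)
}

#' Jaccard similarity of two presence sets
#'
#' J(A, B) = |A intersect B| / |A union B|, the probability measure of
#' co-occurrence of two variants across strains.
#'
#' @param A,B non-empty vectors of strain ids.
#' @return numeric in `[0, 1]`.
#' @export
jaccardSimilarity <- function(A, B) {
  A <- unique(A); B <- unique(B)
  if (!length(A) || !length(B))
    stop("Jaccard similarity is undefined for an empty presence set")
  length(intersect(A, B)) / length(union(A, B))
}

#' Pairwise Jaccard matrix over variants of a panel
#'
#' @param panel a [GenotypePanel-class].
#' @param variants variant ids (default: all).
#' @return symmetric matrix of Jaccard similarities.
#' @export
pairwiseJaccard <- function(panel, variants = rownames(panel)) {
  gt <- assay(panel, "GT")[variants, , drop = FALSE] > 0L
  sz <- rowSums(gt)
  if (any(sz == 0))
    stop("variant(s) with empty presence set: ",
         paste(variants[sz == 0], collapse = ", "))
  inter <- tcrossprod(gt * 1L)
  un <- outer(sz, sz, "+") - inter
  J <- inter / un
  dimnames(J) <- list(variants, variants)
  J
}

meanPairwiseJaccard <- function(J) {
  m <- nrow(J)
  stopifnot(m >= 2)
  (sum(J) - sum(diag(J))) / (m * (m - 1))
}

#' Match focal variants to frequency-matched controls
#'
#' Greedy matching without replacement: focal variants are processed in a
#' deterministic order (descending allele frequency, then variant id); each
#' is paired with the unmatched candidate minimizing the absolute allele
#' frequency difference, ties broken by minimal Jaccard similarity with the
#' focal variant (to avoid pairing linked variants with identical
#' phylogenetic distributions), remaining ties broken uniformly at random
#' under `seed`. Focal variants left without a candidate are reported as
#' unmatched, never silently dropped.
#'
#' @param focal,candidates disjoint vectors of variant ids.
#' @param panel a [GenotypePanel-class].
#' @param seed integer seed for the final random tie-break.
#' @return list with `pairs` (data.frame focal, control, delta_af,
#'   jaccard) and `unmatched` (character).
#' @export
matchControls <- function(focal, candidates, panel, seed = 1L) {
  stopifnot(length(intersect(focal, candidates)) == 0)
  ps <- presenceStats(panel)
  af <- stats::setNames(ps$allele_frequency, ps$variant_id)
  stopifnot(all(focal %in% names(af)), all(candidates %in% names(af)))
  gt <- assay(panel, "GT") > 0L
  set.seed(as.integer(seed))
  ord <- focal[order(-af[focal], focal)]
  avail <- candidates
  rows <- list()
  unmatched <- character()
  for (f in ord) {
    if (!length(avail)) { unmatched <- c(unmatched, f); next }
    d <- abs(af[avail] - af[f])
    tied <- avail[d == min(d)]
    if (length(tied) > 1L) {
      fj <- vapply(tied, function(v) {
        A <- which(gt[f, ]); B <- which(gt[v, ])
        length(intersect(A, B)) / length(union(A, B))
      }, numeric(1))
      tied <- tied[fj == min(fj)]
    }
    ctrl <- if (length(tied) > 1L) sample(tied, 1L) else tied
    A <- which(gt[f, ]); B <- which(gt[ctrl, ])
    rows[[length(rows) + 1L]] <- data.frame(
      focal = f, control = ctrl, delta_af = abs(af[ctrl] - af[f]),
      jaccard = length(intersect(A, B)) / length(union(A, B)),
      stringsAsFactors = FALSE)
    avail <- setdiff(avail, ctrl)
  }
  pairs <- if (length(rows)) do.call(rbind, rows)
           else data.frame(focal = character(), control = character(),
                           delta_af = numeric(), jaccard = numeric())
  rownames(pairs) <- NULL
  list(pairs = pairs, unmatched = unmatched)
}

#' Co-occurrence bootstrap test
#'
#' Compares the mean pairwise Jaccard similarity within `setX` against that
#' within `setY`. The difference (and, descriptively, the ratio) of means
#' is bootstrapped by resampling variants with replacement within each set;
#' the two-sided p-value is the (smoothed) tail probability of the
#' bootstrap difference distribution crossing zero. Resampled pairs that
#' draw the same variant twice are excluded from the mean.
#'
#' @param setX,setY variant-id vectors, each of size >= 2.
#' @param panel a [GenotypePanel-class].
#' @param nBoot bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @return list: mean_jaccard_x, mean_jaccard_y, difference, ratio,
#'   p_value, n_boot, seed.
#' @export
cooccurrenceTest <- function(setX, setY, panel, nBoot = 1000L, seed = 1L) {
  stopifnot(length(setX) >= 2, length(setY) >= 2)
  JX <- pairwiseJaccard(panel, setX)
  JY <- pairwiseJaccard(panel, setY)
  mx <- meanPairwiseJaccard(JX)
  my <- meanPairwiseJaccard(JY)
  bootMean <- function(J) {
    m <- nrow(J)
    idx <- sample.int(m, m, replace = TRUE)
    S <- J[idx, idx]
    dup <- sum(choose(tabulate(idx, m), 2))
    tot <- (sum(S) - sum(diag(S))) / 2
    npair <- choose(m, 2) - dup
    if (npair == 0) return(NA_real_)
    (tot - dup) / npair   # drawn-twice pairs have J = 1; excluded
  }
  set.seed(as.integer(seed))
  boot <- replicate(nBoot, bootMean(JX) - bootMean(JY))
  boot <- boot[!is.na(boot)]
  ## ties at exactly zero (common with sparse presence sets) are split
  ## between the tails, otherwise the point mass makes the test blind
  eq <- sum(boot == 0)
  p_lo <- (1 + sum(boot < 0) + eq / 2) / (1 + length(boot))
  p_hi <- (1 + sum(boot > 0) + eq / 2) / (1 + length(boot))
  list(mean_jaccard_x = mx, mean_jaccard_y = my,
       difference = mx - my,
       ratio = if (my > 0) mx / my else Inf,
       p_value = min(1, 2 * min(p_lo, p_hi)),
       n_boot = as.integer(nBoot), seed = as.integer(seed))
}

#' Singleton counts per strain
#'
#' Number of singleton variants (present in exactly one strain) carried by
#' each strain; the terminal-branch-length proxy of strain age.
#'
#' @param panel a [GenotypePanel-class].
#' @return named integer vector over strains.
#' @export
singletonsPerStrain <- function(panel) {
  gt <- assay(panel, "GT") > 0L
  singleton <- rowSums(gt) == 1L
  counts <- colSums(gt[singleton, , drop = FALSE])
  stats::setNames(as.integer(counts), colnames(gt))
}

#' Attach singleton counts to the strain metadata
#'
#' @param panel a [GenotypePanel-class].
#' @return the panel with `colData(panel)$n_singletons` populated.
#' @export
addSingletonCounts <- function(panel) {
  colData(panel)$n_singletons <- singletonsPerStrain(panel)
  panel
}

#' Strain-age comparison for two singleton variant sets
#'
#' For each set of singleton variants, collects the singleton count of the
#' (unique) carrier strain — the strain-age proxy — and compares the two
#' distributions with a Wilcoxon rank-sum test. Optionally stratified by
#' ploidy.
#'
#' @param variantsA,variantsB singleton variant ids.
#' @param panel a [GenotypePanel-class].
#' @param stratifyPloidy also test within haploid and non-haploid strata.
#' @return data.frame with one row per stratum: stratum, n_a, n_b,
#'   median_a, median_b, W, p.
#' @export
strainAgeComparison <- function(variantsA, variantsB, panel,
                                stratifyPloidy = FALSE) {
  ps <- presenceStats(panel)
  sing <- ps$variant_id[ps$is_singleton]
  stopifnot(all(variantsA %in% sing), all(variantsB %in% sing))
  nsing <- singletonsPerStrain(panel)
  gt <- assay(panel, "GT") > 0L
  carrier <- function(v) colnames(gt)[which(gt[v, ])[1]]
  strainsA <- vapply(variantsA, carrier, character(1))
  strainsB <- vapply(variantsB, carrier, character(1))
  if (!length(strainsA) || !length(strainsB))
    stop("empty carrier set")
  ploidy <- stats::setNames(colData(panel)$ploidy, colnames(gt))
  strata <- list(all = function(s) rep(TRUE, length(s)))
  if (stratifyPloidy)
    strata <- c(strata, list(haploid = function(s) ploidy[s] == 1L,
                             diploid = function(s) ploidy[s] != 1L))
  out <- list()
  for (nm in names(strata)) {
    a <- nsing[strainsA[strata[[nm]](strainsA)]]
    b <- nsing[strainsB[strata[[nm]](strainsB)]]
    if (!length(a) || !length(b)) {
      out[[nm]] <- data.frame(stratum = nm, n_a = length(a), n_b = length(b),
                              median_a = NA, median_b = NA, W = NA, p = NA)
      next
    }
    wt <- stats::wilcox.test(a, b, exact = length(a) + length(b) < 20)
    out[[nm]] <- data.frame(stratum = nm, n_a = length(a), n_b = length(b),
                            median_a = stats::median(a),
                            median_b = stats::median(b),
                            W = unname(wt$statistic), p = wt$p.value,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
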