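#' Per-strain enrichment of focal variants over matched controls
#'
#' For every strain, counts the focal variants it carries (N_focal, e.g.
#' variants beneficial in at least one condition) and the matched control
#' variants it carries (N_control). Because controls are frequency-matched
#' one-to-one, the expected difference is zero for exchangeable sets; a
#' positive per-strain difference marks enrichment. Unmatched focal
#' variants are excluded and reported via a warning.
#'
#' @param focal focal variant ids.
#' @param pairs matched pairs from [matchControls()] (the `pairs`
#'   data.frame or the full list).
#' @param panel a [GenotypePanel-class].
#' @return data.frame: strain, clade, clade_class, ecology_class, ploidy,
#'   n_focal, n_control, diff.
#' @export
perStrainEnrichment <- function(focal, pairs, panel) {
  if (is.list(pairs) && !is.data.frame(pairs)) pairs <- pairs$pairs
  stopifnot(is(panel, "GenotypePanel"),
            all(c("focal", "control") %in% colnames(pairs)))
  matched <- intersect(focal, pairs$focal)
  dropped <- setdiff(focal, matched)
  if (length(dropped))
    warning(length(dropped), " unmatched focal variant(s) excluded: ",
            paste(utils::head(dropped, 5), collapse = ", "))
  controls <- pairs$control[match(matched, pairs$focal)]
  gt <- assay(panel, "GT") > 0L
  nf <- colSums(gt[matched, , drop = FALSE])
  nc <- colSums(gt[controls, , drop = FALSE])
  cd <- colData(panel)
  data.frame(strain = colnames(gt), clade = cd$clade,
             clade_class = cd$clade_class, ecology_class = cd$ecology_class,
             ploidy = cd$ploidy, n_focal = as.integer(nf),
             n_control = as.integer(nc),
             diff = as.integer(nf) - as.integer(nc),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Group comparisons of per-strain enrichment
#'
#' Pairwise Wilcoxon rank-sum tests of the per-strain difference
#' N_focal - N_control between groups (clade classes
#' domesticated/wild/other, or ecology classes industrial/natural/other).
#' Groups below the minimum size are flagged and skipped.
#'
#' @param res enrichment table from [perStrainEnrichment()].
#' @param grouping column of `res` to group by (`"clade_class"` or
#'   `"ecology_class"`).
#' @param minSize minimum strains per group (default 2).
#' @return data.frame: group_a, group_b, n_a, n_b, median_a, median_b, W,
#'   p, skipped.
#' @export
groupComparison <- function(res, grouping = "clade_class", minSize = 2L) {
  stopifnot(grouping %in% colnames(res), "diff" %in% colnames(res))
  groups <- sort(unique(res[[grouping]]))
  if (length(groups) < 2L) stop("need >= 2 groups")
  out <- list()
  for (i in seq_along(groups)) for (j in seq_along(groups)) {
    if (i >= j) next
    a <- res$diff[res[[grouping]] == groups[i]]
    b <- res$diff[res[[grouping]] == groups[j]]
    skip <- length(a) < minSize || length(b) < minSize
    if (skip) {
      wt <- list(statistic = NA_real_, p.value = NA_real_)
    } else {
      wt <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
    }
    out[[length(out) + 1L]] <- data.frame(
      group_a = groups[i], group_b = groups[j],
      n_a = length(a), n_b = length(b),
      median_a = if (length(a)) stats::median(a) else NA_real_,
      median_b = if (length(b)) stats::median(b) else NA_real_,
      W = unname(wt$statistic), p = wt$p.value, skipped = skip,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Allele-frequency sweep of the enrichment signal
#'
#' Iteratively removes variants above a carrier-strain-count threshold
#' (focal and control variants filtered independently; the matching is
#' never redone) and recomputes the per-strain enrichment and its group
#' comparison at each threshold. Variant sets are nested across
#' thresholds. Thresholds leaving fewer than 2 focal variants are flagged.
#'
#' @param focal focal variant ids.
#' @param pairs matched pairs from [matchControls()].
#' @param panel a [GenotypePanel-class].
#' @param grouping grouping column for the comparison.
#' @param thresholds decreasing carrier-count thresholds; default: all
#'   carrier counts observed among focal and control variants, descending.
#' @return list with `sweep` (data.frame: threshold, n_focal_kept, flagged,
#'   one mean-diff column per group, p of the first group pair) and
#'   `details` (per-threshold group-comparison tables).
#' @export
frequencySweep <- function(focal, pairs, panel, grouping = "clade_class",
                           thresholds = NULL) {
  if (is.list(pairs) && !is.data.frame(pairs)) pairs <- pairs$pairs
  ps <- presenceStats(panel)
  nstrain <- stats::setNames(ps$n_strains, ps$variant_id)
  matched <- intersect(focal, pairs$focal)
  controls <- pairs$control[match(matched, pairs$focal)]
  if (is.null(thresholds))
    thresholds <- sort(unique(nstrain[c(matched, controls)]),
                       decreasing = TRUE)
  thresholds <- sort(thresholds, decreasing = TRUE)
  groups <- sort(unique(panel@colData[[grouping]]))
  rows <- list(); details <- list()
  for (th in thresholds) {
    keep_f <- matched[nstrain[matched] <= th]
    sub_pairs <- pairs[nstrain[pairs$control] <= th &
                       pairs$focal %in% keep_f, , drop = FALSE]
    flagged <- length(keep_f) < 2L || nrow(sub_pairs) < 2L
    if (!flagged) {
      er <- suppressWarnings(
        perStrainEnrichment(sub_pairs$focal, sub_pairs, panel))
      gc <- groupComparison(er, grouping = grouping)
      means <- vapply(groups, function(g)
        mean(er$diff[er[[grouping]] == g]), numeric(1))
      p1 <- gc$p[1]
    } else {
      means <- rep(NA_real_, length(groups))
      gc <- NULL
      p1 <- NA_real_
    }
    row <- data.frame(threshold = th, n_focal_kept = length(keep_f),
                      flagged = flagged, p = p1, stringsAsFactors = FALSE)
    for (k in seq_along(groups))
      row[[paste0("mean_diff_", groups[k])]] <- means[k]
    rows[[length(rows) + 1L]] <- row
    details[[as.character(th)]] <- gc
  }
  list(sweep = do.call(rbind, rows), details = details)
}

#' Mixed-effects model of ecological origin on enrichment
#'
#' Fits `diff ~ ecology + (1 | clade)` by REML on strains of industrial or
#' natural ecology (reference level: natural), so the fixed effect is the
#' industrial-strain excess in per-strain enrichment after controlling for
#' clade identity. The p-value uses the Satterthwaite degrees-of-freedom
#' approximation; if the random-intercept fit is singular the result is
#' flagged and a fixed-effects-only fit is reported as fallback.
#'
#' @param res enrichment table from [perStrainEnrichment()].
#' @return list: estimate, se, p, df, method, singular, n, formula.
#' @export
ecologyMixedModel <- function(res) {
  d <- res[res$ecology_class %in% c("industrial", "natural"), , drop = FALSE]
  if (length(unique(d$ecology_class)) < 2L)
    stop("need both industrial and natural strains")
  if (length(unique(d$clade[!is.na(d$clade)])) < 2L)
    stop("need >= 2 clades")
  d$ecology <- stats::relevel(factor(d$ecology_class), ref = "natural")
  fit <- lmerTest::lmer(diff ~ ecology + (1 | clade), data = d, REML = TRUE)
  singular <- lme4::isSingular(fit)
  cf <- stats::coef(summary(fit))
  row <- grep("^ecologyindustrial$", rownames(cf))
  out <- list(estimate = unname(cf[row, "Estimate"]),
              se = unname(cf[row, "Std. Error"]),
              df = unname(cf[row, "df"]),
              p = unname(cf[row, "Pr(>|t|)"]),
              method = "lmer REML + Satterthwaite",
              singular = singular, n = nrow(d),
              formula = "diff ~ ecology + (1 | clade)")
  if (singular) {
    warning("singular random-effect fit; reporting fixed-effects-only fallback")
    lmfit <- stats::lm(diff ~ ecology, data = d)
    cf2 <- stats::coef(summary(lmfit))
    out$fallback <- list(estimate = unname(cf2[2, "Estimate"]),
                         se = unname(cf2[2, "Std. Error"]),
                         p = unname(cf2[2, "Pr(>|t|)"]),
                         method = "lm fixed-effects-only")
  }
  out
}
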