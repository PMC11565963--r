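#' Configure the clade-structured population simulator
#'
#' Defaults emulate, at desk scale, a strain panel with monophyletic
#' domesticated, wild and "other" clades, a singleton-heavy site-frequency
#' spectrum, mostly diploid strains, and ecology labels correlated with
#' clade class (domesticated clades are mostly industrial isolates, wild
#' clades mostly natural ones).
#'
#' @param n_strains,n_variants panel dimensions.
#' @param clade_spec data.frame (clade, clade_class, size); sizes sum to
#'   `n_strains` and every clade has at least 2 strains.
#' @param ecology_probs 3x3 row-stochastic matrix of P(ecology | clade
#'   class); rows domesticated/wild/other, columns industrial/natural/other.
#' @param planted_beneficial number of variants placed with a bias toward
#'   domesticated-clade branches (they are flagged in the output rowData).
#' @param bias_strength probability that a planted variant is forced onto a
#'   branch whose descendants are all domesticated (1 = always).
#' @param singleton_skew probability of placing a variant uniformly on a
#'   terminal branch instead of length-weighted on any branch.
#' @param ploidy_fraction_haploid proportion of haploid strains.
#' @param het_prob probability a diploid carrier is heterozygous.
#' @param seed integer seed.
#' @return A [PopulationSimConfig-class].
#' @export
populationSimConfig <- function(n_strains = 200L, n_variants = 400L,
                                clade_spec = NULL, ecology_probs = NULL,
                                planted_beneficial = 0L, bias_strength = 0.8,
                                singleton_skew = 0.3,
                                ploidy_fraction_haploid = 0.2,
                                het_prob = 0.3, seed = 1L) {
  if (is.null(clade_spec)) {
    stopifnot(n_strains == 200L)
    clade_spec <- data.frame(
      clade = sprintf("clade_%02d", 1:9),
      clade_class = c(rep("domesticated", 4), rep("wild", 3),
                      rep("other", 2)),
      size = c(30L, 30L, 30L, 30L, 10L, 10L, 10L, 25L, 25L),
      stringsAsFactors = FALSE)
  }
  if (is.null(ecology_probs)) {
    ecology_probs <- rbind(domesticated = c(0.80, 0.15, 0.05),
                           wild         = c(0.05, 0.90, 0.05),
                           other        = c(0.40, 0.50, 0.10))
    colnames(ecology_probs) <- c("industrial", "natural", "other")
  }
  new("PopulationSimConfig",
      n_strains = as.integer(n_strains), n_variants = as.integer(n_variants),
      clade_spec = clade_spec, ecology_probs = ecology_probs,
      planted_beneficial = as.integer(planted_beneficial),
      bias_strength = as.numeric(bias_strength),
      singleton_skew = as.numeric(singleton_skew),
      ploidy_fraction_haploid = as.numeric(ploidy_fraction_haploid),
      het_prob = as.numeric(het_prob), seed = as.integer(seed))
}

## list of tip-index sets per node (tips + internal), by postorder pass
tipDescendants <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  desc <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- i
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  desc
}

#' Simulate a clade-structured strain population
#'
#' Builds a rooted strain tree by grafting per-clade coalescent subtrees
#' onto a coalescent backbone (so every declared clade is monophyletic),
#' places variants as single mutations on branches (presence sets are
#' therefore clades of the tree), skews placement toward terminal branches
#' to produce a singleton-rich site-frequency spectrum, optionally plants
#' beneficial variants preferentially on domesticated-clade branches, and
#' assigns ploidy, heterozygosity and ecology labels.
#'
#' @param cfg a [PopulationSimConfig-class].
#' @return A [GenotypePanel-class]; the rooted tree is in
#'   `metadata(panel)$tree`, planted variants are flagged in
#'   `rowData(panel)$planted_beneficial`.
#' @export
simulatePopulation <- function(cfg) {
  stopifnot(is(cfg, "PopulationSimConfig"))
  validObject(cfg)
  set.seed(cfg@seed)
  cs <- cfg@clade_spec
  n_clades <- nrow(cs)

  ## backbone over clade placeholders, then graft clade subtrees
  backbone <- if (n_clades >= 2) ape::rcoal(n_clades,
                tip.label = paste0("PLACEHOLDER_", cs$clade))
              else NULL
  if (!is.null(backbone)) {
    backbone$edge.length <- backbone$edge.length /
      max(ape::node.depth.edgelength(backbone))
  }
  tree <- backbone
  for (i in seq_len(n_clades)) {
    sub <- ape::rcoal(cs$size[i],
                      tip.label = sprintf("%s_s%03d", cs$clade[i],
                                          seq_len(cs$size[i])))
    sub$edge.length <- 0.3 * sub$edge.length /
      max(ape::node.depth.edgelength(sub))
    if (is.null(tree)) { tree <- sub; next }
    where <- match(paste0("PLACEHOLDER_", cs$clade[i]), tree$tip.label)
    tree <- ape::bind.tree(tree, sub, where = where)
  }
  tree <- ape::reorder.phylo(tree, "cladewise")
  strains <- tree$tip.label
  n <- length(strains)
  stopifnot(n == cfg@n_strains)

  clade <- sub("_s[0-9]+$", "", strains)
  clade_class <- cs$clade_class[match(clade, cs$clade)]
  ecology <- vapply(clade_class, function(cc)
    sample(colnames(cfg@ecology_probs), 1, prob = cfg@ecology_probs[cc, ]),
    character(1))
  ploidy <- ifelse(stats::runif(n) < cfg@ploidy_fraction_haploid, 1L, 2L)

  ## mutation placement
  desc <- tipDescendants(tree)
  edge_child <- tree$edge[, 2]
  edge_len <- tree$edge.length
  terminal <- edge_child <= n
  dom_strains <- which(clade_class == "domesticated")
  dom_edge <- vapply(seq_along(edge_child), function(k)
    all(desc[[edge_child[k]]] %in% dom_strains), logical(1))

  pick_edge <- function(pool) {
    if (stats::runif(1) < cfg@singleton_skew) {
      cand <- which(terminal & pool)
      if (!length(cand)) cand <- which(pool)
      sample(cand, 1)
    } else {
      cand <- which(pool)
      sample(cand, 1, prob = edge_len[cand])
    }
  }

  gt <- matrix(0L, nrow = cfg@n_variants, ncol = n,
               dimnames = list(sprintf("var_%05d", seq_len(cfg@n_variants)),
                               strains))
  planted <- seq_len(cfg@n_variants) <= cfg@planted_beneficial
  all_pool <- rep(TRUE, length(edge_child))
  for (v in seq_len(cfg@n_variants)) {
    pool <- if (planted[v] && any(dom_edge) &&
                stats::runif(1) < cfg@bias_strength) dom_edge else all_pool
    carriers <- desc[[edge_child[pick_edge(pool)]]]
    g <- rep(2L, length(carriers))
    dip <- ploidy[carriers] == 2L
    g[dip] <- ifelse(stats::runif(sum(dip)) < cfg@het_prob, 1L, 2L)
    gt[v, carriers] <- g
  }

  cd <- DataFrame(clade = clade, clade_class = clade_class,
                  ecology_class = ecology, ploidy = ploidy,
                  row.names = strains)
  rd <- DataFrame(variant_id = rownames(gt), planted_beneficial = planted,
                  row.names = rownames(gt))
  panel <- SummarizedExperiment(assays = SimpleList(GT = gt),
                                rowData = rd, colData = cd)
  panel <- new("GenotypePanel", panel)
  metadata(panel)$tree <- tree
  metadata(panel)$config_seed <- cfg@seed
  panel
}

#' Accessors for GenotypePanel
#'
#' `genotypes()` returns the integer GT matrix (0/1/2), `strainData()` the
#' strain metadata, `strainTree()` the attached rooted tree (or NULL), and
#' `presenceSet()` the strain names carrying a given variant.
#'
#' @param x a [GenotypePanel-class].
#' @param variant a variant id (rowname).
#' @name GenotypePanel-accessors
NULL

#' @rdname GenotypePanel-accessors
#' @export
setMethod("genotypes", "GenotypePanel", function(x) assay(x, "GT"))

#' @rdname GenotypePanel-accessors
#' @export
setMethod("strainData", "GenotypePanel", function(x) colData(x))

#' @rdname GenotypePanel-accessors
#' @export
setMethod("strainTree", "GenotypePanel", function(x) metadata(x)$tree)

#' @rdname GenotypePanel-accessors
#' @export
setMethod("presenceSet", "GenotypePanel", function(x, variant) {
  gt <- assay(x, "GT")
  stopifnot(variant %in% rownames(gt))
  colnames(gt)[which(gt[variant, ] > 0L)]
})
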