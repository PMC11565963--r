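# Small fixtures shared across tests; everything is generated in code.

# tiny competition design for fast inference tests
tinyDesign <- function(..., seed = 1L) {
  competitionDesign(n_edits = 40L, barcodes_per_edit = 5L,
                    n_neutral_barcodes = 10L, n_replicates = 2L,
                    n_timepoints = 5L, tau = 4.3,
                    bottleneck_cells = 2e6, reads_per_timepoint = 1e6,
                    seed = seed, ...)
}

# genotype panel built from an explicit GT matrix (variants x strains)
panelFromGT <- function(gt, ploidy = NULL, clade = NULL, clade_class = NULL,
                        ecology = NULL, tree = NULL) {
  n <- ncol(gt)
  if (is.null(ploidy)) ploidy <- rep(2L, n)
  if (is.null(clade)) clade <- rep("c1", n)
  if (is.null(clade_class)) clade_class <- rep("other", n)
  if (is.null(ecology)) ecology <- rep("other", n)
  meta <- data.frame(clade = clade, clade_class = clade_class,
                     ecology_class = ecology, ploidy = ploidy,
                     row.names = colnames(gt))
  makeGenotypePanel(gt, meta, tree = tree)
}

# random exchangeable variant placement: each variant carried by a
# size drawn from a singleton-skewed distribution, strains uniform
randomPlacementGT <- function(n_variants, n_strains, seed,
                              sizes = NULL) {
  set.seed(seed)
  gt <- matrix(0L, n_variants, n_strains,
               dimnames = list(sprintf("v%04d", seq_len(n_variants)),
                               sprintf("s%03d", seq_len(n_strains))))
  for (i in seq_len(n_variants)) {
    k <- if (is.null(sizes)) min(n_strains, 1L + stats::rgeom(1, 0.4))
         else sizes[i]
    gt[i, sample.int(n_strains, k)] <- 2L
  }
  gt
}

# brute-force parsimony: minimum changes over all internal labelings
bruteForceParsimony <- function(tree, trait) {
  ntip <- length(tree$tip.label)
  v <- as.integer(as.logical(trait[tree$tip.label]))
  nint <- tree$Nnode
  best <- Inf
  for (mask in 0:(2^nint - 1)) {
    lab <- c(v, as.integer(intToBits(mask))[seq_len(nint)])
    ch <- sum(lab[tree$edge[, 1]] != lab[tree$edge[, 2]])
    best <- min(best, ch)
  }
  best
}
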