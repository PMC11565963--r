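#' Fitch parsimony score of a binary trait
#'
#' Minimum number of state changes needed to explain a binary tip trait on
#' a rooted binary tree, computed with the Fitch bottom-up pass (each
#' union event at an internal node costs one change).
#'
#' @param tree a rooted, binary `phylo` tree.
#' @param trait binary (0/1 or logical) vector named by tip label, one
#'   value per tip.
#' @return integer parsimony score.
#' @export
fitchParsimony <- function(tree, trait) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.binary(tree))
    stop("tree must be binary-resolvable; resolve multifurcations first")
  tips <- tree$tip.label
  if (is.null(names(trait))) {
    if (length(trait) != length(tips))
      stop("unnamed trait must have one value per tip")
    names(trait) <- tips
  }
  if (!all(tips %in% names(trait)))
    stop("trait missing for tip(s): ",
         paste(setdiff(tips, names(trait)), collapse = ", "))
  trait <- trait[tips]
  if (any(is.na(trait))) stop("trait contains NA")
  v <- as.integer(as.logical(trait))  # 0/1
  ntip <- length(tips)
  ## state sets as bitmasks: 1 = {0}, 2 = {1}, 3 = {0,1}
  state <- integer(ntip + tree$Nnode)
  state[seq_len(ntip)] <- ifelse(v == 1L, 2L, 1L)
  tr <- ape::reorder.phylo(tree, "postorder")
  changes <- 0L
  for (k in seq(1, nrow(tr$edge), by = 2)) {
    p <- tr$edge[k, 1]
    c1 <- tr$edge[k, 2]
    c2 <- tr$edge[k + 1, 2]
    inter <- bitwAnd(state[c1], state[c2])
    if (inter == 0L) {
      state[p] <- bitwOr(state[c1], state[c2])
      changes <- changes + 1L
    } else state[p] <- inter
  }
  changes
}

#' Retention index of a binary trait
#'
#' RI = (MaxSteps - ObservedSteps) / (MaxSteps - MinSteps), where for a
#' binary trait MinSteps = 1 and MaxSteps is the minority-state tip count.
#' RI = 1 means the derived state forms one clean clade; RI = 0 means the
#' minority state is maximally scattered. Undefined (NA, with a warning)
#' when MaxSteps = MinSteps, i.e. for a single-tip minority state, and an
#' error for an invariant trait.
#'
#' @inheritParams fitchParsimony
#' @return numeric in `[0, 1]`, or `NA` when undefined.
#' @export
retentionIndex <- function(tree, trait) {
  tips <- tree$tip.label
  if (is.null(names(trait))) {
    stopifnot(length(trait) == length(tips))
    names(trait) <- tips
  }
  v <- as.integer(as.logical(trait[tips]))
  n1 <- sum(v == 1L)
  n0 <- sum(v == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("retention index requires both states among tips")
  maxSteps <- min(n0, n1)
  minSteps <- 1L
  if (maxSteps == minSteps) {
    warning("retention index undefined: MaxSteps equals MinSteps")
    return(NA_real_)
  }
  obs <- fitchParsimony(tree, trait)
  (maxSteps - obs) / (maxSteps - minSteps)
}
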