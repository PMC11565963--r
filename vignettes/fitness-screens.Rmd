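---
title: "Inferring selection coefficients from pooled barcode screens and testing their population-genetic signatures"
author: "screenfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring selection coefficients from pooled barcode screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenfit)
```

# The problem

Pooled precision-editing screens measure the fitness effect of thousands of
genetic variants at once: each edited lineage carries a genomic barcode, the
pool is propagated by serial dilution in competition, and barcode abundances
are read out by sequencing at regular intervals. Two layers of analysis are
needed. First, the barcode count trajectories must be converted into
per-variant selection coefficients with honest uncertainty, in the presence
of sequencing noise, transfer-bottleneck drift, shared mean-fitness decline
and occasional hitchhiker mutations. Second, once variants are classified as
neutral, beneficial or deleterious, their distribution across a panel of
natural strains carries population-genetic signal: purifying selection
pushes functional variants toward low frequencies, young strains and
heterozygous states, while local adaptation concentrates beneficial variants
in particular clades (in budding yeast, domesticated and industrial
strains). `screenfit` implements both layers plus the simulators needed to
test every stage against known ground truth.

# The fitness model

## Dynamics

Within one replicate of one condition, the relative frequency $f_t(j)$ of
lineage $j$ evolves across a sampling interval of $\tau$ generations as

$$ f_{t+1}(j) \;=\; \frac{f_t(j)\, e^{s(j)\tau}}{\sum_k f_t(k)\, e^{s(k)\tau}}, $$

where $s(j)$ is the per-generation selection coefficient. To first order
the log-frequency increment is $(s(j) - \bar s_t)\tau$ with
$\bar s_t = \sum_j f_t(j) s(j)$ the population mean fitness, a nuisance
series shared by all lineages. The experiment includes non-editing
*neutral anchor* barcodes whose fitness is zero by construction; they
identify $\bar s_t$ and hence the absolute scale of all other coefficients.

## Hierarchy

Barcode counts of one edit are aggregated (after hitchhiker removal, below)
into a single trajectory per replicate. Each edit $j$ has a latent
*hyperfitness* $\phi(j)$ per condition; its per-replicate fitness values
$s(j,n)$ are draws from $\mathrm{Normal}(\phi(j), \sigma_h^2)$, pooling all
replicates into a single inference problem. Conditions are fitted
independently — they differ biologically, and per-condition calls are what
the downstream analyses consume.

## Observation model

The likelihood is Gaussian on observed log-frequency increments
$y_t = \log \hat f_{t+1} - \log \hat f_t$ with mean $(s(j,n)-\bar s_t)\tau$.
Its covariance is the delta-method read-noise covariance: the variance of
$y_t$ is

$$ \sigma^2 \;+\; \kappa / \tilde r_{t+1} \;+\; 1/\tilde r_t \;+\; 1/\tilde r_{t+1}, $$

with $\tilde r = r + 0.5$ (pseudocount for zero reads), and adjacent
increments covary by $-1/\tilde r_{t+1}$ because they share the interior
read count. Ignoring that covariance double-counts interior timepoints and
inflates the slope variance by roughly $\sqrt{T/2}$; with it, intervals are
close to nominal. The two scale parameters have distinct roles:
$\kappa/\tilde r_{t+1}$ captures transfer-bottleneck drift, whose variance
is inversely proportional to the number of cells carrying the lineage (and
cells are proportional to reads, so $\kappa$ is essentially the
read-to-bottleneck ratio); $\sigma^2$ is a residual additive scale for
anything left over. Both are estimated by penalized restricted marginal
likelihood under HalfNormal priors (scales 10 and 1). Missing transitions
(for example a contaminated timepoint) are decoupled from the covariance
and dropped from the likelihood, never imputed.

## Priors and the hyperfitness population scale

The mean-fitness series has a weak $\mathrm{Normal}(0, 0.5^2)$ prior per
transition, and the replicate-deviation scale $\sigma_h$ a
HalfNormal(0.05) prior — weakly informative at the per-generation scale of
yeast competition effects. The population scale of the hyperfitness values
themselves is *estimated* (marginal-likelihood point update with a
HalfNormal(0.5) hyperprior) rather than fixed. This matters because the
level of the mean-fitness series is identified only by the neutral anchors:
their finite read depth leaves a small error that shifts every edit's
estimate coherently. When the screen contains real effects the estimated
population scale is large (about 0.075 on the canonical simulation) and
shrinkage is negligible; when the screen is entirely neutral the scale
collapses and the common-mode error is shrunk away rather than being
declared significant, keeping the false-positive rate of an all-null screen
well below the credible level.

## Inference engines

The default engine is a deterministic structured variational scheme:
coordinate ascent on Gaussian blocks in which the per-replicate fitness is
collapsed analytically into a stream summary
$\hat s(j,n) \sim \mathrm{Normal}(\phi(j), \sigma_h^2 + v_{jn})$ (so the
$\phi$ block sees the full replicate-level uncertainty), alternating with
the mean-fitness block and the variance-scale updates until the maximum
parameter change falls below $10^{-6}$ (per-generation units; the posterior
standard deviations are two to three orders of magnitude larger).
Because the mean-field factorization does not carry the anchor-limited
common-mode uncertainty, that covariance is computed analytically at the
optimum (the anchor-only precision of each replicate's mean-fitness series,
propagated through each edit's combination weights) and added to the
reported posterior variances.

A Gibbs/Metropolis MCMC engine is available as an alternative
(`engine = "mcmc"`): Gaussian full conditionals for the fitness blocks,
log-scale random-walk Metropolis for the variance scales, plus a
common-mode recentering move that shifts all edit fitness values, the
hyperfitness and the mean-fitness series jointly along the
anchor-constrained ridge — one-at-a-time updates mix that direction far too
slowly. Split-chain $\widehat R$ and a lag-1 effective-sample estimate are
reported. Both engines are exercised by the recovery tests; the variational
engine is the default because it is deterministic and an order of magnitude
faster at screen scale.

## Classification

A variant is non-neutral in a condition when the central credible interval
of its hyperfitness (default mass 0.95) excludes zero — beneficial if the
lower bound is positive, deleterious if the upper bound is negative. No
multiplicity correction is applied; the interval mass is exposed as
configuration. Derived per-edit flags count the conditions in which a
variant is non-neutral: "non-neutral in at least two conditions" defines
the focal set of the population analyses, and "beneficial in at least one
condition" defines the enrichment focal set.

## Hitchhiker barcodes

Spontaneous beneficial mutations can take over a single barcode lineage and
masquerade as an effect of the edit. Because such mutants are unlikely to
recur across a variant's independently edited barcodes, the barcode with
the highest total read count is discarded for every editing edit with at
least two barcodes (neutral anchors and single-barcode edits are left
alone). The rule is applied per replicate/condition stream by default — a
hitchhiker arises within one flask — with a global mode available; ties
break toward the lexicographically smallest barcode id, and removal happens
before aggregation. On simulations with 5% hitchhikers at +0.1 per
generation this removes the large majority of the bias on affected edits at
the cost of one barcode's worth of depth everywhere.

# The synthetic-data generators

`simulateCompetition()` emulates the serial-dilution competition: exact
multiplicative frequency propagation over $\tau$ generations per cycle, a
multinomial transfer bottleneck, and an independent multinomial sequencing
draw per sampled timepoint; barcodes of an edit share its coefficient,
hitchhikers add theirs; neutral anchors are single-barcode edits at
exactly zero. Default design (the canonical desk-scale conditions used
throughout the tests): 300 edits with 10 barcodes each, 30 anchors, 3
replicates, 7 timepoints at $\tau = 4.3$ generations, $5\times10^6$ reads
per timepoint, and a $10^7$-cell bottleneck (500 uL of saturated culture at
roughly $2\times10^7$ cells/mL). True coefficients are drawn from a point
mass at zero (probability 0.2) mixed with Uniform($-0.15, 0.15$). The
per-transfer dilution factor is not modeled separately: growth is
parameterized directly by $\tau$ per sampling interval, and the four
serial-dilution conditions (1D/2D/3D/5D) differ by label and optionally by
their true-coefficient mapping, not structurally. One RNG stream is used
per (replicate, condition).

What the generator deliberately does *not* include: PCR-amplification
noise (the generative model is matched to the inference model's
assumptions; robustness to mismatch is probed only through hitchhiker
injection), editing-efficiency variation, barcode-identity sequencing
errors, and epistasis. Passing the recovery suite therefore demonstrates
correctness of the inference given the stated noise model, not robustness
to every artifact of real sequencing data.

`simulatePopulation()` builds a clade-structured panel: per-clade
coalescent subtrees grafted onto a coalescent backbone (declared clades are
monophyletic), variants placed as single mutations on branches so presence
sets are clades of the tree, placement skewed toward terminal branches to
produce a singleton-rich site-frequency spectrum (the singleton fraction is
monotone in the skew parameter), optional planted variants biased onto
domesticated-clade branches, and ploidy/heterozygosity/ecology labels. Its
default shape (200 strains in 9 clades, 20% haploid, domesticated clades
mostly industrial) is a desk-scale caricature of a natural isolate panel;
it does not model recombination, mosaic strains, introgression or
genotyping error. One consequence worth knowing: because presence sets are
exact clades, carrier counts are quantized, and a frequency-matched control
can be the *same* clade set as its focal variant (the minimal-Jaccard tie
rule exists precisely to avoid such linked pairs when alternatives exist).

`simulateStructure()` generates a self-avoiding random-walk C-alpha chain
with the realistic 3.8 Angstrom consecutive spacing, as a fixture for the
packing-density code.

# Population-genetic analyses

Allele frequency is the carrier-strain fraction — every threshold in the
analyses ("present in just one strain", "more than 10 strains") operates on
strain counts — with an allele-dosage mode available. Heterozygous fraction
counts haploid carriers as non-het.

**Matched controls.** Each focal variant is paired greedily, without
replacement, to the candidate neutral variant with the smallest absolute
allele-frequency difference; ties break to the candidate with minimal
Jaccard similarity to the focal variant (avoiding linked pairs with
identical phylogenetic distributions), then uniformly at random under the
seed. Focal variants are processed in descending allele frequency (then id)
because rare variants have many near-frequency candidates while
high-frequency controls are scarce; unmatched focal variants are reported,
never dropped.

**Co-occurrence.** The statistic is the difference in mean pairwise Jaccard
similarity between two variant sets (the ratio is reported alongside, since
fold-type statements are natural for this quantity; the difference is what
is tested). The null is built by resampling variants with replacement
within each set, 1000 replicates by default, with the two-sided p-value
read from the bootstrap distribution of the difference; resampled pairs
that draw the same variant twice are excluded, and the point mass of the
bootstrap distribution at exactly zero is split between the tails. A
calibration caveat: for sparse sets (singletons), the Jaccard kernel is
dominated by its degenerate part and this bootstrap is *conservative*
(measured null rejection around 0.5–1% at nominal 5%); in the
frequency-matched common-variant regime it is close to nominal (measured
4.5%). Conservative here means fewer false positives, so significant
co-occurrence differences survive the caveat.

**Strain age.** The number of singleton variants a strain carries proxies
its terminal branch length; singleton variant sets are compared by the
singleton counts of their carrier strains with a Wilcoxon rank-sum test
(exact below 20 observations, normal approximation with tie correction
otherwise), optionally stratified by ploidy.

**Tree statistics.** Fitch parsimony is the package's own bottom-up pass on
rooted binary trees (verified against brute-force minimization over all
internal labelings, and against an independent phylogenetics library); the
retention index for a binary trait uses MinSteps = 1 and MaxSteps = the
minority-state tip count, and is flagged undefined when they coincide.

**Enrichment.** Per strain, the difference between the number of focal
variants carried ($N_\mathrm{beneficial}$, default: beneficial in at least
one condition) and the number of matched controls carried
($N_\mathrm{control}$); exchangeable sets give mean difference zero.
Group structure is tested with pairwise Wilcoxon rank-sum tests between
clade classes or ecology classes; the frequency sweep recomputes the
comparison after iteratively removing variants above each observed
carrier-count threshold (pairs fixed, no re-matching, sets nested); and the
ecology effect is quantified with `diff ~ ecology + (1 | clade)` fitted by
REML, p-value by the Satterthwaite approximation, with a flagged
fixed-effects-only fallback when the random-intercept fit is singular.

# Numerical and interface choices

* Pseudocount 0.5 on reads before log-frequency increments; frequencies
  renormalized per timepoint; an all-zero timepoint is an error naming the
  sample.
* Coordinates are 1-based inclusive (VCF convention); residue indices
  1-based; packing density counts other C-alpha atoms within 10 Angstrom
  *inclusive*, excluding self and excluding residues without coordinates
  from both sides of the count.
* Annotation thresholds are strict inequalities: SIFT < 0.05 flags strong
  predicted impact, ddG > 2 kcal/mol flags destabilization; missing scores
  give missing flags, never FALSE.
* TSV artifacts are tab-separated with a header and '.' for missing
  values; genotypes are written as a minimal GT-only VCF (haploid calls as
  single alleles); trees as rooted newick with branch lengths; truth,
  diagnostics and manifests as JSON.
* The pipeline driver derives every stage seed from one global seed,
  records a configuration hash in the run manifest, and skips stages whose
  outputs already exist under an identical hash, so deleting one
  intermediate regenerates only its downstream stages.

# Problem sizes used by the test suite

The recovery, null-calibration and hitchhiker experiments run at the
canonical design above (300 edits, three replicates, one condition). The
co-occurrence calibration uses 200 exchangeable datasets of two 15-variant
sets over 50 strains; the matching audit 50 panels of 110 variants over 30
strains; tree statistics 20 random 6-tip trees with all 62 informative
binary traits; the enrichment null and power experiments 100 simulated
panels each (120 strains, 260 variants, 30 planted variants at bias 0.8);
the mixed-model recovery 100 datasets of 6 clades with 20 strains each and
a true ecology effect of 0.9 against clade intercepts of SD 0.5. These
sizes are the package's own choices: large enough that Monte-Carlo error is
well inside the acceptance margins, small enough to run comfortably on a
laptop.

# Known limitations

* The observation model is Gaussian on log-frequency increments; at very
  low counts (a handful of reads) the delta-method variance is only an
  approximation, mitigated but not removed by the pseudocount. A full
  multinomial observation layer would be the natural upgrade path.
* Fitness is assumed constant within a condition across the competition;
  frequency-dependent or time-varying selection is not modeled.
* The hierarchical pooling is per condition; a joint cross-condition model
  (shared effects with condition deviations) is out of scope.
* The co-occurrence bootstrap is conservative for singleton-dominated sets
  (see above).
* The population simulator's variants are perfect clades; real panels
  contain homoplasy, introgression and genotyping error, which the matching
  and enrichment machinery consumes happily but the simulator cannot
  generate.
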