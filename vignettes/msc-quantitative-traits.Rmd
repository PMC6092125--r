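---
title: "Quantitative traits under the multispecies coalescent: model, simulator and evaluation battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative traits under the multispecies coalescent}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mscquant)
```

## The model

Comparative methods usually assume that a continuous trait evolves along the
species tree, most often as Brownian motion (BM): the species trait values are
multivariate normal with covariance $\sigma^2 \mathbf{T}$, where the diagonal
of $\mathbf{T}$ holds root-to-tip path lengths and entry $(i,j)$ holds the
depth of the most recent common ancestor of $i$ and $j$ (`bm_vcv()`).

`mscquant` instead models a quantitative trait as the sum of mutational
effects accumulated along the *gene trees* of the $L$ loci that control it.
Gene trees are drawn from the multispecies coalescent (MSC) along a fixed
species tree whose branch lengths are in coalescent units (multiples of $2N$
generations): within a population carrying size multiplier $f$, each pair of
lineages coalesces at rate $1/f$ per unit. Mutations fall on a gene-tree
branch of length $\ell$ as Poisson($\ell\theta/2$), with $\theta = 4N\mu$ the
per-locus population mutation parameter, and each mutation's effect is an
independent draw from $\mathcal{N}(0, \sigma_M^2/L)$; a mutation is inherited
by every species descending from its branch, and ancestral alleles contribute
nothing. A species' trait value is the sum over all loci of its inherited
effects, so the ancestral (root) trait value is 0 by construction.

Two phenomena distinguish this model from BM on the species tree:

* **Deep coalescence (DC):** gene trees are taller than the species tree
  because lineages must wait to coalesce in ancestral populations. Trait
  variances (and the sister covariance) are inflated even without any
  topological discordance.
* **Hemiplasy:** when lineages fail to coalesce in their own ancestral
  population (probability $e^{-x}$ across a scaled internal branch of length
  $x = t/2N$), the locus's gene tree can be discordant with the species tree,
  and mutations on its "wrong" internal branches create covariance between
  *non-sister* species that BM cannot represent.

## Closed forms for three species

On the tree `((A:1,B:1):4,C:5)` (available as `tree_3taxon()`), with the
prefactor $2N\mu\sigma_M^2$ written as $(\theta/2)\,\sigma_M^2$:

* variance of a sister species:
  $\mathrm{Var} = \mathrm{pf}\,[\,t_e + (1-e^{-x})(x+1) + e^{-x}(x+1+\tfrac13)\,]$
  (`coal_var()`); for the outgroup the $x$ path terms are dropped. Both
  simplify to $\mathrm{pf}\,(t_e + x + 1 + e^{-x}/3)$ and
  $\mathrm{pf}\,(t_e + 1 + e^{-x}/3)$, and on an ultrametric tree the three
  species variances are equal.
* sister covariance:
  $\mathrm{pf}\,[(1-e^{-x})(1 + x - (1 - \frac{x}{e^{x}-1})) + \tfrac13 e^{-x}]
  = \mathrm{pf}\,(x + e^{-x}/3)$ (`coal_cov_sisters()`); the removable
  singularity at $x=0$ is handled by its analytic limit $\mathrm{pf}/3$, not
  by numerical perturbation.
* non-sister covariance: $\mathrm{pf}\,\tfrac13 e^{-x}$
  (`coal_cov_nonsisters()`) — zero only in the no-ILS limit. The difference
  between sister and non-sister covariance is exactly $\mathrm{pf}\cdot x$.

With $x=4$ and $t_e=1$ at unit prefactor these evaluate to $\approx 6.006$,
$4.006$ and $0.0061$: the variance exceeds the BM value 5 even though
discordance is rare ($e^{-4} \approx 0.018$), while the sister covariance
matches BM's 4 up to the tiny hemiplasy term.

**Population-size multipliers.** The printed forms measure coalescent waits
in units of the *local* population. When ancestral populations are inflated
by $f$ (the package's mechanism for raising ILS), the coalescent terms scale
by $f$ while species-tree path lengths stay in reference units; pass
$x = x_0/f$ together with `pop_multiplier = f`, or use `coal_vcv_3taxon()`
which assembles the full matrix for any single ancestral multiplier:
$\mathrm{Var} = \mathrm{pf}(t_e + x_0 + f(1 + e^{-x}/3))$,
$\mathrm{Cov}_{AB} = \mathrm{pf}(x_0 + f e^{-x}/3)$,
$\mathrm{Cov}_{AC} = \mathrm{pf}\, f e^{-x}/3$. At $f=1$ these reduce exactly
to the printed equations; the Monte-Carlo agreement tests exercise the
general form.

## ILS conditions and calibration

Experimental conditions are specified as *target discordance fractions*, not
as raw multipliers. For three species the multiplier is obtained analytically
by inverting the discordance probability $\tfrac23 e^{-x_0/f}$
(`calibrate_multiplier()`); for larger trees no closed form is used and
`calibrate_multiplier_mc()` bisects on $\log f$ over $[1, 10^6]$ against the
Monte-Carlo discordance fraction, stopping when the estimate is within two
Monte-Carlo standard errors of the target (or after 40 iterations). A target
of 0 maps to $f = 1$ by convention: the baseline tree retains a small
residual discordance ($\approx 0.012$ for the three-taxon fixture,
$\approx 0.04$ for the five-taxon fixture), which is what the "0%" condition
denotes. We calibrate rather than reuse published multiplier factors because
raw factors are meaningful only under a fixed time-unit convention, whereas a
target discordance fraction is convention-free and directly checkable against
`empirical_discordance()`.

Multipliers are applied to all *ancestral* (non-terminal) populations,
including the root population; terminal populations keep multiplier 1.

## The simulator

`simulate_gene_tree()` implements the standard MSC: within each species-tree
branch the waiting time to the next coalescence among $k$ lineages is
exponential with rate $k(k-1)/2 \cdot 1/f$, survivors are passed upward, and
everything coalesces in the root population. `simulate_trait_dataset()`
draws `n_loci` independent gene trees per replicate and sums the per-species
compound-Poisson mutational contributions; per-branch totals are drawn as
$\mathcal{N}(0, n_{\mathrm{mut}}\sigma_M^2/L)$, which is distributionally
identical to summing individual mutation effects. Within each replicate,
genealogies and mutations use two separate seeded RNG streams, so the gene
trees (and hence the realized discordance) of a replicate are identical
across mutation-parameter settings and the whole dataset is bit-for-bit
reproducible from `(seed, configuration)`.

Default parameters are the study conditions: $\theta = 4$, unit total
mutational-effect variance $\sigma_M^2 = 1$ with per-locus variance
$\sigma_M^2/L$ (the infinitesimal scaling that makes trait moments invariant
to $L$; the absolute per-locus effect size is a configuration knob because
only the scaling rule, not the constant, is determined), locus counts from
$\{5, 15, 25, 50, 100\}$, and 1000 replicates per condition.

What the simulator deliberately omits: recombination within loci, migration
and introgression, selection, dominance and epistasis, non-Gaussian effect
distributions, within-species sampling variance, and multiple lineages per
species. Passing tests therefore show that the package reproduces the
*neutral, additive, one-lineage-per-species* MSC trait model, not that real
traits behave this way.

## Estimation and testing battery

* `fit_sigma2()` — ML estimates of the root state and BM rate via the
  generalized-least-squares closed forms (Cholesky solves; no silent
  regularization — a singular covariance raises an error). The ML rate uses
  denominator $n$, so its expectation under the model is $(n-1)/n\,\sigma^2$.
* `fit_lambda_sigma2()` — joint ML with Pagel's $\lambda$ multiplying the
  off-diagonal entries (`lambda_transform()`). $\lambda$ is profiled over
  $[0,1]$ by bounded scalar optimization (tolerance $10^{-8}$) with the
  endpoints checked explicitly; the closed forms above give the root state
  and rate at each $\lambda$. We bound $\lambda$ at 1 because values above 1
  are ill-posed on ultrametric trees; with only 5 species the constrained MLE
  is strongly boundary-attracted and individual estimates are highly
  variable — the *median* under pure BM sits near 1 while the mean sits well
  below it, which is why calibration checks use boundary-mass and median
  summaries rather than the mean.
* `phylo_anova()` — simulation-based phylogenetic ANOVA: the two-group F
  statistic is referred to an empirical null of BM simulations on the species
  tree. The null rate is fixed at 1 (F is scale-invariant, and this avoids
  coupling the null to an estimated rate); p-values follow the add-one rule
  and are never 0, with ties counting toward rejection. Defaults: 1000 null
  simulations, $\alpha = 0.05$. `count_significant_groupings()` runs all 10
  pair-versus-triple groupings per replicate and shares one null draw across
  replicates and groupings — valid for the same scale-invariance reason, and
  necessary to keep thousand-replicate screens tractable.
* `compute_threshold()` / `discretize()` / `classify_pattern()` — liability
  discretization at one pooled sample standard deviation (denominator
  $n - 1$) above the pooled mean, pooling over all species and replicates of
  one (condition, locus count) cell so that higher-ILS conditions get higher
  cutoffs; ties code to 0. A pattern is *uninformative* unless at least two
  species carry each state; it is *congruent* when its derived set is exactly
  a species-tree clade (a single gain with ancestral state 0). We fix the
  ancestral state at 0 because the trait is built from derived-allele
  effects; the alternative any-root-state rule (which would also accept
  patterns like `00111`, whose '0'-set is a clade) is available via
  `allow_root_state_one = TRUE` but off by default, matching the worked
  pattern examples. `incongruence_frequency()` restricts by default to
  patterns with exactly two derived species, the tabulation used in the
  threshold analysis.

## The factorial experiment

`run_experiment()` crosses calibrated ILS conditions with locus counts; each
cell simulates one `trait_dataset` and computes moments, fits, the ANOVA
screen and the threshold incongruence, writing tidy CSVs plus a JSON manifest
(seed, multipliers, package version). Calibration is done once per condition
and shared across locus counts; cells are seeded independently from the root
seed, so results for one cell do not depend on which other cells run, and the
whole experiment is byte-reproducible.

Expected behavior as discordance rises, for any locus count: trait variances
and non-sister covariances rise; normalized covariances between all pairs
converge; the estimated BM rate $\hat\sigma^2$ rises (DC plus hemiplasy);
$\hat\lambda$ falls and, when estimated jointly, absorbs part of the rate
inflation (hemiplasy only), so $\hat\sigma^2_{\lambda} < \hat\sigma^2$; the
mean number of significant pair-versus-rest ANOVA tests rises above its
BM-null calibration of $10\alpha = 0.5$; and the threshold incongruence
frequency rises. The incongruence trend is real but shallow (roughly 0.70 to
0.79 across the calibrated range on the five-taxon tree), and per-cell
incongruence is estimated from only the two-derived informative replicates
(roughly a tenth of them), so trend checks compare successive levels with
explicit Monte-Carlo standard errors rather than demanding strict sample
monotonicity.

## Problem sizes and numerical choices

The test suite runs the simulator-versus-theory comparison at 1000 replicates
per condition with $L = 25$ loci (three-species tree), the estimator
calibrations at 1000-2000 BM replicates, and the five-species factorial at
1000 replicates per cell with $L \in \{5, 100\}$, 500 shared-null ANOVA
simulations and 4000 calibration simulations per bisection step; a full run
of the suite takes a few minutes on one core. `experiment_config(fast =
TRUE)` caps replicates at 200 for quick exploratory runs. All Monte-Carlo
assertions use 3-standard-error bands derived from the theoretical moments
(variance SE $\approx V\sqrt{2/(n-1)}$, covariance SE $\approx
\sqrt{(V_iV_j + C_{ij}^2)/(n-1)}$).

Other numerical conventions: Newick I/O is strict (rooted, bifurcating,
every branch with a non-negative length, unique `[A-Za-z0-9_.-]` tip labels,
semicolon required); canonical topology comparison uses a label-sorted,
length-free Newick key with locale-independent (C radix) ordering; the
single-species-pair F statistic reports `Inf` when within-group variance is
exactly zero; and degenerate trait vectors (all values equal) yield
$\hat\sigma^2 = 0$ with a degeneracy flag rather than an optimizer failure.

## Known limitations

Closed-form expectations exist only for three species; five-species
expectations are Monte-Carlo. The per-locus mutational variance used in the
original study is not recoverable, so absolute trait scales are arbitrary
(all downstream statistics used here are scale-invariant or scale-equivariant).
$\lambda$ above 1 is not considered. The ANOVA null is BM with the species
tree, so even the 0%-discordance MSC condition shows a mild excess of
significant tests — that excess is the DC effect, not an error in the test.
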