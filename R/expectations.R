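#' Brownian-motion variance-covariance matrix
#'
#' Under Brownian motion the species trait values are multivariate normal
#' with covariance `sigma2 * T`, where the diagonal of `T` holds root-to-tip
#' path lengths and entry (i, j) holds the root-to-MRCA(i, j) path length.
#'
#' @param tree A `"species_tree"`, `"phylo"`, or Newick string.
#' @param sigma2 BM rate (>= 0).
#' @return A labelled symmetric matrix.
#' @examples
#' bm_vcv(tree_3taxon(), 1)  # diag 5, (A,B) = 4, rest 0
#' @export
bm_vcv <- function(tree, sigma2 = 1) {
  st <- as_species_tree(tree)
  stopifnot(is.numeric(sigma2), length(sigma2) == 1L, sigma2 >= 0)
  sigma2 * ape::vcv(st$phy)
}

check_x <- function(x) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
    stop("scaled branch length 'x' must be a non-negative number", call. = FALSE)
  x
}

#' Expected trait variance within one species under the coalescent
#'
#' Closed-form expectation for the across-replicate variance of a species'
#' trait value on the three-species tree ((A,B),C), per locus. For a sister
#' species (A or B) the bracketed path length is
#' `t_e + (1 - e^(-x)) (x + 1) + e^(-x) (x + 1 + 1/3)`;
#' for the outgroup C the `x` path terms are dropped (the probabilities keep
#' `x`). The prefactor 2\*N\*mu\*sigma_M2 equals `theta/2 * sigma_M2` in the
#' package's 2N-generation time unit.
#'
#' When the ancestral populations are inflated by a multiplier `f`, the
#' coalescent waiting terms scale by `f` while species-tree path lengths stay
#' in reference units: pass `x = x0/f` (the branch length over the local
#' population size) together with `pop_multiplier = f`. At `f = 1` the value
#' is exactly the printed formula.
#'
#' @param x Internal branch length divided by the local population-size
#'   multiplier (t/2N for that branch).
#' @param t_e Terminal branch length, coalescent units (reference population).
#' @param model A [mutation_model()].
#' @param outgroup If `TRUE`, use the outgroup variant.
#' @param pop_multiplier Ancestral population-size multiplier f (>= 0).
#' @return Expected per-locus trait variance.
#' @examples
#' coal_var(4, 1, mutation_model(theta = 2, sigma_M2 = 1))  # ~ 6.006
#' @export
coal_var <- function(x, t_e, model = mutation_model(theta = 2, sigma_M2 = 1),
                     outgroup = FALSE, pop_multiplier = 1) {
  check_x(x)
  if (!is.numeric(t_e) || length(t_e) != 1L || is.na(t_e) || t_e < 0)
    stop("terminal branch length 't_e' must be non-negative", call. = FALSE)
  p0 <- exp(-x)
  xp <- if (outgroup) 0 else x
  bracket <- (1 - p0) * (xp + 1) + p0 * (xp + 1 + 1 / 3)
  prefactor(model) * (t_e + pop_multiplier * bracket)
}

#' Expected trait covariance between sister species under the coalescent
#'
#' Per-locus expectation of Cov(A, B) on ((A,B),C):
#' `prefactor * [(1 - e^(-x)) (1 + x - (1 - x / (e^x - 1))) + e^(-x)/3]`,
#' which simplifies to `prefactor * (x + e^(-x)/3)`. The removable
#' singularity at `x = 0` is handled by its analytic limit (1/3 of the
#' prefactor). See [coal_var()] for the `pop_multiplier` convention.
#'
#' @inheritParams coal_var
#' @return Expected per-locus trait covariance.
#' @export
coal_cov_sisters <- function(x, model = mutation_model(theta = 2, sigma_M2 = 1),
                             pop_multiplier = 1) {
  check_x(x)
  p0 <- exp(-x)
  em1 <- expm1(x)
  middle <- if (em1 == 0) 0 else (1 - p0) * (1 + x - (1 - x / em1))
  prefactor(model) * pop_multiplier * (middle + p0 / 3)
}

#' Expected trait covariance between non-sister species under the coalescent
#'
#' Per-locus expectation of Cov(A, C) = Cov(B, C) on ((A,B),C):
#' `prefactor * e^(-x)/3`. Non-zero only through discordant gene trees --
#' this is the covariance signature of hemiplasy. See [coal_var()] for the
#' `pop_multiplier` convention.
#'
#' @inheritParams coal_var
#' @return Expected per-locus trait covariance.
#' @export
coal_cov_nonsisters <- function(x, model = mutation_model(theta = 2, sigma_M2 = 1),
                                pop_multiplier = 1) {
  if (!identical(x, Inf)) check_x(x)
  prefactor(model) * pop_multiplier * exp(-x) / 3
}

#' Coalescent trait variance-covariance matrix for a three-species tree
#'
#' Assembles the closed-form expectations into one matrix for a tree with
#' topology ((A,B),C). Requires a single ancestral multiplier (internal and
#' root populations equal); terminal populations must have multiplier 1.
#' Entries are per locus; for a trait controlled by L loci with per-mutation
#' effect variance sigma_M2/L the matrix is unchanged (contributions add).
#'
#' @param tree A `"species_tree"` with exactly three tips.
#' @param model A [mutation_model()].
#' @return A labelled symmetric 3x3 matrix in the tree's tip order.
#' @export
coal_vcv_3taxon <- function(tree, model = mutation_model()) {
  st <- as_species_tree(tree)
  phy <- st$phy
  nt <- length(phy$tip.label)
  if (nt != 3L) stop("closed forms are available for 3 species only", call. = FALSE)
  anc <- st$multipliers[(nt + 1L):(nt + phy$Nnode)]
  if (length(unique(anc)) != 1L)
    stop("closed forms assume one common ancestral multiplier", call. = FALSE)
  if (any(st$multipliers[seq_len(nt)] != 1))
    stop("terminal populations must keep multiplier 1", call. = FALSE)
  f <- anc[1L]
  ## internal (non-root) node and its subtending branch
  root <- nt + 1L
  inner <- setdiff((nt + 1L):(nt + phy$Nnode), root)
  x0 <- phy$edge.length[phy$edge[, 2L] == inner]
  sisters <- phy$edge[phy$edge[, 1L] == inner, 2L]   # tip indices
  out <- setdiff(seq_len(nt), sisters)
  x <- x0 / f
  depths <- root_to_tip_depths(phy)
  V <- matrix(0, 3L, 3L, dimnames = list(phy$tip.label, phy$tip.label))
  for (i in sisters)
    V[i, i] <- coal_var(x, depths[i] - x0, model, outgroup = FALSE,
                        pop_multiplier = f)
  V[out, out] <- coal_var(x, depths[out], model, outgroup = TRUE,
                          pop_multiplier = f)
  V[sisters[1L], sisters[2L]] <- V[sisters[2L], sisters[1L]] <-
    coal_cov_sisters(x, model, pop_multiplier = f)
  cnn <- coal_cov_nonsisters(x, model, pop_multiplier = f)
  V[out, sisters] <- V[sisters, out] <- cnn
  V
}

#' Gene-tree topology probabilities for three species
#'
#' For ((A,B),C) with scaled internal branch `x = t/2N`: the concordant
#' topology has probability `1 - (2/3) e^(-x)`; each of the two discordant
#' topologies has probability `(1/3) e^(-x)`.
#'
#' @inheritParams coal_var
#' @return Numeric vector `c(concordant, discordant1, discordant2)`.
#' @export
topology_probs_3taxon <- function(x) {
  if (!identical(x, Inf)) check_x(x)
  p0 <- exp(-x)
  c(concordant = 1 - 2 / 3 * p0,
    discordant1 = p0 / 3, discordant2 = p0 / 3)
}

#' Probability that two lineages fail to coalesce within a branch
#'
#' `e^(-x)` for a scaled branch length `x`: the probability of incomplete
#' lineage sorting across that branch.
#'
#' @inheritParams coal_var
#' @export
prob_no_coalescence <- function(x) {
  if (!identical(x, Inf)) check_x(x)
  exp(-x)
}

#' Number of rooted, bifurcating, labelled topologies
#'
#' `(2n - 3)!!` for n species.
#'
#' @param n Number of species (>= 2).
#' @return A number: 1, 3, 15, 105, ...
#' @examples
#' count_rooted_topologies(5)  # 105
#' @export
count_rooted_topologies <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 2 || n != round(n))
    stop("'n' must be an integer >= 2", call. = FALSE)
  if (n == 2) return(1)
  prod(seq(3, 2 * n - 3, by = 2))
}

#' Analytic multiplier calibration for a three-species tree
#'
#' Inverts the discordance probability `(2/3) e^(-x0/f)` to find the
#' ancestral population-size multiplier `f` giving a target discordance
#' fraction: `f = x0 / (-log(3 * target / 2))`. A target of 0 returns the
#' convention `f = 1` (the baseline tree; its residual discordance,
#' `(2/3) e^(-x0)`, is what the study labels "0%").
#'
#' @param x0 Baseline internal branch length in coalescent units (> 0).
#' @param target_discordance Target discordance fraction in `[0, 2/3)`.
#' @return The multiplier `f`.
#' @examples
#' calibrate_multiplier(4, 0.30)
#' @export
calibrate_multiplier <- function(x0, target_discordance) {
  stopifnot(is.numeric(x0), length(x0) == 1L, x0 > 0,
            is.numeric(target_discordance), length(target_discordance) == 1L)
  if (target_discordance < 0 || target_discordance >= 2 / 3)
    stop("target discordance must lie in [0, 2/3): the panmixia limit is 2/3",
         call. = FALSE)
  if (target_discordance == 0) return(1)
  x0 / (-log(3 * target_discordance / 2))
}

#' Monte-Carlo multiplier calibration for arbitrary species trees
#'
#' Bisection (on log f over the bracket \[1, 1e6\]) against the Monte-Carlo
#' discordance fraction: the fraction of simulated gene trees whose
#' [topology_key()] differs from the species tree's. Stops when the
#' Monte-Carlo estimate is within 2 Monte-Carlo standard errors of the
#' target, or after 40 iterations. A target of 0 returns `f = 1` without
#' simulation.
#'
#' @param tree A `"species_tree"` (baseline multipliers; the candidate
#'   multiplier replaces the ancestral entries during the search).
#' @param target_discordance Target discordance fraction.
#' @param n_sims Gene trees simulated per bisection step.
#' @param seed RNG seed.
#' @return The calibrated multiplier `f`.
#' @export
calibrate_multiplier_mc <- function(tree, target_discordance, n_sims = 10000L,
                                    seed = NULL) {
  st <- as_species_tree(tree)
  stopifnot(is.numeric(target_discordance), length(target_discordance) == 1L,
            target_discordance >= 0, target_discordance < 1)
  if (target_discordance == 0) return(1)
  species_key <- topology_key(st$phy)
  disc_at <- function(f) {
    plan <- msc_sim_plan(species_tree(st$phy, ancestral_multiplier = f))
    mean(vapply(seq_len(n_sims),
                function(i) sim_gene_tree_impl(plan, keys = TRUE)$key != species_key,
                logical(1L)))
  }
  with_seed(seed, {
    flo <- 1; fhi <- 1e6
    dlo <- disc_at(flo)
    se <- function(d) sqrt(max(d * (1 - d), 1 / n_sims) / n_sims)
    if (dlo > target_discordance + 2 * se(dlo))
      stop("target discordance is below the tree's baseline level", call. = FALSE)
    dhi <- disc_at(fhi)
    if (dhi < target_discordance - 2 * se(dhi))
      stop("target discordance is unreachable on this tree", call. = FALSE)
    f <- sqrt(flo * fhi)
    for (i in seq_len(40L)) {
      f <- sqrt(flo * fhi)
      d <- disc_at(f)
      if (abs(d - target_discordance) <= 2 * se(d)) return(f)
      if (d < target_discordance) flo <- f else fhi <- f
    }
    f
  })
}

#' Build calibrated ILS conditions for a species tree
#'
#' Uses the analytic inversion for three-species trees and Monte-Carlo
#' bisection otherwise.
#'
#' @param tree A `"species_tree"`.
#' @param targets Numeric vector of target discordance fractions.
#' @param n_sims,seed Passed to [calibrate_multiplier_mc()] when needed.
#' @return A list of [ils_condition()] objects.
#' @export
calibrate_conditions <- function(tree, targets, n_sims = 10000L, seed = NULL) {
  st <- as_species_tree(tree)
  phy <- st$phy
  nt <- length(phy$tip.label)
  seeds <- with_seed(seed, spawn_seeds(length(targets)))
  out <- vector("list", length(targets))
  for (i in seq_along(targets)) {
    f <- if (nt == 3L) {
      root <- nt + 1L
      inner <- setdiff((nt + 1L):(nt + phy$Nnode), root)
      x0 <- phy$edge.length[phy$edge[, 2L] == inner]
      max(1, calibrate_multiplier(x0, targets[i]))
    } else {
      calibrate_multiplier_mc(st, targets[i], n_sims = n_sims, seed = seeds[i])
    }
    out[[i]] <- ils_condition(targets[i], f)
  }
  out
}
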