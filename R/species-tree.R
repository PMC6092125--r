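#' Species tree with per-population size multipliers
#'
#' A rooted, bifurcating phylogeny whose branch lengths are in coalescent
#' units (multiples of 2N generations, where N is the reference population
#' size), together with one population-size multiplier per population. The
#' population associated with a node is the species-tree branch immediately
#' above it; the root entry describes the ancestral population in which all
#' remaining lineages must coalesce. Within a population carrying multiplier
#' f, each pair of lineages coalesces at rate 1/f per coalescent unit.
#'
#' @param phy A `"phylo"` object, or a Newick string.
#' @param ancestral_multiplier Convenience: one multiplier applied to every
#'   non-terminal population (all internal branches and the root population);
#'   terminal populations keep multiplier 1. This is how levels of incomplete
#'   lineage sorting are raised while the species tree itself is held fixed.
#' @param multipliers Optional full numeric vector, one entry per node
#'   (tips first, then internal nodes in `phy`'s node numbering), overriding
#'   `ancestral_multiplier`. All entries must be positive.
#' @return An object of class `"species_tree"`: a list with elements `phy`
#'   and `multipliers`.
#' @examples
#' st <- species_tree("((A:1,B:1):4,C:5);", ancestral_multiplier = 2.7)
#' st
#' @export
species_tree <- function(phy, ancestral_multiplier = 1, multipliers = NULL) {
  if (is.character(phy)) phy <- parse_newick(phy)
  phy <- validate_phylo(phy)
  nt <- length(phy$tip.label)
  nn <- nt + phy$Nnode
  if (is.null(multipliers)) {
    if (!is.numeric(ancestral_multiplier) || length(ancestral_multiplier) != 1L ||
        is.na(ancestral_multiplier) || ancestral_multiplier <= 0)
      stop("'ancestral_multiplier' must be a positive number", call. = FALSE)
    multipliers <- rep(1, nn)
    if (phy$Nnode >= 1L) multipliers[(nt + 1L):nn] <- ancestral_multiplier
  }
  if (length(multipliers) != nn || anyNA(multipliers) || any(multipliers <= 0))
    stop("'multipliers' must be one positive value per node", call. = FALSE)
  structure(list(phy = phy, multipliers = as.numeric(multipliers)),
            class = "species_tree")
}

#' @export
print.species_tree <- function(x, ...) {
  nt <- length(x$phy$tip.label)
  cat("Species tree with", nt, "tips:", write_newick(x$phy), "\n")
  anc <- x$multipliers[(nt + 1L):length(x$multipliers)]
  cat("Population-size multipliers: terminal ",
      paste(unique(x$multipliers[seq_len(nt)]), collapse = "/"),
      ", ancestral ", paste(format(unique(anc), digits = 4), collapse = "/"),
      "\n", sep = "")
  invisible(x)
}

as_species_tree <- function(x) {
  if (inherits(x, "species_tree")) x else species_tree(x)
}

#' Three- and five-species study phylogenies
#'
#' The ultrametric fixture trees used throughout: `((A:1,B:1):4,C:5)` and
#' `((((A:1,B:1):4,C:5):4,D:9):4,E:13)`, with branch lengths in units of
#' 2N generations.
#'
#' @param ancestral_multiplier Population-size multiplier applied to all
#'   ancestral populations (see [species_tree()]).
#' @return A `"species_tree"`.
#' @export
tree_3taxon <- function(ancestral_multiplier = 1) {
  species_tree("((A:1,B:1):4,C:5);", ancestral_multiplier)
}

#' @rdname tree_3taxon
#' @export
tree_5taxon <- function(ancestral_multiplier = 1) {
  species_tree("((((A:1,B:1):4,C:5):4,D:9):4,E:13);", ancestral_multiplier)
}

#' Mutation model for trait-affecting loci
#'
#' Parameters governing how mutations arise on gene trees and affect the
#' trait: the population mutation parameter theta = 4*N*mu per locus (so that
#' mutations fall on a gene-tree branch of length l coalescent units as a
#' Poisson with mean l*theta/2), and the variance sigma_M2 of the Gaussian
#' per-mutation effect distribution. For a trait controlled by L loci the
#' simulator uses per-mutation effect variance sigma_M2 / L (infinitesimal
#' scaling), keeping total trait variance constant in L.
#'
#' @param theta Population mutation parameter (> 0); the study value is 4.
#' @param sigma_M2 Variance of the per-mutation effect distribution (> 0).
#' @param n_loci Number of loci L controlling the trait (>= 1).
#' @return An object of class `"mutation_model"`.
#' @export
mutation_model <- function(theta = 4, sigma_M2 = 1, n_loci = 1L) {
  stopifnot(is.numeric(theta), length(theta) == 1L, theta >= 0,
            is.numeric(sigma_M2), length(sigma_M2) == 1L, sigma_M2 >= 0,
            length(n_loci) == 1L, n_loci >= 1)
  structure(list(theta = theta, sigma_M2 = sigma_M2,
                 n_loci = as.integer(n_loci)),
            class = "mutation_model")
}

## 2*N*mu*sigma_M2 in the package's time unit: theta/2 * sigma_M2 (per locus)
prefactor <- function(model) model$theta / 2 * model$sigma_M2

#' An ILS condition: a target discordance level and its calibrated multiplier
#'
#' @param target Target gene-tree discordance fraction.
#' @param multiplier Calibrated ancestral population-size multiplier (>= 1).
#' @param label Optional condition label; defaults to the target.
#' @return An object of class `"ils_condition"`.
#' @export
ils_condition <- function(target, multiplier, label = NULL) {
  stopifnot(is.numeric(target), length(target) == 1L, target >= 0, target < 1,
            is.numeric(multiplier), length(multiplier) == 1L)
  if (multiplier < 1)
    stop("condition multiplier must be >= 1 (ancestral populations are inflated, never shrunk)",
         call. = FALSE)
  if (is.null(label)) label <- paste0("disc", format(target))
  structure(list(label = label, target = target, multiplier = multiplier),
            class = "ils_condition")
}

## Apply a condition's multiplier to a species tree's ancestral populations.
apply_condition <- function(st, condition) {
  if (is.null(condition)) return(st)
  species_tree(st$phy, ancestral_multiplier = condition$multiplier)
}

## evaluate expr under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## deterministic child seeds below 2^31
spawn_seeds <- function(n) sample.int(2147483646L, n, replace = FALSE)
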