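## Multispecies-coalescent gene-tree simulation and trait simulation.
##
## One haploid lineage is sampled per species. Time runs from the present
## (0) toward the root; all lengths are in coalescent units (2N generations
## of the reference population). Within the population above species-tree
## node v (multiplier f), k lineages coalesce at total rate k(k-1)/2 / f per
## unit; survivors are handed to the parent population, and everything
## coalesces in the root population, whose multiplier applies indefinitely.

## Precompute the traversal used by the simulator. Requires ultrametric
## trees (tips at the present).
msc_sim_plan <- function(st) {
  phy <- st$phy
  nt <- length(phy$tip.label)
  if (nt < 2L) stop("need at least two species to simulate", call. = FALSE)
  nn <- nt + phy$Nnode
  depths <- ape::node.depth.edgelength(phy)
  h <- max(depths[seq_len(nt)])
  if (max(depths[seq_len(nt)]) - min(depths[seq_len(nt)]) > 1e-8)
    stop("gene-tree simulation requires an ultrametric species tree",
         call. = FALSE)
  times <- h - depths                       # node times before present
  parent_time <- rep(Inf, nn)
  pe <- match(seq_len(nn), phy$edge[, 2L])
  parent_time[!is.na(pe)] <- times[phy$edge[pe[!is.na(pe)], 1L]]
  po <- ape::reorder.phylo(phy, "postorder")
  parents <- unique(po$edge[, 1L])          # children always precede parents
  kids <- lapply(parents, function(nd) po$edge[po$edge[, 1L] == nd, 2L])
  list(nt = nt, tips = phy$tip.label, times = times,
       parent_time = parent_time, parents = parents, kids = kids,
       mult = st$multipliers, root = nt + 1L)
}

## Core simulation. Returns branch bitmasks (which species inherit mutations
## on that branch), branch lengths, the canonical topology key (if keys),
## a Newick string with branch lengths (if newick), and the root time.
sim_gene_tree_impl <- function(plan, keys = TRUE, newick = FALSE) {
  nt <- plan$nt
  nl <- 2L * nt - 1L
  lmask <- integer(nl)
  lmask[seq_len(nt)] <- bitwShiftL(1L, seq_len(nt) - 1L)
  torig <- numeric(nl)
  torig[seq_len(nt)] <- plan$times[seq_len(nt)]
  key <- if (keys) c(plan$tips, character(nt - 1L)) else NULL
  nwk <- if (newick) c(plan$tips, character(nt - 1L)) else NULL
  bmask <- integer(2L * nt - 2L)
  blen <- numeric(2L * nt - 2L)
  bi <- 0L
  surv <- vector("list", nt + length(plan$parents))
  for (i in seq_len(nt)) surv[[i]] <- i
  nid <- nt
  for (j in seq_along(plan$parents)) {
    nd <- plan$parents[[j]]
    ids <- c(surv[[plan$kids[[j]][1L]]], surv[[plan$kids[[j]][2L]]])
    tt <- plan$times[nd]
    t1 <- plan$parent_time[nd]
    f <- plan$mult[nd]
    k <- length(ids)
    while (k > 1L) {
      tt <- tt + stats::rexp(1L) * f / (k * (k - 1L) / 2)
      if (tt > t1) break
      pick <- sample.int(k, 2L)
      a <- ids[pick[1L]]
      b <- ids[pick[2L]]
      bmask[bi + 1L] <- lmask[a]
      blen[bi + 1L] <- tt - torig[a]
      bmask[bi + 2L] <- lmask[b]
      blen[bi + 2L] <- tt - torig[b]
      bi <- bi + 2L
      nid <- nid + 1L
      lmask[nid] <- bitwOr(lmask[a], lmask[b])
      torig[nid] <- tt
      if (keys) {
        kk <- sort(c(key[a], key[b]), method = "radix")
        key[nid] <- paste0("(", kk[1L], ",", kk[2L], ")")
      }
      if (newick) {
        nwk[nid] <- paste0("(", nwk[a], ":",
                           format(tt - torig[a], digits = 15), ",",
                           nwk[b], ":",
                           format(tt - torig[b], digits = 15), ")")
      }
      ids <- c(ids[-pick], nid)
      k <- k - 1L
    }
    surv[[nd]] <- ids
  }
  list(bmask = bmask, blen = blen,
       key = if (keys) key[nid] else NULL,
       newick = if (newick) paste0(nwk[nid], ";") else NULL,
       root_time = torig[nid])
}

#' Simulate one gene tree under the multispecies coalescent
#'
#' Draws a coalescent genealogy for one locus along a species tree, one
#' haploid lineage per species. Larger ancestral population multipliers give
#' longer coalescent waits, hence more incomplete lineage sorting and more
#' topological discordance.
#'
#' @param tree A `"species_tree"` (ultrametric).
#' @param condition Optional [ils_condition()]; its multiplier replaces the
#'   tree's ancestral multipliers.
#' @param seed Optional RNG seed; if `NULL` the current RNG stream is used.
#' @return An object of class `"gene_tree"`: fields `phy` (the genealogy as a
#'   `"phylo"`), `key` (canonical topology key), `root_time` (time of the
#'   final coalescence, coalescent units before present), `branch_mask` /
#'   `branch_len` (per-branch descendant-species bitmasks and lengths, used
#'   by the mutation layer) and `species` (tip labels; the tip-to-species map
#'   is the identity).
#' @examples
#' gt <- simulate_gene_tree(tree_3taxon(), seed = 1)
#' gt$key
#' @export
simulate_gene_tree <- function(tree, condition = NULL, seed = NULL) {
  st <- apply_condition(as_species_tree(tree), condition)
  plan <- msc_sim_plan(st)
  g <- with_seed(seed, sim_gene_tree_impl(plan, keys = TRUE, newick = TRUE))
  structure(list(phy = parse_newick(g$newick), key = g$key,
                 root_time = g$root_time, branch_mask = g$bmask,
                 branch_len = g$blen, species = plan$tips),
            class = "gene_tree")
}

#' @export
print.gene_tree <- function(x, ...) {
  cat("Gene tree (", length(x$species), " species): ", x$key,
      ", root at ", format(x$root_time, digits = 4),
      " coalescent units\n", sep = "")
  invisible(x)
}

#' Coerce an existing genealogy to the simulator's gene-tree form
#'
#' Computes the per-branch descendant bitmasks needed by
#' [simulate_locus_contributions()] from any rooted, bifurcating,
#' branch-length-bearing `"phylo"`.
#'
#' @param phy A `"phylo"` whose tips are the sampled species.
#' @return A `"gene_tree"`.
#' @export
as_gene_tree <- function(phy) {
  phy <- validate_phylo(phy)
  nt <- length(phy$tip.label)
  nn <- nt + phy$Nnode
  mask <- integer(nn)
  mask[seq_len(nt)] <- bitwShiftL(1L, seq_len(nt) - 1L)
  po <- ape::reorder.phylo(phy, "postorder")
  for (nd in unique(po$edge[, 1L])) {
    kk <- po$edge[po$edge[, 1L] == nd, 2L]
    mask[nd] <- bitwOr(mask[kk[1L]], mask[kk[2L]])
  }
  depths <- ape::node.depth.edgelength(phy)
  structure(list(phy = phy, key = topology_key(phy),
                 root_time = max(depths),
                 branch_mask = mask[phy$edge[, 2L]],
                 branch_len = phy$edge.length,
                 species = phy$tip.label),
            class = "gene_tree")
}

#' Per-species trait contributions from one locus
#'
#' Mutations fall on each gene-tree branch of length l as a Poisson with
#' mean `l * theta / 2`; each mutation's effect is an independent draw from
#' Normal(0, sigma_M2) and is inherited by every species descending from the
#' branch (ancestral alleles contribute 0). Branch totals are drawn
#' equivalently as Normal(0, n_mutations * sigma_M2).
#'
#' @param gtree A `"gene_tree"`.
#' @param model A [mutation_model()]; `sigma_M2` is used as given (apply the
#'   per-locus 1/L scaling upstream if simulating an L-locus trait).
#' @param seed Optional RNG seed.
#' @return Named numeric vector: one trait contribution per species.
#' @export
simulate_locus_contributions <- function(gtree, model, seed = NULL) {
  stopifnot(inherits(gtree, "gene_tree"), inherits(model, "mutation_model"))
  with_seed(seed, {
    nmut <- stats::rpois(length(gtree$branch_len),
                         gtree$branch_len * model$theta / 2)
    eff <- stats::rnorm(length(nmut), 0, sqrt(nmut * model$sigma_M2))
    contrib <- vapply(seq_along(gtree$species), function(j) {
      sum(eff[bitwAnd(gtree$branch_mask, bitwShiftL(1L, j - 1L)) != 0L])
    }, numeric(1L))
    names(contrib) <- gtree$species
    contrib
  })
}

#' Simulate a replicate-by-species trait dataset under the MSC
#'
#' For each replicate, `n_loci` independent gene trees are drawn along the
#' species tree (with the condition's ancestral multiplier applied) and the
#' per-species mutational contributions of all loci are summed into one trait
#' value per species. Per-mutation effect variance is `sigma_M2 / n_loci`
#' (infinitesimal scaling), so expected trait variances and covariances do
#' not depend on the number of loci.
#'
#' @param tree A `"species_tree"` (ultrametric).
#' @param condition An [ils_condition()], or `NULL` for the baseline tree.
#' @param n_loci Number of loci controlling the trait.
#' @param model A [mutation_model()] (its `n_loci` field is ignored here).
#' @param n_replicates Number of independent trait replicates.
#' @param seed Root RNG seed; per-replicate seeds are spawned from it and
#'   stored, so the dataset is bit-for-bit reproducible.
#' @param store_keys Keep the per-locus gene-tree topology keys (needed by
#'   [empirical_discordance()]).
#' @return An object of class `"trait_dataset"`: `values` (replicate x
#'   species matrix), `condition`, `n_loci`, `theta`, `sigma_M2`, `seed`,
#'   `replicate_seeds`, `topology_keys` (replicate x locus matrix or `NULL`)
#'   and `species_key` (the species tree's topology key).
#' @examples
#' ds <- simulate_trait_dataset(tree_3taxon(), NULL, n_loci = 5,
#'                              n_replicates = 10, seed = 1)
#' summary_moments(ds)$vcv
#' @export
simulate_trait_dataset <- function(tree, condition = NULL, n_loci = 25L,
                                   model = mutation_model(),
                                   n_replicates = 1000L, seed = NULL,
                                   store_keys = TRUE) {
  stopifnot(n_loci >= 1L, n_replicates >= 1L)
  st <- apply_condition(as_species_tree(tree), condition)
  plan <- msc_sim_plan(st)
  nt <- plan$nt
  s2_locus <- model$sigma_M2 / n_loci
  theta <- model$theta
  rep_seeds <- with_seed(seed, spawn_seeds(2L * n_replicates))
  values <- matrix(0, n_replicates, nt,
                   dimnames = list(NULL, plan$tips))
  keys <- if (store_keys) matrix(NA_character_, n_replicates, n_loci) else NULL
  bits <- bitwShiftL(1L, seq_len(nt) - 1L)
  for (r in seq_len(n_replicates)) {
    ## separate streams for genealogies and mutations, so the gene trees of a
    ## replicate (hence its discordance) do not depend on theta or sigma_M2
    genes <- with_seed(rep_seeds[2L * r - 1L],
      lapply(seq_len(n_loci), function(l)
        sim_gene_tree_impl(plan, keys = store_keys)))
    vals <- numeric(nt)
    with_seed(rep_seeds[2L * r], {
      for (l in seq_len(n_loci)) {
        g <- genes[[l]]
        nmut <- stats::rpois(length(g$blen), g$blen * theta / 2)
        eff <- stats::rnorm(length(nmut), 0, sqrt(nmut * s2_locus))
        for (j in seq_len(nt))
          vals[j] <- vals[j] + sum(eff[bitwAnd(g$bmask, bits[j]) != 0L])
        if (store_keys) keys[r, l] <- g$key
      }
    })
    values[r, ] <- vals
  }
  structure(list(values = values,
                 condition = condition, n_loci = as.integer(n_loci),
                 theta = theta, sigma_M2 = model$sigma_M2,
                 seed = seed, replicate_seeds = rep_seeds,
                 topology_keys = keys,
                 species_key = topology_key(st$phy)),
            class = "trait_dataset")
}

#' @export
print.trait_dataset <- function(x, ...) {
  cat("Trait dataset:", nrow(x$values), "replicates x",
      ncol(x$values), "species;", x$n_loci, "loci, theta =", x$theta, "\n")
  if (!is.null(x$condition))
    cat("ILS condition:", x$condition$label,
        "(multiplier", format(x$condition$multiplier, digits = 4), ")\n")
  invisible(x)
}

#' Realized gene-tree discordance of a simulated dataset
#'
#' Fraction of simulated loci (over all replicates) whose gene-tree topology
#' key differs from the species tree's. Independent of the mutation process.
#'
#' @param dataset A `"trait_dataset"` simulated with `store_keys = TRUE`.
#' @return A fraction in `[0, 1]`.
#' @export
empirical_discordance <- function(dataset) {
  stopifnot(inherits(dataset, "trait_dataset"))
  if (is.null(dataset$topology_keys))
    stop("dataset was simulated without stored topology keys", call. = FALSE)
  mean(dataset$topology_keys != dataset$species_key)
}

#' Across-replicate trait moments
#'
#' Sample variances (diagonal) and covariances of trait values across
#' replicates (denominator n - 1), plus the same matrix normalized by the
#' variance of the first species.
#'
#' @param dataset A `"trait_dataset"`, or a replicate x species matrix.
#' @return List with `vcv` and `vcv_normalized`.
#' @export
summary_moments <- function(dataset) {
  values <- if (inherits(dataset, "trait_dataset")) dataset$values else dataset
  if (!is.matrix(values) || nrow(values) < 2L)
    stop("need at least two replicates to compute moments", call. = FALSE)
  S <- stats::cov(values)
  list(vcv = S, vcv_normalized = S / S[1L, 1L])
}
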