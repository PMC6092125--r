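#' One-way ANOVA F statistic for a two-group species partition
#'
#' Treats the species trait values as observations and compares group means
#' with degrees of freedom (1, n - 2). A zero within-group sum of squares
#' with distinct group means yields `Inf` (flagged maximum).
#'
#' @param traits Named numeric vector of species trait values.
#' @param group1 Character vector of tip labels in the first group; the rest
#'   of the species form the second group.
#' @return The F statistic.
#' @examples
#' anova_f(c(A = 1, B = 2, C = 3, D = 4, E = 5), c("A", "B"))  # 9
#' @export
anova_f <- function(traits, group1) {
  if (is.null(names(traits))) stop("'traits' must be named", call. = FALSE)
  if (!all(group1 %in% names(traits)))
    stop("unknown species in 'group1'", call. = FALSE)
  g1 <- names(traits) %in% group1
  n1 <- sum(g1); n2 <- sum(!g1); n <- n1 + n2
  if (n1 < 1L || n2 < 1L || n < 3L)
    stop("both groups must be non-empty and n >= 3", call. = FALSE)
  z <- as.numeric(traits)
  m1 <- mean(z[g1]); m2 <- mean(z[!g1]); gm <- mean(z)
  ssb <- n1 * (m1 - gm)^2 + n2 * (m2 - gm)^2
  ssw <- sum((z[g1] - m1)^2) + sum((z[!g1] - m2)^2)
  if (ssw == 0) {
    if (ssb == 0) stop("all trait values identical: F undefined", call. = FALSE)
    return(Inf)
  }
  (ssb / 1) / (ssw / (n - 2))
}

## F statistics for many trait vectors (rows) at once, one grouping
f_stat_rows <- function(Z, g1) {
  n <- ncol(Z); n1 <- sum(g1); n2 <- n - n1
  Z1 <- Z[, g1, drop = FALSE]; Z2 <- Z[, !g1, drop = FALSE]
  m1 <- rowMeans(Z1); m2 <- rowMeans(Z2); gm <- rowMeans(Z)
  ssb <- n1 * (m1 - gm)^2 + n2 * (m2 - gm)^2
  ssw <- rowSums((Z1 - m1)^2) + rowSums((Z2 - m2)^2)
  ifelse(ssw == 0, Inf, ssb / (ssw / (n - 2)))
}

#' Phylogenetic ANOVA with a simulation-based null
#'
#' The observed F statistic is referred to an empirical null distribution
#' obtained by simulating trait vectors under Brownian motion along the
#' species tree (rate fixed at 1: F is invariant to trait scale) and
#' computing F for each under the same grouping. The p-value uses the
#' add-one rule `p = (1 + #\{F_sim >= F_obs\}) / (1 + n_null_sims)`, so it is
#' never exactly 0; ties count toward rejection.
#'
#' @param tree A `"species_tree"`, `"phylo"`, or Newick string.
#' @param traits Named numeric vector of species trait values.
#' @param group1 Character vector of tip labels in the first group.
#' @param n_null_sims Number of null BM simulations.
#' @param seed Optional RNG seed for the null simulations.
#' @return An object of class `"anova_result"`: `group1`, `f` (observed),
#'   `n_null_sims`, `p_value`.
#' @export
phylo_anova <- function(tree, traits, group1, n_null_sims = 1000L,
                        seed = NULL) {
  st <- as_species_tree(tree)
  stopifnot(n_null_sims >= 1L)
  traits <- traits[st$phy$tip.label]
  f_obs <- anova_f(traits, group1)
  Z <- simulate_bm_traits(st, n_null_sims, sigma2 = 1, seed = seed)
  f_null <- f_stat_rows(Z, colnames(Z) %in% group1)
  p <- (1 + sum(f_null >= f_obs)) / (1 + n_null_sims)
  structure(list(group1 = sort(group1), f = f_obs,
                 n_null_sims = as.integer(n_null_sims), p_value = p),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat("Phylogenetic ANOVA: {", paste(x$group1, collapse = ","),
      "} vs rest; F =", format(x$f, digits = 5),
      "; p =", format(x$p_value, digits = 4),
      "(", x$n_null_sims, "null simulations )\n")
  invisible(x)
}

#' Pair-versus-rest phylogenetic ANOVA screen
#'
#' For each replicate of a five-species dataset, runs the phylogenetic ANOVA
#' for every pair of species against the remaining three (10 groupings) and
#' counts how many tests are significant at `alpha`; returns the
#' across-replicate mean count. One BM null sample (per grouping) is shared
#' across replicates: the null does not depend on the observed data because
#' the simulating rate is fixed and F is scale-invariant.
#'
#' @param tree A five-tip `"species_tree"`.
#' @param dataset A `"trait_dataset"` (or replicate x species matrix).
#' @param alpha Significance level (study value 0.05).
#' @param n_null_sims Null BM simulations per grouping.
#' @param seed Optional RNG seed for the shared null.
#' @return List: `mean_count`, per-replicate `counts`, per-replicate x
#'   grouping `p_values`, `groupings`, `alpha`.
#' @export
count_significant_groupings <- function(tree, dataset, alpha = 0.05,
                                        n_null_sims = 1000L, seed = NULL) {
  st <- as_species_tree(tree)
  tips <- st$phy$tip.label
  if (length(tips) != 5L)
    stop("the pair-versus-rest screen is defined for 5 species", call. = FALSE)
  values <- if (inherits(dataset, "trait_dataset")) dataset$values else dataset
  if (!setequal(colnames(values), tips))
    stop("dataset species do not match the tree", call. = FALSE)
  values <- values[, tips, drop = FALSE]
  pairs <- utils::combn(tips, 2L, simplify = FALSE)
  Z <- simulate_bm_traits(st, n_null_sims, sigma2 = 1, seed = seed)
  P <- matrix(NA_real_, nrow(values), length(pairs))
  colnames(P) <- vapply(pairs, paste, "", collapse = "+")
  for (j in seq_along(pairs)) {
    g1 <- tips %in% pairs[[j]]
    f_null <- sort(f_stat_rows(Z, g1))
    f_obs <- f_stat_rows(values, g1)
    ## p = (1 + #{null >= obs}) / (1 + n): count via binary search
    ge <- n_null_sims - findInterval(f_obs, f_null, left.open = TRUE)
    P[, j] <- (1 + ge) / (1 + n_null_sims)
  }
  counts <- rowSums(P < alpha)
  list(mean_count = mean(counts), counts = counts, p_values = P,
       groupings = pairs, alpha = alpha)
}
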