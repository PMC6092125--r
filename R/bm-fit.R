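#' Pagel's lambda transform of a variance-covariance matrix
#'
#' Multiplies off-diagonal (shared-history) entries by `lambda`, leaving the
#' diagonal unchanged. `lambda = 1` is pure Brownian motion on the tree,
#' `lambda = 0` a star phylogeny; for an ultrametric-tree matrix the result
#' stays positive semi-definite over the whole interval.
#'
#' @param V A symmetric variance-covariance matrix.
#' @param lambda Scalar in `[0, 1]`.
#' @return The transformed matrix.
#' @export
lambda_transform <- function(V, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1)
    stop("'lambda' must lie in [0, 1]", call. = FALSE)
  W <- V * lambda
  diag(W) <- diag(V)
  W
}

## traits as a vector ordered like the tree's tips
align_traits <- function(st, traits) {
  tips <- st$phy$tip.label
  if (!is.null(names(traits))) {
    if (!all(tips %in% names(traits)))
      stop("traits must cover every tip label", call. = FALSE)
    traits <- traits[tips]
  } else if (length(traits) != length(tips)) {
    stop("traits must be named or match the number of tips", call. = FALSE)
  }
  if (anyNA(traits)) stop("missing trait values", call. = FALSE)
  as.numeric(traits)
}

chol_or_stop <- function(V) {
  tryCatch(chol(V), error = function(e)
    stop("covariance matrix is not positive definite (singular fit): ",
         conditionMessage(e), call. = FALSE))
}

#' Brownian-motion log-likelihood on a species tree
#'
#' Multivariate-normal log-density of one trait value per species, with mean
#' `root_state` and covariance `lambda_transform(bm_vcv(tree, sigma2),
#' lambda)`.
#'
#' @param tree A `"species_tree"`, `"phylo"`, or Newick string.
#' @param traits Named numeric vector of species trait values.
#' @param sigma2 BM rate (> 0).
#' @param root_state Ancestral (root) trait value.
#' @param lambda Pagel's lambda in `[0, 1]`.
#' @return The log-likelihood.
#' @export
bm_loglik <- function(tree, traits, sigma2, root_state, lambda = 1) {
  st <- as_species_tree(tree)
  z <- align_traits(st, traits)
  if (!is.numeric(sigma2) || sigma2 <= 0)
    stop("'sigma2' must be positive", call. = FALSE)
  V <- lambda_transform(bm_vcv(st, sigma2), lambda)
  L <- chol_or_stop(V)
  u <- backsolve(L, z - root_state, transpose = TRUE)
  -0.5 * (length(z) * log(2 * pi) + 2 * sum(log(diag(L))) + sum(u^2))
}

## Closed-form ML root state and rate on a fixed (possibly
## lambda-transformed) relatedness matrix; loglik at the optimum.
ml_on_matrix <- function(Tm, z) {
  L <- chol_or_stop(Tm)
  n <- length(z)
  a <- backsolve(L, z, transpose = TRUE)
  b <- backsolve(L, rep(1, n), transpose = TRUE)
  m <- sum(a * b) / sum(b * b)
  q <- sum((a - m * b)^2)            # (z - m1)' T^-1 (z - m1)
  logdetT <- 2 * sum(log(diag(L)))
  if (q <= 0) {
    return(list(root_state = m, sigma2 = 0, loglik = Inf, degenerate = TRUE))
  }
  s2 <- q / n
  ll <- -0.5 * (n * log(2 * pi) + n * log(s2) + logdetT + n)
  list(root_state = m, sigma2 = s2, loglik = ll, degenerate = FALSE)
}

new_bm_fit <- function(fit, lambda = NA_real_) {
  structure(list(root_state = fit$root_state, sigma2 = fit$sigma2,
                 lambda = lambda, loglik = fit$loglik,
                 degenerate = fit$degenerate),
            class = "bm_fit")
}

#' @export
print.bm_fit <- function(x, ...) {
  cat("BM fit: root =", format(x$root_state, digits = 5),
      " sigma2 =", format(x$sigma2, digits = 5),
      if (!is.na(x$lambda)) paste(" lambda =", format(x$lambda, digits = 5)),
      " loglik =", format(x$loglik, digits = 7), "\n")
  invisible(x)
}

#' Maximum-likelihood Brownian-motion rate
#'
#' ML estimates of the ancestral state and the BM rate `sigma2` for one trait
#' observation per species on a fixed species tree:
#' `root = (1' T^-1 z) / (1' T^-1 1)` and
#' `sigma2 = (z - m 1)' T^-1 (z - m 1) / n` (ML denominator `n`, matching the
#' usual ML fit; expected value `(n-1)/n * sigma2_true` under the model).
#'
#' @param tree A `"species_tree"`, `"phylo"`, or Newick string (>= 3 tips).
#' @param traits Named numeric vector of species trait values.
#' @return A `"bm_fit"` (with `lambda = NA`). Identical trait values give
#'   `sigma2 = 0` with `loglik = Inf` and `degenerate = TRUE`.
#' @export
fit_sigma2 <- function(tree, traits) {
  st <- as_species_tree(tree)
  if (length(st$phy$tip.label) < 3L)
    stop("need at least 3 species", call. = FALSE)
  z <- align_traits(st, traits)
  new_bm_fit(ml_on_matrix(bm_vcv(st, 1), z))
}

#' Joint maximum-likelihood estimation of Pagel's lambda and the BM rate
#'
#' Profiles lambda over `[0, 1]`: for each lambda the root state and rate
#' have closed-form ML solutions on the transformed matrix; lambda itself is
#' maximized by bounded scalar optimization (tolerance 1e-8), with the
#' endpoints checked explicitly so boundary optima are returned exactly.
#'
#' @param tree A `"species_tree"`, `"phylo"`, or Newick string (>= 4 tips).
#' @param traits Named numeric vector of species trait values.
#' @return A `"bm_fit"` with `lambda` set.
#' @export
fit_lambda_sigma2 <- function(tree, traits) {
  st <- as_species_tree(tree)
  if (length(st$phy$tip.label) < 4L)
    stop("need at least 4 species to profile lambda", call. = FALSE)
  z <- align_traits(st, traits)
  Tm <- bm_vcv(st, 1)
  prof <- function(lam) ml_on_matrix(lambda_transform(Tm, lam), z)$loglik
  opt <- stats::optimize(prof, c(0, 1), maximum = TRUE, tol = 1e-8)
  cand <- c(opt$maximum, 0, 1)
  ll <- c(opt$objective, prof(0), prof(1))
  lam <- cand[which.max(ll)]
  new_bm_fit(ml_on_matrix(lambda_transform(Tm, lam), z), lambda = lam)
}

#' Simulate Brownian-motion trait vectors on a species tree
#'
#' Draws replicate multivariate-normal trait vectors with covariance
#' `sigma2 * T` (optionally lambda-transformed) and mean `root_state`.
#'
#' @param tree A `"species_tree"`, `"phylo"`, or Newick string.
#' @param n Number of replicate trait vectors.
#' @param sigma2 BM rate.
#' @param root_state Mean trait value.
#' @param lambda Pagel's lambda for the simulating covariance.
#' @param seed Optional RNG seed.
#' @return An `n` x `n_species` matrix with species as columns.
#' @export
simulate_bm_traits <- function(tree, n, sigma2 = 1, root_state = 0,
                               lambda = 1, seed = NULL) {
  st <- as_species_tree(tree)
  V <- lambda_transform(bm_vcv(st, sigma2), lambda)
  L <- chol_or_stop(V)
  with_seed(seed, {
    Z <- matrix(stats::rnorm(n * ncol(V)), n, ncol(V)) %*% L
    colnames(Z) <- colnames(V)
    Z + root_state
  })
}
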