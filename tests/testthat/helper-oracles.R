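## Independent oracles and small utilities shared across tests.

## Brute-force parsimony: minimize changes over all assignments of states to
## internal nodes (any root state). Oracle for fitch_score on small trees.
fitch_brute <- function(phy, states) {
  nt <- length(phy$tip.label)
  nn <- phy$Nnode
  s <- integer(nt + nn)
  s[seq_len(nt)] <- as.integer(states[phy$tip.label])
  best <- Inf
  for (code in 0:(2^nn - 1)) {
    s[(nt + 1):(nt + nn)] <- bitwAnd(bitwShiftR(code, seq_len(nn) - 1L), 1L)
    changes <- sum(s[phy$edge[, 1]] != s[phy$edge[, 2]])
    best <- min(best, changes)
  }
  best
}

## Standard error of a sample variance of (approximately) normal data
se_var <- function(v, n) v * sqrt(2 / (n - 1))

## Standard error of a sample covariance, from the theoretical moments
## (exact for Gaussian data)
se_cov <- function(vi, vj, cij, n) sqrt((vi * vj + cij^2) / (n - 1))

## Empirical (fourth-moment) standard error of a sample covariance or
## variance: consistent for non-Gaussian data such as finite-locus
## compound-Poisson trait values, whose kurtosis inflates the Monte-Carlo
## error beyond the Gaussian formula.
se_mom_emp <- function(x, y = x) {
  stats::sd((x - mean(x)) * (y - mean(y))) / sqrt(length(x))
}

## Random child-order rotations that preserve the rooted topology
rotate_randomly <- function(phy, times = 1) {
  nt <- length(phy$tip.label)
  for (i in seq_len(times)) {
    nd <- sample((nt + 1):(nt + phy$Nnode), 1)
    phy <- ape::rotate(phy, nd)
  }
  phy
}

five_taxon_phy <- function() parse_newick("((((A:1,B:1):4,C:5):4,D:9):4,E:13);")
three_taxon_phy <- function() parse_newick("((A:1,B:1):4,C:5);")
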