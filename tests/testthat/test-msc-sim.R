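test_that("gene-tree simulation matches the analytic topology distribution", {
  set.seed(101)
  n <- 20000
  keys <- replicate(n, simulate_gene_tree(tree_3taxon())$key)
  disc <- mean(keys != "((A,B),C)")
  p_disc <- 2 / 3 * exp(-4)
  expect_lt(abs(disc - p_disc), 3 * sqrt(p_disc * (1 - p_disc) / n))

  ## panmixia limit: all three topologies equally likely
  keys_pan <- replicate(n, simulate_gene_tree(tree_3taxon(1e6))$key)
  freq <- table(keys_pan) / n
  expect_equal(length(freq), 3L)
  for (p in freq) expect_lt(abs(p - 1 / 3), 3 * sqrt(2 / 9 / n))
})

test_that("two-lineage coalescence time is species divergence plus Exp(1)", {
  st2 <- species_tree("(A:1,B:1);")
  set.seed(5)
  n <- 20000
  rt <- replicate(n, simulate_gene_tree(st2)$root_time)
  expect_true(all(rt > 1))        # never earlier than the species divergence
  expect_lt(abs(mean(rt) - 2), 3 / sqrt(n))   # sd of 1 + Exp(1) is 1
})

test_that("gene trees respect species-tree divergence times", {
  set.seed(9)
  for (i in 1:50) {
    gt <- simulate_gene_tree(tree_5taxon(2))
    phy <- gt$phy
    expect_true(ape::is.binary(phy))
    expect_setequal(phy$tip.label, c("A", "B", "C", "D", "E"))
    ## A,B cannot coalesce below their species divergence at time 1
    d <- ape::node.depth.edgelength(phy)
    h <- max(d)
    mrca_ab <- ape::getMRCA(phy, c("A", "B"))
    expect_gte(h - d[mrca_ab], 1 - 1e-9)
    ## every coalescence is at or above the root of the two species' MRCA
    mrca_ae <- ape::getMRCA(phy, c("A", "E"))
    expect_gte(h - d[mrca_ae], 13 - 1e-9)
  }
})

test_that("locus contributions are compound Poisson with the right moments", {
  ## star genealogy with two tips, branch lengths 1, theta = 4, sigma_M2 = 1:
  ## each species variance = (theta/2)*l*sigma_M2 = 2, covariance 0
  gt <- as_gene_tree(parse_newick("(A:1,B:1);"))
  model <- mutation_model(theta = 4, sigma_M2 = 1)
  set.seed(31)
  n <- 20000
  M <- t(replicate(n, simulate_locus_contributions(gt, model)))
  v <- diag(stats::cov(M))
  ## Var of a variance estimate of a compound-Poisson sum: use kurtosis-free
  ## 3-SE normal bound scaled up, plus exact covariance SE
  for (j in 1:2) expect_lt(abs(v[j] - 2), 5 * se_var(2, n))
  expect_lt(abs(stats::cov(M)[1, 2]), 3 * se_cov(2, 2, 0, n))

  ## degenerate models give exactly zero
  expect_equal(unname(simulate_locus_contributions(
    gt, mutation_model(theta = 0, sigma_M2 = 1))), c(0, 0))
  expect_equal(unname(simulate_locus_contributions(
    gt, mutation_model(theta = 4, sigma_M2 = 0))), c(0, 0))
})

test_that("trait datasets are deterministic given their seed", {
  a <- simulate_trait_dataset(tree_3taxon(), NULL, n_loci = 5,
                              n_replicates = 4, seed = 99)
  b <- simulate_trait_dataset(tree_3taxon(), NULL, n_loci = 5,
                              n_replicates = 4, seed = 99)
  expect_identical(a$values, b$values)
  expect_identical(a$topology_keys, b$topology_keys)
  c1 <- simulate_trait_dataset(tree_3taxon(), NULL, n_loci = 5,
                               n_replicates = 4, seed = 100)
  expect_false(identical(a$values, c1$values))
})

test_that("realized discordance is independent of the mutation process", {
  d1 <- simulate_trait_dataset(tree_3taxon(), NULL, n_loci = 10,
                               model = mutation_model(theta = 4),
                               n_replicates = 50, seed = 7)
  d2 <- simulate_trait_dataset(tree_3taxon(), NULL, n_loci = 10,
                               model = mutation_model(theta = 0.4),
                               n_replicates = 50, seed = 7)
  expect_identical(d1$topology_keys, d2$topology_keys)
  expect_identical(empirical_discordance(d1), empirical_discordance(d2))
  nokeys <- simulate_trait_dataset(tree_3taxon(), NULL, n_loci = 2,
                                   n_replicates = 2, seed = 1,
                                   store_keys = FALSE)
  expect_error(empirical_discordance(nokeys), "keys")
})

test_that("calibrated conditions hit their target discordance", {
  cond <- ils_condition(0.30, calibrate_multiplier(4, 0.30))
  ds <- simulate_trait_dataset(tree_3taxon(), cond, n_loci = 25,
                               n_replicates = 600, seed = 13)
  n_loci_total <- 600 * 25
  expect_lt(abs(empirical_discordance(ds) - 0.30),
            3 * sqrt(0.3 * 0.7 / n_loci_total))
})

test_that("across-replicate moments match the closed-form aggregates", {
  model <- mutation_model(theta = 4, sigma_M2 = 1)
  n <- 1500
  ds <- simulate_trait_dataset(tree_3taxon(), NULL, n_loci = 25,
                               model = model, n_replicates = n, seed = 2024)
  S <- summary_moments(ds)$vcv
  E <- coal_vcv_3taxon(tree_3taxon(), model)
  V <- ds$values
  expect_lt(abs(S["A", "A"] - E["A", "A"]), 3 * se_mom_emp(V[, "A"]))
  expect_lt(abs(S["A", "B"] - E["A", "B"]),
            3 * se_mom_emp(V[, "A"], V[, "B"]))
  expect_lt(abs(S["A", "C"] - E["A", "C"]),
            3 * se_mom_emp(V[, "A"], V[, "C"]))
  ## exchangeability of the two non-sister covariances
  expect_lt(abs(S["A", "C"] - S["B", "C"]),
            6 * se_mom_emp(V[, "A"], V[, "C"]))
})

test_that("locus count does not change the trait moments", {
  model <- mutation_model(theta = 4, sigma_M2 = 1)
  n <- 1200
  s5 <- summary_moments(simulate_trait_dataset(
    tree_3taxon(), NULL, n_loci = 5, model = model,
    n_replicates = n, seed = 5, store_keys = FALSE))$vcv
  s100 <- summary_moments(simulate_trait_dataset(
    tree_3taxon(), NULL, n_loci = 100, model = model,
    n_replicates = n, seed = 6, store_keys = FALSE))$vcv
  E <- coal_vcv_3taxon(tree_3taxon(), model)
  ## L = 5 traits have noticeable excess kurtosis: allow 6 Gaussian-formula
  ## SEs on the difference of the two independent estimates
  expect_lt(abs(s5["A", "A"] - s100["A", "A"]),
            6 * se_var(E["A", "A"], n))
  expect_lt(abs(s5["A", "B"] - s100["A", "B"]),
            6 * se_cov(E["A", "A"], E["B", "B"], E["A", "B"], n))
})

test_that("summary_moments handles edge cases", {
  constant <- matrix(1, 5, 3, dimnames = list(NULL, c("A", "B", "C")))
  expect_equal(unname(summary_moments(constant)$vcv), matrix(0, 3, 3))
  expect_error(summary_moments(constant[1, , drop = FALSE]), "two replicates")
})
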