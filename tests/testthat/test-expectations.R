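unit_model <- mutation_model(theta = 2, sigma_M2 = 1)  # prefactor 1

test_that("bm_vcv reproduces the worked matrices on both fixtures", {
  V <- bm_vcv(tree_3taxon(), 1)
  expect_equal(unname(diag(V)), rep(5, 3))
  expect_equal(V["A", "B"], 4)
  expect_equal(V["A", "C"], 0)
  expect_equal(V["B", "C"], 0)

  expect_equal(unname(bm_vcv(tree_3taxon(), 0)), matrix(0, 3, 3))

  V5 <- bm_vcv(tree_5taxon(), 1)
  expect_equal(unname(diag(V5)), rep(13, 5))
  expect_equal(V5["A", "B"], 12)
  expect_equal(unname(V5[c("A", "B"), "C"]), c(8, 8))
  expect_equal(unname(V5[c("A", "B", "C"), "D"]), c(4, 4, 4))
  expect_equal(unname(V5[c("A", "B", "C", "D"), "E"]), rep(0, 4))
})

test_that("coalescent variance matches the printed value and simplification", {
  expect_equal(round(coal_var(4, 1, unit_model)), 6)
  expect_equal(coal_var(4, 1, unit_model), 1 + 4 + 1 + exp(-4) / 3)
  ## outgroup form drops the x path terms; ultrametric exchangeability
  expect_equal(coal_var(4, 5, unit_model, outgroup = TRUE),
               coal_var(4, 1, unit_model))
  for (x in c(0, 0.3, 1, 2.5, 7)) {
    expect_equal(coal_var(x, 1, unit_model), 1 + x + 1 + exp(-x) / 3,
                 tolerance = 1e-12)
    expect_equal(coal_var(x, 5, unit_model, outgroup = TRUE),
                 5 + 1 + exp(-x) / 3, tolerance = 1e-12)
  }
  expect_error(coal_var(-1, 1, unit_model), "non-negative")
  expect_error(coal_var(1, -1, unit_model), "non-negative")
})

test_that("sister covariance: printed form equals x + exp(-x)/3 times prefactor", {
  expect_equal(round(coal_cov_sisters(4, unit_model)), 4)
  set.seed(3)
  for (x in c(0, 10^runif(1000, -3, 1))) {
    expect_equal(coal_cov_sisters(x, unit_model), x + exp(-x) / 3,
                 tolerance = 1e-12)
  }
  ## removable singularity at x = 0
  expect_equal(coal_cov_sisters(0, unit_model), 1 / 3)
  expect_equal(coal_cov_nonsisters(0, unit_model), 1 / 3)
})

test_that("non-sister covariance vanishes without ILS and separation is exact", {
  expect_equal(coal_cov_nonsisters(Inf, unit_model), 0)
  expect_equal(coal_cov_nonsisters(4, unit_model), exp(-4) / 3)
  for (x in c(0, 0.5, 2, 4, 9)) {
    expect_equal(coal_cov_sisters(x, unit_model) -
                   coal_cov_nonsisters(x, unit_model), x, tolerance = 1e-12)
  }
  ## no-ILS equivalence with BM: Cov(A,B) -> internal branch length
  expect_equal(coal_cov_sisters(4, unit_model), bm_vcv(tree_3taxon(), 1)["A", "B"],
               tolerance = 1e-2)
  expect_equal(coal_cov_sisters(50, unit_model), 50, tolerance = 1e-12)
})

test_that("coal_vcv_3taxon assembles a symmetric exchangeable matrix", {
  V <- coal_vcv_3taxon(tree_3taxon(), unit_model)
  expect_equal(V, t(V))
  expect_equal(unname(diag(V)), rep(6 + exp(-4) / 3, 3))
  expect_equal(V["A", "B"], 4 + exp(-4) / 3)
  expect_equal(V["A", "C"], exp(-4) / 3)
  expect_equal(V["A", "C"], V["B", "C"])
  ## PSD
  expect_gte(min(eigen(V, symmetric = TRUE)$values), -1e-9)
  ## exchangeability of variances for every multiplier
  for (f in c(1, 2, 10, 1e6)) {
    Vf <- coal_vcv_3taxon(tree_3taxon(f), unit_model)
    expect_equal(max(diag(Vf)) - min(diag(Vf)), 0, tolerance = 1e-12)
  }
  ## panmixia limit: off-diagonals converge to f/3 * prefactor scale
  Vinf <- coal_vcv_3taxon(tree_3taxon(1e8), unit_model)
  off <- Vinf[upper.tri(Vinf)]
  expect_equal(max(off) - min(off), 0, tolerance = 1e-4 * max(off))
  ## zero prefactor
  expect_equal(unname(coal_vcv_3taxon(tree_3taxon(),
                                      mutation_model(theta = 0))),
               matrix(0, 3, 3))
  expect_error(coal_vcv_3taxon(tree_5taxon(), unit_model), "3 species")
})

test_that("three-taxon topology probabilities behave across the x range", {
  expect_equal(unname(topology_probs_3taxon(0)), rep(1 / 3, 3))
  expect_equal(unname(topology_probs_3taxon(Inf)), c(1, 0, 0))
  p4 <- topology_probs_3taxon(4)
  expect_equal(unname(p4[1]), 1 - 2 / 3 * exp(-4))
  expect_equal(unname(p4[2]), exp(-4) / 3)
  xs <- seq(0, 10, by = 0.25)
  probs <- t(vapply(xs, topology_probs_3taxon, numeric(3)))
  expect_equal(rowSums(probs), rep(1, length(xs)))
  expect_true(all(diff(probs[, 1]) > 0))
})

test_that("no-coalescence probability matches the quoted discordance level", {
  expect_equal(round(prob_no_coalescence(4), 2), 0.02)
  expect_equal(prob_no_coalescence(0), 1)
  expect_equal(prob_no_coalescence(log(2)), 0.5)
})

test_that("rooted topology counts follow the double factorial", {
  expect_equal(count_rooted_topologies(3), 3)
  expect_equal(count_rooted_topologies(5), 105)
  expect_equal(count_rooted_topologies(2), 1)
  expect_equal(count_rooted_topologies(6), 945)
  expect_error(count_rooted_topologies(1), ">= 2")
})

test_that("analytic multiplier calibration inverts the discordance curve", {
  expect_equal(calibrate_multiplier(4, 0.6), 4 / (-log(0.9)))
  expect_equal(calibrate_multiplier(4, 0), 1)
  expect_error(calibrate_multiplier(4, 2 / 3), "2/3")
  for (target in c(0.1, 0.15, 0.3, 0.45, 0.6)) {
    f <- calibrate_multiplier(4, target)
    expect_equal(unname(sum(topology_probs_3taxon(4 / f)[2:3])), target,
                 tolerance = 1e-12)
  }
})

test_that("Monte-Carlo calibration agrees with the analytic inversion", {
  f_mc <- calibrate_multiplier_mc(tree_3taxon(), 0.30, n_sims = 20000,
                                  seed = 11)
  f_an <- calibrate_multiplier(4, 0.30)
  ## realized discordance at f_mc must be near the target
  d <- sum(topology_probs_3taxon(4 / f_mc)[2:3])
  expect_lt(abs(d - 0.30), 3 * sqrt(0.3 * 0.7 / 20000) * 2)
  expect_lt(abs(f_mc - f_an) / f_an, 0.1)
  expect_equal(calibrate_multiplier_mc(tree_3taxon(), 0), 1)
  expect_error(calibrate_multiplier_mc(tree_3taxon(), 0.95, n_sims = 2000,
                                       seed = 1), "unreachable")
})
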