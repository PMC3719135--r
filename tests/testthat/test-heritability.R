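test_that("population threshold solves F(t) = 1/2 for the mixture", {
  # all effects zero: symmetric Gaussian around the intercept
  null_spec <- liability_spec(c(0.4, 0.4), c(0, 0))
  expect_equal(population_threshold(null_spec), 20, tolerance = 1e-9)

  # equal effects at maf 0.5: mixture symmetric about b0 + sum(beta) * 1
  sym <- liability_spec(c(0.5, 0.5), c(0.3, 0.3))
  expect_equal(population_threshold(sym), 20 + 0.6, tolerance = 1e-9)

  # matches the empirical median of a large simulation
  spec <- four_common_spec()
  t_analytic <- population_threshold(spec)
  set.seed(17)
  g <- sample_genotypes_hwe(spec$loci, 1e6)
  y <- liability_predictor(spec, g) + rnorm(1e6, 0, sqrt(10))
  expect_equal(t_analytic, median(y), tolerance = 0.02)

  expect_error(population_threshold(liability_spec(rep(0.4, 9), rep(0.1, 9))),
               "at most")
})

test_that("analytic penetrances average to the 50% prevalence", {
  null_spec <- liability_spec(c(0.4, 0.05), c(0, 0))
  pm0 <- analytic_penetrances(null_spec)
  expect_equal(pm0$penetrance, rep(0.5, 9), tolerance = 1e-12)

  spec <- four_common_spec(beta = c(0.2, 0.2, 0.2, 0.5), beta34 = 0.3)
  pm <- analytic_penetrances(spec)
  expect_equal(sum(pm$prob * pm$penetrance), 0.5, tolerance = 1e-10)
  expect_equal(pm$prevalence, 0.5, tolerance = 1e-10)
})

test_that("single-locus heritability follows the small-effect closed form", {
  # H2 -> (2pq beta^2 / Var Y) * (2/pi) as beta -> 0 at 50% prevalence
  spec <- four_common_spec()
  h2 <- h2_single(spec, 3)
  p <- 0.4
  var_y <- 10 + 4 * 2 * p * (1 - p) * 0.2^2
  approx <- (2 * p * (1 - p) * 0.2^2 / var_y) * (2 / pi)
  expect_lt(abs(h2 - approx) / approx, 0.02)

  # null locus contributes nothing
  null_spec <- liability_spec(c(0.4, 0.4), c(0, 0.4))
  expect_equal(h2_single(null_spec, 1), 0, tolerance = 1e-14)

  # relabeling the risk allele leaves H2 unchanged
  flipped <- liability_spec(
    list(locus_spec(0.4), locus_spec(0.4, risk_allele_is_minor = FALSE),
         locus_spec(0.4), locus_spec(0.4)),
    rep(0.2, 4))
  expect_equal(h2_single(flipped, 2), h2_single(spec, 2), tolerance = 1e-5)
})

test_that("pair decomposition identity and monotonicity hold", {
  spec <- four_common_spec(beta34 = 0.3)
  pm <- analytic_penetrances(spec)
  total <- h2_pair(pm, c(3, 4))
  m3 <- h2_marginal(pm, 3)
  m4 <- h2_marginal(pm, 4)
  i34 <- h2_interaction(pm, c(3, 4))
  expect_equal(total, m3 + m4 + i34, tolerance = 1e-12)
  expect_gt(i34, 0)
  expect_gte(total, max(m3, m4))

  # total strictly increases with the two-way coefficient
  totals <- vapply(c(0, 0.2, 0.5), function(b34) {
    h2_pair(four_common_spec(beta34 = b34), c(3, 4))
  }, numeric(1))
  expect_true(all(diff(totals) > 0))

  # with no interaction term the interaction component is ~0 (threshold
  # nonlinearity only)
  i0 <- h2_interaction(four_rare_spec(), c(3, 4))
  expect_lt(abs(i0), 5e-4)
})

test_that("three-way interaction component is the higher-order remainder", {
  spec <- liability_spec(rep(0.4, 3), rep(0.2, 3),
                         interactions = list(interaction_term(1:3, 0.4)))
  pm <- analytic_penetrances(spec)
  total <- h2_group(pm, 1:3)
  marg <- sum(vapply(1:3, function(l) h2_marginal(pm, l), numeric(1)))
  pairw <- sum(vapply(list(c(1, 2), c(1, 3), c(2, 3)), function(pr) {
    h2_interaction(pm, pr)
  }, numeric(1)))
  i123 <- h2_interaction(pm, 1:3)
  expect_equal(total, marg + pairw + i123, tolerance = 1e-12)
  expect_gt(i123, 0)
})

test_that("decomposition assembles group totals with sane defaults", {
  spec <- four_common_spec(beta34 = 0.2)
  dec <- h2_decompose(spec)
  expect_equal(dec$prevalence, 0.5, tolerance = 1e-10)
  # default grouping: interacting pair {3,4}; main-effect pair {1,2}
  expect_setequal(dec$groups$group, c("G3G4", "G1G2"))
  g34 <- dec$groups[dec$groups$group == "G3G4", ]
  expect_equal(g34$h2, g34$h2_marginals + g34$h2_interaction,
               tolerance = 1e-14)
  expect_equal(dec$h2_total, sum(dec$groups$h2), tolerance = 1e-14)
  expect_true(all(dec$marginal >= 0))

  # six-SNP three-way model groups {3,4,5} together
  m38 <- liability_presets()[["sixsnp_threeway"]]
  dec38 <- h2_decompose(m38)
  expect_true("G3G4G5" %in% dec38$groups$group)
  expect_true("G1G2G6" %in% dec38$groups$group)

  expect_error(h2_decompose(spec, groups = list(bad = c(1, 9))), "unknown")
})

test_that("Monte-Carlo oracle agrees with the analytic decomposition", {
  spec <- four_common_spec(beta = c(0.2, 0.2, 0.2, 0.5), beta34 = 0.5,
                           seed = 8)
  groups <- list(G1G2 = c(1, 2), G3G4 = c(3, 4))
  ana <- h2_decompose(spec, groups = groups)
  mc <- mc_h2_decompose(spec, groups = groups, n = 6e5, seed = 12)
  for (i in 1:2) {
    expect_lt(abs(ana$groups$h2[i] - mc$groups$h2[i]),
              3 * mc$se$groups[i] + 2e-5)
  }
  expect_lt(abs(ana$h2_total - mc$h2_total), 3 * mc$se$h2_total + 2e-5)
})

test_that("heritability curves trace the expected relationships", {
  base <- liability_spec(c(0.4, 0.4), c(0.1, 0.1))

  # MAF sweep: monotone increasing on (0, 0.5]
  maf_curve <- h2_curves(base, "MAF", seq(0.05, 0.5, by = 0.05), locus = 2)
  expect_true(all(diff(maf_curve$h2_marginal_2) > 0))

  # RAF sweep: zero at the monomorphic endpoints, rises in between
  raf_curve <- h2_curves(base, "RAF", c(0, 0.25, 0.5, 0.75, 1), locus = 2)
  expect_equal(raf_curve$h2_marginal_2[c(1, 5)], c(0, 0), tolerance = 1e-14)
  expect_gt(raf_curve$h2_marginal_2[3], 0)

  # ES sweep: increasing in the swept effect
  es_curve <- h2_curves(base, "ES", seq(0, 0.5, by = 0.1), locus = 2)
  expect_true(all(diff(es_curve$h2_marginal_2) >= 0))

  # positive interaction sweep: total, marginal and interaction components
  # all increase
  int_curve <- h2_curves(base, "interaction", seq(0, 0.6, by = 0.2))
  expect_true(all(diff(int_curve$h2_total) > 0))
  expect_true(all(diff(int_curve$h2_interaction) > 0))
  expect_true(all(diff(int_curve$h2_marginal_1) > 0))
})

test_that("EV weight tracks single-locus heritability along a RAF sweep", {
  single <- liability_spec(0.25, 0.5)
  sweep <- h2_curves(single, "RAF", seq(0, 1, by = 0.02), locus = 1)
  rho <- cor(sweep$ev_weight, sweep$h2_marginal_1, method = "spearman")
  expect_gt(rho, 0.99)
})
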