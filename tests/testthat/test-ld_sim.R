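test_that("additive penetrance table reproduces the closed-form cells", {
  # no-effect limit: every cell is the baseline
  expect_true(all(additive_penetrance_table(0.1, 1, 1) == 0.1))

  tab <- additive_penetrance_table(0.1, 1.5, 1.5)
  expect_equal(tab["2", "2"], (1.5 + 1.5 - 1) * 0.1) # 0.20
  expect_equal(tab["1", "1"], (1.5 + 1.5) * 0.1 / 2) # 0.15

  tab2 <- additive_penetrance_table(0.1, 1.75, 1.25)
  expect_equal(tab2["2", "0"], 1.75 * 0.1) # theta_a * k
  expect_equal(tab2["0", "2"], 1.25 * 0.1) # theta_b * k
  expect_equal(tab2["0", "0"], 0.1)

  # full Table-1 matrix written out explicitly, as an independent check
  k <- 0.07; ta <- 1.6; tb <- 1.3
  want <- rbind(
    c(k,            (tb + 1) * k / 2,           tb * k),
    c((ta + 1) * k / 2, (ta + tb) * k / 2,      (ta + 2 * tb - 1) * k / 2),
    c(ta * k,       (2 * ta + tb - 1) * k / 2,  (ta + tb - 1) * k)
  )
  got <- additive_penetrance_table(k, ta, tb)
  expect_equal(unname(got), want)
})

test_that("penetrance additivity identity holds exactly for all cells", {
  for (theta in list(c(1.25, 1.75), c(1.5, 1.5), c(1.75, 1.25))) {
    P <- additive_penetrance_table(0.1, theta[1], theta[2])
    for (a in 1:3) for (b in 1:3) {
      expect_equal(P[a, b] - P[a, 1] - P[1, b] + P[1, 1], 0,
                   tolerance = 1e-15)
    }
  }
})

test_that("invalid penetrance models are rejected", {
  expect_error(additive_penetrance_table(0.3, 3, 3), "exceeds 1")
  expect_error(additive_penetrance_table(0, 1.5, 1.5), "k")
  expect_error(additive_penetrance_table(0.1, 0.8, 1.5), ">= 1")
  expect_error(penetrance_spec(k = 0.4, theta = c(2, 2)), "exceeds 1")
})

test_that("LD structures are row-stochastic with the documented modes", {
  p <- 0.4
  hwe <- c(0.36, 0.48, 0.16)
  weak <- ld_structure(p, "weak")
  expect_equal(unname(rowSums(weak$conditional)), rep(1, 3))
  for (i in 1:3) expect_equal(unname(weak$conditional[i, ]), hwe)

  strong <- ld_structure(p, "strong")
  expect_equal(unname(rowSums(strong$conditional)), rep(1, 3))
  expect_equal(unname(diag(strong$conditional)), 0.8 + 0.2 * hwe)

  expect_error(ld_structure(0.4, conditional = matrix(1, 3, 3)),
               "row-stochastic")
  expect_error(ld_structure(0.6, "weak"), "marker_maf")
})

test_that("linked genotypes respect the conditional structure", {
  set.seed(21)
  n <- 120000
  weak <- ld_structure(0.4, "weak")
  g_w <- sample_linked_genotypes(c(0.4, 0.4), weak, n)
  expect_lt(abs(cor(g_w[, 2], g_w[, 3])), 0.02)

  strong <- ld_structure(0.4, "strong")
  g_s <- sample_linked_genotypes(c(0.4, 0.4), strong, n)
  expect_gt(cor(g_s[, 2], g_s[, 3]), 0.5)

  # law of total probability: marginal of G3 = sum_i P(G2 = i) * row_i
  hwe2 <- c(0.36, 0.48, 0.16)
  want <- drop(hwe2 %*% strong$conditional)
  got <- tabulate(g_s[, 3] + 1L, 3) / n
  expect_equal(got, unname(want), tolerance = 0.01)
})

test_that("case-control sampling is balanced, reproducible, marker-neutral", {
  spec <- penetrance_spec(seed = 5, n_replicates = 5)
  ld <- ld_structure(0.4, "strong")
  d1 <- simulate_ld_case_control(spec, ld, 1)
  expect_identical(sum(d1$status), 200L)
  expect_identical(length(d1$status), 400L)
  expect_identical(colnames(d1$genotypes), c("G1", "G2", "G3"))
  d1b <- simulate_ld_case_control(spec, ld, 1)
  expect_identical(d1$genotypes, d1b$genotypes)

  # theta = 1: null model, case and control genotype distributions agree
  null_spec <- penetrance_spec(theta = c(1, 1), n_cases = 2000,
                               n_controls = 2000, seed = 6)
  d0 <- simulate_ld_case_control(null_spec, ld, 1)
  m_case <- colMeans(d0$genotypes[d0$status == 1, ])
  m_ctrl <- colMeans(d0$genotypes[d0$status == 0, ])
  expect_equal(m_case, m_ctrl, tolerance = 0.05)
})

test_that("raw prevalence matches enumeration over the 9-cell joint table", {
  k <- 0.1; theta <- c(1.5, 1.5); p <- c(0.4, 0.4)
  tab <- additive_penetrance_table(k, theta[1], theta[2])
  hwe <- function(q) c((1 - q)^2, 2 * q * (1 - q), q^2)
  pop_prev <- drop(hwe(p[1]) %*% tab %*% hwe(p[2]))

  set.seed(31)
  n <- 200000
  ld <- ld_structure(0.4, "weak")
  g <- sample_linked_genotypes(p, ld, n)
  pen <- tab[cbind(g[, 1] + 1L, g[, 2] + 1L)]
  d <- rbinom(n, 1, pen)
  se <- sqrt(pop_prev * (1 - pop_prev) / n)
  expect_lt(abs(mean(d) - pop_prev), 3 * se + 1e-12)
})

test_that("rejection sampling cap errors out rather than truncating", {
  spec <- penetrance_spec(seed = 1, max_draws = 50,
                          n_cases = 200, n_controls = 200)
  ld <- ld_structure(0.4, "weak")
  expect_error(simulate_ld_case_control(spec, ld, 1), "exhausted")
})

test_that("train/test collections use disjoint seed streams", {
  spec <- penetrance_spec(seed = 9, n_replicates = 10)
  ld <- ld_structure(0.4, "strong")
  study <- make_train_test_study(spec, ld)
  expect_length(study$train, 10)
  expect_length(study$test, 10)
  expect_false(identical(study$train[[1]]$genotypes,
                         study$test[[1]]$genotypes))
  seeds_train <- vapply(study$train, function(d) d$seed_used, 1L)
  seeds_test <- vapply(study$test, function(d) d$seed_used, 1L)
  expect_length(intersect(seeds_train, seeds_test), 0)
})
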