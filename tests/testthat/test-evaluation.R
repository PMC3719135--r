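test_that("C-statistic matches brute force over all case-control pairs", {
  brute_auc <- function(status, scores) {
    cases <- scores[status == 1]
    ctrls <- scores[status == 0]
    tot <- 0
    for (x in cases) for (y in ctrls) {
      tot <- tot + (x > y) + 0.5 * (x == y)
    }
    tot / (length(cases) * length(ctrls))
  }
  status <- c(1, 1, 1, 0, 0, 0)
  scores <- c(1, 2, 3, 0, 1, 2)
  # 6 concordant, 2 ties, 1 discordant out of 9 pairs
  expect_equal(brute_auc(status, scores), 7 / 9)
  expect_equal(c_statistic(status, scores), 7 / 9)

  set.seed(5)
  st <- rep(0:1, each = 25)
  sc <- sample(0:8, 50, replace = TRUE)
  expect_equal(c_statistic(st, sc), brute_auc(st, sc))
})

test_that("degenerate predictors are handled explicitly", {
  status <- rep(0:1, each = 10)
  f_const <- fit_grs_model(status, rep(4, 20))
  expect_equal(f_const$c_statistic, 0.5)
  expect_equal(f_const$lrt_statistic, 0)
  expect_equal(f_const$lrt_pvalue, 1)
  expect_equal(f_const$slope_hat, 0)
  expect_match(f_const$note, "constant")

  # perfectly separating scores: C = 1, flagged
  f_sep <- fit_grs_model(status, c(rep(0, 10), rep(5, 10)))
  expect_equal(f_sep$c_statistic, 1)
  expect_false(f_sep$converged)
  expect_error(fit_grs_model(rep(1L, 5), 1:5), "both cases and controls")
})

test_that("logistic fit statistics are internally consistent", {
  spec <- four_common_spec(beta = c(0.2, 0.2, 0.5, 0.5))
  d <- simulate_liability_dataset(spec, 2)
  f <- fit_grs_model(d, simple_count_score(d))
  expect_equal(f$aic, 2 * 2 - 2 * f$log_likelihood, tolerance = 1e-10)
  expect_gte(f$lrt_statistic, 0)
  # cross-check LRT p against a direct glm/anova computation
  m <- glm(d$status ~ simple_count_score(d), family = binomial())
  want <- anova(m, test = "LRT")[["Pr(>Chi)"]][2]
  expect_equal(f$lrt_pvalue, want, tolerance = 1e-10)
})

test_that("summaries count rejections like the paper's power definition", {
  # counting oracle: 40 of 100 p-values below 0.05 by construction
  fits <- data.frame(
    method = "SC",
    p_value = c(runif(40, 0, 0.049), runif(60, 0.051, 1)),
    c_statistic = rep(0.6, 100), aic = rep(650, 100)
  )
  s <- summarize_fits(fits, alpha = 0.05)
  expect_equal(s$rejection_rate, 0.40)
  expect_equal(s$n_replicates, 100L)
  expect_true(s$ci_low < 0.4 && s$ci_high > 0.4)
})

test_that("equal true weights collapse all methods to identical p-values", {
  spec <- four_common_spec(n_replicates = 5)
  test <- lapply(1:5, function(r) simulate_liability_dataset(spec, r))
  ws <- list(
    OR = grs_weight_set("OR", paste0("G", 1:4), weights = rep(0.2, 4)),
    EV = grs_weight_set("EV", paste0("G", 1:4), weights = rep(0.05, 4))
  )
  ev <- run_study(test, weight_sets = ws)
  wide <- reshape(ev$fits[, c("replicate", "method", "p_value")],
                  direction = "wide", idvar = "replicate",
                  timevar = "method")
  expect_equal(wide$p_value.OR, wide$p_value.SC, tolerance = 1e-9)
  expect_equal(wide$p_value.EV, wide$p_value.SC, tolerance = 1e-9)
})

test_that("run_study validates inputs", {
  expect_error(run_study(list()), "empty")
  spec <- four_common_spec(n_replicates = 2)
  test <- lapply(1:2, function(r) simulate_liability_dataset(spec, r))
  expect_error(run_study(test, methods = c("SC", "OR")), "no weight set")
})

test_that("Tukey contrasts declare winners only for real differences", {
  set.seed(14)
  base <- rnorm(60, 0.6, 0.05)
  scen <- rep(rep(c("s1", "s2", "s3"), each = 20), 3)
  # identical metric vectors for all methods: no significant pairs
  same <- data.frame(method = rep(c("SC", "OR", "EV"), each = 60),
                     scenario = scen, value = rep(base, 3))
  ct_same <- pairwise_method_contrasts(same)
  expect_true(all(ct_same$winner == ""))
  expect_equal(nrow(ct_same), 3)

  # OR uniformly 10 points above SC: OR declared winner over SC
  shifted <- same
  shifted$value[shifted$method == "OR"] <-
    shifted$value[shifted$method == "OR"] + 0.10
  ct <- pairwise_method_contrasts(shifted)
  sc_or <- ct[grepl("OR", ct$pair) & grepl("SC", ct$pair), ]
  expect_equal(sc_or$winner, "OR")

  # with smaller-is-better (AIC-like), the winner flips
  ct_aic <- pairwise_method_contrasts(shifted, larger_is_better = FALSE)
  sc_or2 <- ct_aic[grepl("OR", ct_aic$pair) & grepl("SC", ct_aic$pair), ]
  expect_equal(sc_or2$winner, "SC")
})

test_that("Tukey adjustment never reports smaller p than the plain contrast", {
  set.seed(15)
  oneway <- data.frame(method = rep(c("SC", "OR", "EV"), each = 30),
                       value = rnorm(90, rep(c(0.60, 0.63, 0.61), each = 30),
                                     0.05))
  ct <- pairwise_method_contrasts(oneway)
  raw <- pairwise.t.test(oneway$value, oneway$method, p.adjust.method = "none",
                         pool.sd = TRUE)$p.value
  get_raw <- function(pair) {
    ab <- strsplit(pair, "-", fixed = TRUE)[[1]]
    if (!is.na(raw[ab[1], ab[2]])) raw[ab[1], ab[2]] else raw[ab[2], ab[1]]
  }
  for (i in seq_len(nrow(ct))) {
    expect_gte(ct$p_adj[i], get_raw(ct$pair[i]) - 1e-12)
  }
})
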