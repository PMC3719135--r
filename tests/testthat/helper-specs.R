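# Small shared builders for the test suite.

four_common_spec <- function(beta = rep(0.2, 4), beta34 = 0, seed = 1, ...) {
  ints <- if (beta34 != 0) list(interaction_term(c(3L, 4L), beta34)) else list()
  liability_spec(rep(0.4, 4), beta, interactions = ints, seed = seed, ...)
}

four_rare_spec <- function(beta = rep(0.8, 4), beta34 = 0, seed = 1, ...) {
  ints <- if (beta34 != 0) list(interaction_term(c(3L, 4L), beta34)) else list()
  liability_spec(rep(0.05, 4), beta, interactions = ints, seed = seed, ...)
}

# Genotypes + status from an ordinary logistic generative model (independent
# of the package's own simulators), used as an oracle for weight estimation.
logistic_training <- function(n, p, log_or, intercept = -sum(log_or),
                              seed = 42) {
  set.seed(seed)
  g <- vapply(p, function(pi) stats::rbinom(n, 2, pi), numeric(n))
  colnames(g) <- paste0("G", seq_along(p))
  eta <- intercept + drop(g %*% log_or)
  d <- stats::rbinom(n, 1, stats::plogis(eta))
  grseval:::new_case_control_dataset(
    matrix(as.integer(g), nrow = n, dimnames = dimnames(g)),
    d, replicate = 1L, seed_used = seed, generator = "logistic-oracle")
}
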