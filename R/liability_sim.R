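#' Product-interaction term for the liability model
#'
#' An epistatic term contributing \code{coef * prod(G[loci])} to the latent
#' liability: two indices give a two-way interaction, three a three-way one,
#' and so on.
#'
#' @param loci Integer vector of locus indices (length >= 2, no duplicates).
#' @param coef Finite real coefficient.
#' @return An object of class \code{interaction_term}.
#' @examples
#' interaction_term(c(3, 4), 0.2)   # beta_34
#' interaction_term(c(3, 4, 5), 0.2) # beta_345
#' @export
interaction_term <- function(loci, coef) {
  loci <- as.integer(loci)
  if (length(loci) < 2L || anyDuplicated(loci) > 0L || any(loci < 1L)) {
    stop("interaction 'loci' must be >= 2 distinct positive indices",
         call. = FALSE)
  }
  if (!is.numeric(coef) || length(coef) != 1L || !is.finite(coef)) {
    stop("interaction 'coef' must be a single finite number", call. = FALSE)
  }
  structure(list(loci = loci, coef = as.numeric(coef)),
            class = "interaction_term")
}

#' Specify a liability-threshold generative model
#'
#' The latent trait is
#' \deqn{Y = \beta_0 + \sum_i \beta_i G_i + \sum_T c_T \prod_{i \in T} G_i + e,
#'   \quad e \sim N(0, \sigma^2),}
#' with genotypes \eqn{G_i \in \{0,1,2\}} drawn independently under
#' Hardy-Weinberg equilibrium. Disease status is 1 when \eqn{Y} exceeds the
#' sample median, giving 50\% prevalence by construction.
#'
#' @param loci Numeric vector of MAFs or list of \code{\link{locus_spec}}.
#' @param main_effects Per-locus main-effect coefficients \eqn{\beta_i}.
#' @param interactions List of \code{\link{interaction_term}} objects.
#' @param intercept Liability intercept \eqn{\beta_0}; default 20.
#' @param noise_variance Residual variance \eqn{\sigma^2 > 0}; default 10.
#' @param n_cases,n_controls Subjects per replicate; defaults 250 each.
#' @param n_replicates Number of replicates in a study; default 100.
#' @param seed Root seed for the study; default 1.
#' @return An object of class \code{liability_spec}.
#' @examples
#' liability_spec(rep(0.4, 4), main_effects = rep(0.2, 4),
#'                interactions = list(interaction_term(c(3, 4), 0.2)))
#' @export
liability_spec <- function(loci, main_effects,
                           interactions = list(),
                           intercept = 20, noise_variance = 10,
                           n_cases = 250, n_controls = 250,
                           n_replicates = 100, seed = 1) {
  loci <- as_loci(loci)
  L <- length(loci)
  if (L == 0L) stop("at least one locus is required", call. = FALSE)
  if (length(main_effects) != L) {
    stop("'main_effects' must have one coefficient per locus", call. = FALSE)
  }
  if (!all(is.finite(main_effects))) {
    stop("'main_effects' must be finite", call. = FALSE)
  }
  if (inherits(interactions, "interaction_term")) {
    interactions <- list(interactions)
  }
  if (!all(vapply(interactions, inherits, TRUE, "interaction_term"))) {
    stop("'interactions' must be a list of interaction_term objects",
         call. = FALSE)
  }
  for (term in interactions) {
    if (any(term$loci > L)) {
      stop("interaction term references a locus beyond the model",
           call. = FALSE)
    }
  }
  if (!is.numeric(noise_variance) || noise_variance <= 0) {
    stop("'noise_variance' must be > 0", call. = FALSE)
  }
  if (n_cases < 1 || n_controls < 1 || n_replicates < 1) {
    stop("'n_cases', 'n_controls', 'n_replicates' must be positive",
         call. = FALSE)
  }
  structure(
    list(loci = loci, intercept = as.numeric(intercept),
         main_effects = as.numeric(main_effects),
         interactions = interactions,
         noise_variance = as.numeric(noise_variance),
         n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
         n_replicates = as.integer(n_replicates), seed = as.integer(seed)),
    class = "liability_spec"
  )
}

#' @export
print.liability_spec <- function(x, ...) {
  cat(sprintf("Liability-threshold model: %d loci, beta0 = %g, sigma^2 = %g\n",
              length(x$loci), x$intercept, x$noise_variance))
  cat(sprintf("  MAF: %s\n",
              paste(vapply(x$loci, function(l) format(l$maf), ""),
                    collapse = ", ")))
  cat(sprintf("  main effects: %s\n",
              paste(format(x$main_effects), collapse = ", ")))
  if (length(x$interactions)) {
    for (term in x$interactions) {
      cat(sprintf("  interaction (%s): coef %g\n",
                  paste(term$loci, collapse = ","), term$coef))
    }
  } else {
    cat("  no interaction terms\n")
  }
  cat(sprintf("  %d cases + %d controls x %d replicates, seed %d\n",
              x$n_cases, x$n_controls, x$n_replicates, x$seed))
  invisible(x)
}

#' Sample genotype matrices under Hardy-Weinberg equilibrium
#'
#' Each locus is drawn independently with genotype probabilities
#' \eqn{((1-p)^2, 2p(1-p), p^2)} for risk-allele counts (0, 1, 2), where
#' \eqn{p} is the locus's risk allele frequency. Uses R's global random
#' number generator; call \code{set.seed} for reproducibility.
#'
#' @param loci Numeric vector of MAFs or list of \code{\link{locus_spec}}.
#' @param n Number of subjects.
#' @return An \code{n x L} integer matrix of risk-allele counts.
#' @examples
#' set.seed(1)
#' g <- sample_genotypes_hwe(c(0.4, 0.05), 1000)
#' colMeans(g) / 2 # close to the RAFs
#' @export
sample_genotypes_hwe <- function(loci, n) {
  loci <- as_loci(loci)
  if (n < 1) stop("'n' must be >= 1", call. = FALSE)
  p <- rafs(loci)
  g <- vapply(p, function(pi) {
    sample(0:2, n, replace = TRUE,
           prob = c((1 - pi)^2, 2 * pi * (1 - pi), pi^2))
  }, integer(n))
  g <- matrix(as.integer(g), nrow = n)
  colnames(g) <- locus_ids(loci)
  g
}

#' Latent liability linear predictor
#'
#' Evaluates \eqn{\mu = \beta_0 + \sum \beta_i G_i + \sum_T c_T \prod G_{T}}
#' (the noiseless part of the liability) for each row of a genotype matrix.
#'
#' @param spec A \code{\link{liability_spec}}.
#' @param genotypes Subjects-by-loci matrix of 0/1/2 risk-allele counts.
#' @return Numeric vector of per-subject expected liabilities.
#' @export
liability_predictor <- function(spec, genotypes) {
  stopifnot(inherits(spec, "liability_spec"))
  genotypes <- as.matrix(genotypes)
  if (ncol(genotypes) != length(spec$loci)) {
    stop("genotype matrix has wrong number of loci", call. = FALSE)
  }
  mu <- spec$intercept + drop(genotypes %*% spec$main_effects)
  for (term in spec$interactions) {
    prod_term <- genotypes[, term$loci[1]]
    for (j in term$loci[-1]) prod_term <- prod_term * genotypes[, j]
    mu <- mu + term$coef * prod_term
  }
  mu
}

new_case_control_dataset <- function(genotypes, status, replicate, seed_used,
                                     generator, phenotype = NULL) {
  structure(
    list(genotypes = genotypes, status = as.integer(status),
         phenotype = phenotype, replicate = as.integer(replicate),
         seed_used = seed_used, generator = generator),
    class = "case_control_dataset"
  )
}

#' @export
print.case_control_dataset <- function(x, ...) {
  cat(sprintf("case_control_dataset (%s): %d subjects (%d cases), %d loci, replicate %d\n",
              x$generator, length(x$status), sum(x$status),
              ncol(x$genotypes), x$replicate))
  invisible(x)
}

#' Simulate one case-control replicate from the liability-threshold model
#'
#' Draws \code{n_cases + n_controls} subjects, computes the latent trait per
#' \code{\link{liability_predictor}} plus Gaussian noise, and assigns case
#' status \code{D = 1} when the trait strictly exceeds the replicate's
#' empirical median. With an even subject count and continuous noise this
#' yields exactly 50\% cases (ties, a probability-zero event, break toward
#' control).
#'
#' @param spec A \code{\link{liability_spec}}.
#' @param replicate Replicate index (determines the child seed).
#' @return A \code{case_control_dataset}.
#' @examples
#' spec <- liability_spec(rep(0.4, 4), rep(0.2, 4))
#' d <- simulate_liability_dataset(spec, replicate = 1)
#' mean(d$status) # exactly 0.5
#' @export
simulate_liability_dataset <- function(spec, replicate = 1L) {
  stopifnot(inherits(spec, "liability_spec"))
  seed <- derive_seed(spec$seed, stream = 1L, index = replicate)
  set.seed(seed)
  n <- spec$n_cases + spec$n_controls
  g <- sample_genotypes_hwe(spec$loci, n)
  y <- liability_predictor(spec, g) +
    stats::rnorm(n, 0, sqrt(spec$noise_variance))
  status <- as.integer(y > stats::median(y))
  new_case_control_dataset(g, status, replicate, seed, "liability",
                           phenotype = y)
}

#' Named scenario presets for the liability simulator
#'
#' Builds the full grid of shipped scenarios: two causal-architecture
#' scenarios (scenario 1: all four SNPs causal; scenario 2: SNPs 1-2 pure
#' noise, SNPs 3-4 causal), three MAF patterns (all common 0.4, all rare
#' 0.05, and mixed with SNPs 1 and 3 common / SNPs 2 and 4 rare), equal vs
#' unequal main effects, and three interaction strengths for the SNP 3 x
#' SNP 4 term. Two six-SNP follow-up models are included: one with two
#' two-way interactions (3x4 and 5x6) and one with a three-way interaction
#' (3x4x5).
#'
#' Preset names follow
#' \code{scenario<1|2>_<common|rare|mixed>_<equal|unequal>_<none|moderate|strong>},
#' plus \code{sixsnp_two_twoway} and \code{sixsnp_threeway}.
#'
#' @param interaction_levels Named numeric vector giving the two-way
#'   interaction coefficient per strength label. Defaults to
#'   \code{c(none = 0, moderate = 0.2, strong = 0.5)}.
#' @param seed Root seed stored in every preset.
#' @return Named list of \code{\link{liability_spec}} objects.
#' @export
liability_presets <- function(interaction_levels = c(none = 0, moderate = 0.2,
                                                     strong = 0.5),
                              seed = 1) {
  maf_patterns <- list(
    common = rep(0.4, 4),
    rare = rep(0.05, 4),
    mixed = c(0.4, 0.05, 0.4, 0.05)
  )
  # Equal-effect values follow the printed heritability ladder: common
  # variants carry beta 0.2, rare variants 0.8 (mixed pattern pairs them).
  effect_patterns <- list(
    common = list(equal = rep(0.2, 4), unequal = c(0.2, 0.2, 0.2, 0.5)),
    rare = list(equal = rep(0.8, 4), unequal = c(0.8, 0.8, 0.2, 0.8)),
    mixed = list(equal = c(0.2, 0.8, 0.2, 0.8),
                 unequal = c(0.2, 0.8, 0.5, 0.8))
  )
  presets <- list()
  for (scen in c("scenario1", "scenario2")) {
    for (pat in names(maf_patterns)) {
      for (es in c("equal", "unequal")) {
        for (lev in names(interaction_levels)) {
          beta <- effect_patterns[[pat]][[es]]
          if (scen == "scenario2") beta[1:2] <- 0
          coef <- unname(interaction_levels[[lev]])
          ints <- if (coef != 0) list(interaction_term(c(3L, 4L), coef))
                  else list()
          nm <- paste(scen, pat, es, lev, sep = "_")
          presets[[nm]] <- liability_spec(
            maf_patterns[[pat]], beta, interactions = ints, seed = seed
          )
        }
      }
    }
  }
  presets[["sixsnp_two_twoway"]] <- liability_spec(
    rep(0.4, 6), rep(0.2, 6),
    interactions = list(interaction_term(c(3L, 4L), 0.2),
                        interaction_term(c(5L, 6L), 0.2)),
    seed = seed
  )
  presets[["sixsnp_threeway"]] <- liability_spec(
    rep(0.4, 6), rep(0.2, 6),
    interactions = list(interaction_term(c(3L, 4L, 5L), 0.2)),
    seed = seed
  )
  presets
}
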