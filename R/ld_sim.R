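#' Two-locus additive penetrance table
#'
#' Builds the 3x3 penetrance matrix for two biallelic loci acting additively
#' on the penetrance scale: with baseline penetrance \eqn{k} and relative
#' risks \eqn{\theta_a, \theta_b}, each locus adds
#' \eqn{r(\theta, g) = 0, (\theta - 1)k/2, (\theta - 1)k} for genotype
#' \eqn{g = 0, 1, 2} risk alleles, so
#' \eqn{P(D | g_a, g_b) = k + r(\theta_a, g_a) + r(\theta_b, g_b)}. The four
#' corners are \eqn{k}, \eqn{\theta_a k}, \eqn{\theta_b k} and
#' \eqn{(\theta_a + \theta_b - 1)k}.
#'
#' @param k Baseline penetrance in (0, 1).
#' @param theta_a,theta_b Relative risks (>= 1) of the two causal loci.
#' @return A 3x3 matrix \code{P[g_a + 1, g_b + 1]} of penetrances.
#' @examples
#' additive_penetrance_table(0.1, 1.5, 1.5)
#' @export
additive_penetrance_table <- function(k, theta_a, theta_b) {
  if (!is.numeric(k) || k <= 0 || k >= 1) {
    stop("'k' must lie in (0, 1)", call. = FALSE)
  }
  if (theta_a < 1 || theta_b < 1) {
    stop("relative risks must be >= 1", call. = FALSE)
  }
  r <- function(theta) c(0, (theta - 1) * k / 2, (theta - 1) * k)
  tab <- outer(r(theta_a), r(theta_b), `+`) + k
  if (any(tab < 0 | tab > 1)) {
    stop(sprintf(
      "invalid penetrance model: (theta_a + theta_b - 1) * k = %.4g exceeds 1",
      (theta_a + theta_b - 1) * k), call. = FALSE)
  }
  dimnames(tab) <- list(g_a = 0:2, g_b = 0:2)
  tab
}

#' Conditional genotype structure linking a marker to a causal locus
#'
#' Encodes \eqn{P(G_3 = j | G_2 = i)} as a row-stochastic 3x3 table. In
#' \code{weak} mode all rows equal the marker's own HWE genotype frequencies
#' (independence). In \code{strong} mode row \eqn{i} places mass
#' \code{retention} on \eqn{j = i} and spreads the remainder proportionally
#' to the marker's HWE frequencies, producing a strongly correlated marker.
#' A custom conditional table may be supplied instead.
#'
#' @param marker_maf MAF of the non-causal marker (its risk allele is taken
#'   as the minor allele).
#' @param mode \code{"strong"} or \code{"weak"}; ignored when
#'   \code{conditional} is supplied (the mode tag is still recorded).
#' @param retention Probability mass retained on the matching genotype in
#'   strong mode; default 0.8.
#' @param conditional Optional user 3x3 row-stochastic matrix overriding the
#'   built-in construction.
#' @return An object of class \code{ld_structure} with elements
#'   \code{conditional} and \code{mode}.
#' @examples
#' ld_structure(0.4, "strong")
#' ld_structure(0.4, "weak")
#' @export
ld_structure <- function(marker_maf, mode = c("strong", "weak"),
                         retention = 0.8, conditional = NULL) {
  mode <- match.arg(mode)
  p <- marker_maf
  if (is.null(conditional)) {
    if (!is.numeric(p) || p <= 0 || p > 0.5) {
      stop("'marker_maf' must lie in (0, 0.5]", call. = FALSE)
    }
    hwe <- c((1 - p)^2, 2 * p * (1 - p), p^2)
    conditional <- if (mode == "weak") {
      matrix(hwe, 3, 3, byrow = TRUE)
    } else {
      retention * diag(3) + (1 - retention) *
        matrix(hwe, 3, 3, byrow = TRUE)
    }
  } else {
    conditional <- as.matrix(conditional)
    if (!all(dim(conditional) == c(3, 3)) || any(conditional < 0) ||
        any(abs(rowSums(conditional) - 1) > 1e-8)) {
      stop("'conditional' must be a 3x3 row-stochastic matrix", call. = FALSE)
    }
  }
  dimnames(conditional) <- list(g2 = 0:2, g3 = 0:2)
  structure(list(conditional = conditional, mode = mode),
            class = "ld_structure")
}

#' @export
print.ld_structure <- function(x, ...) {
  cat(sprintf("LD structure (%s): P(G3 = j | G2 = i)\n", x$mode))
  print(round(x$conditional, 4))
  invisible(x)
}

#' Specify the two-locus penetrance generative model
#'
#' Disease is generated directly from the additive penetrance table of the
#' two causal loci (see \code{\link{additive_penetrance_table}}); a third,
#' non-causal marker may be appended in strong or weak LD with locus 2.
#'
#' @param k Baseline penetrance; default 0.1.
#' @param theta Length-2 vector of relative risks; default \code{c(1.5, 1.5)}.
#' @param mafs Length-2 vector of causal-locus MAFs; default
#'   \code{c(0.4, 0.4)}.
#' @param n_cases,n_controls Subjects per replicate; defaults 200 each (total
#'   sample size 400, balanced).
#' @param n_replicates Replicates per collection; default 100.
#' @param seed Root seed; default 1.
#' @param max_draws Rejection-sampling cap per replicate; exceeding it is an
#'   error, never a silent truncation. Default 1e6.
#' @return An object of class \code{penetrance_spec}.
#' @export
penetrance_spec <- function(k = 0.1, theta = c(1.5, 1.5), mafs = c(0.4, 0.4),
                            n_cases = 200, n_controls = 200,
                            n_replicates = 100, seed = 1, max_draws = 1e6) {
  if (length(theta) != 2L || length(mafs) != 2L) {
    stop("'theta' and 'mafs' must each have length 2", call. = FALSE)
  }
  # validates k, theta and all nine cells
  tab <- additive_penetrance_table(k, theta[1], theta[2])
  loci <- as_loci(mafs)
  structure(
    list(k = k, theta = as.numeric(theta), loci = loci,
         penetrance = tab,
         n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
         n_replicates = as.integer(n_replicates), seed = as.integer(seed),
         max_draws = max_draws),
    class = "penetrance_spec"
  )
}

#' @export
print.penetrance_spec <- function(x, ...) {
  cat(sprintf("Two-locus penetrance model: k = %g, RR = (%g, %g), MAF = (%g, %g)\n",
              x$k, x$theta[1], x$theta[2], x$loci[[1]]$maf, x$loci[[2]]$maf))
  cat(sprintf("  %d cases + %d controls x %d replicates, seed %d\n",
              x$n_cases, x$n_controls, x$n_replicates, x$seed))
  invisible(x)
}

#' Sample genotypes for two causal loci plus a linked marker
#'
#' Loci 1 and 2 are drawn independently under HWE; the third locus is drawn
#' from the conditional row of \code{ld} indexed by each subject's locus-2
#' genotype. Uses R's global RNG.
#'
#' @param mafs Length-2 vector of causal MAFs (or list of
#'   \code{\link{locus_spec}}).
#' @param ld An \code{\link{ld_structure}}.
#' @param n Number of subjects.
#' @return An \code{n x 3} integer matrix with columns G1, G2, G3.
#' @export
sample_linked_genotypes <- function(mafs, ld, n) {
  stopifnot(inherits(ld, "ld_structure"))
  loci <- as_loci(mafs)
  if (length(loci) != 2L) stop("exactly two causal loci expected",
                               call. = FALSE)
  g12 <- sample_genotypes_hwe(loci, n)
  g3 <- integer(n)
  for (i in 0:2) {
    idx <- which(g12[, 2] == i)
    if (length(idx)) {
      g3[idx] <- sample(0:2, length(idx), replace = TRUE,
                        prob = ld$conditional[i + 1, ])
    }
  }
  g <- cbind(g12, G3 = as.integer(g3))
  colnames(g) <- c(locus_ids(loci), "G3")
  g
}

#' Simulate a balanced case-control replicate from the penetrance model
#'
#' Subjects are drawn in batches; disease status is Bernoulli with
#' probability given by the two causal loci's penetrance cell (the marker
#' never enters disease generation). Drawing continues until the case and
#' control quotas are both met (rejection sampling), up to
#' \code{spec$max_draws} candidate subjects.
#'
#' @param spec A \code{\link{penetrance_spec}}.
#' @param ld An \code{\link{ld_structure}}; set \code{include_marker = FALSE}
#'   to omit the marker column entirely.
#' @param replicate Replicate index.
#' @param stream Internal seed stream (training and test collections use
#'   different streams).
#' @param include_marker Keep the LD marker as a third genotype column?
#'   Default \code{TRUE}.
#' @return A \code{case_control_dataset} with exactly \code{n_cases} cases.
#' @export
simulate_ld_case_control <- function(spec, ld, replicate = 1L, stream = 2L,
                                     include_marker = TRUE) {
  stopifnot(inherits(spec, "penetrance_spec"))
  seed <- derive_seed(spec$seed, stream = stream, index = replicate)
  set.seed(seed)
  need_cases <- spec$n_cases
  need_ctrls <- spec$n_controls
  # expected draws: n / min(prevalence, 1 - prevalence); batch generously
  batch <- max(1000L, 4L * (need_cases + need_ctrls))
  g_cases <- g_ctrls <- NULL
  drawn <- 0
  while (need_cases > 0 || need_ctrls > 0) {
    if (drawn >= spec$max_draws) {
      stop(sprintf(
        "rejection sampling exhausted %g draws with %d cases / %d controls still needed",
        spec$max_draws, need_cases, need_ctrls), call. = FALSE)
    }
    b <- min(batch, spec$max_draws - drawn)
    g <- sample_linked_genotypes(spec$loci, ld, b)
    pen <- spec$penetrance[cbind(g[, 1] + 1L, g[, 2] + 1L)]
    d <- stats::rbinom(b, 1L, pen)
    drawn <- drawn + b
    if (need_cases > 0) {
      take <- which(d == 1L)[seq_len(min(need_cases, sum(d == 1L)))]
      g_cases <- rbind(g_cases, g[take, , drop = FALSE])
      need_cases <- spec$n_cases - NROW(g_cases)
    }
    if (need_ctrls > 0) {
      take <- which(d == 0L)[seq_len(min(need_ctrls, sum(d == 0L)))]
      g_ctrls <- rbind(g_ctrls, g[take, , drop = FALSE])
      need_ctrls <- spec$n_controls - NROW(g_ctrls)
    }
  }
  g_all <- rbind(g_cases, g_ctrls)
  if (!include_marker) g_all <- g_all[, 1:2, drop = FALSE]
  status <- c(rep(1L, spec$n_cases), rep(0L, spec$n_controls))
  new_case_control_dataset(g_all, status, replicate, seed, "penetrance")
}

#' Paired training and test replicate collections
#'
#' Generates disjoint-seed-stream training and test collections from the
#' same penetrance model: training replicates feed
#' \code{\link{estimate_grs_weights}}, test replicates feed
#' \code{\link{run_study}}.
#'
#' @param spec A \code{\link{penetrance_spec}}.
#' @param ld An \code{\link{ld_structure}}.
#' @param n_train,n_test Replicate counts; default \code{spec$n_replicates}
#'   each.
#' @param include_marker Passed through to
#'   \code{\link{simulate_ld_case_control}}.
#' @return List with elements \code{train} and \code{test}, each a list of
#'   \code{case_control_dataset}.
#' @export
make_train_test_study <- function(spec, ld,
                                  n_train = spec$n_replicates,
                                  n_test = spec$n_replicates,
                                  include_marker = TRUE) {
  train <- lapply(seq_len(n_train), function(r) {
    simulate_ld_case_control(spec, ld, replicate = r, stream = 2L,
                             include_marker = include_marker)
  })
  test <- lapply(seq_len(n_test), function(r) {
    simulate_ld_case_control(spec, ld, replicate = r, stream = 3L,
                             include_marker = include_marker)
  })
  list(train = train, test = test)
}
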