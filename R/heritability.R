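# Internal raw representation of a liability model: risk-allele frequencies
# (allowed anywhere in [0, 1] so monomorphic limits and RAF sweeps work),
# intercept, main effects, interaction terms and noise variance.
raw_model <- function(spec) {
  stopifnot(inherits(spec, "liability_spec"))
  list(p = rafs(spec$loci), b0 = spec$intercept, beta = spec$main_effects,
       ints = spec$interactions, s2 = spec$noise_variance)
}

# Enumerate all 3^L genotype combinations with their HWE probabilities.
genotype_grid <- function(p, cap = 8L) {
  L <- length(p)
  if (L > cap) {
    stop(sprintf(
      "analytic enumeration supports at most %d loci (3^%d cells); use the Monte-Carlo oracle beyond that",
      cap, cap), call. = FALSE)
  }
  G <- as.matrix(expand.grid(rep(list(0:2), L), KEEP.OUT.ATTRS = FALSE))
  colnames(G) <- paste0("G", seq_len(L))
  prob <- rep(1, nrow(G))
  for (i in seq_len(L)) {
    pi <- p[i]
    hwe <- c((1 - pi)^2, 2 * pi * (1 - pi), pi^2)
    prob <- prob * hwe[G[, i] + 1L]
  }
  list(G = G, prob = prob)
}

raw_predictor <- function(raw, G) {
  mu <- raw$b0 + drop(G %*% raw$beta)
  for (term in raw$ints) {
    pt <- G[, term$loci[1]]
    for (j in term$loci[-1]) pt <- pt * G[, j]
    mu <- mu + term$coef * pt
  }
  mu
}

# Population median of the liability: the liability is a finite mixture of
# Gaussians over genotype cells, so solve F(t) = 1/2 by bracketed
# root-finding followed by one Newton polish (|F(t) - 1/2| < 1e-12).
raw_threshold <- function(raw) {
  grid <- genotype_grid(raw$p)
  mu <- raw_predictor(raw, grid$G)
  sd <- sqrt(raw$s2)
  f <- function(t) sum(grid$prob * stats::pnorm(t, mu, sd)) - 0.5
  lo <- min(mu) - 10 * sd
  hi <- max(mu) + 10 * sd
  t <- stats::uniroot(f, c(lo, hi), tol = .Machine$double.eps^0.75)$root
  deriv <- sum(grid$prob * stats::dnorm(t, mu, sd))
  if (deriv > 0) t <- t - f(t) / deriv
  t
}

# Analytic penetrance map: every genotype combination with its probability
# and P(D | G) = 1 - Phi((t - mu_G) / sigma).
raw_pen_map <- function(raw, threshold = NULL) {
  grid <- genotype_grid(raw$p)
  mu <- raw_predictor(raw, grid$G)
  if (is.null(threshold)) threshold <- raw_threshold(raw)
  pen <- stats::pnorm((mu - threshold) / sqrt(raw$s2))
  structure(
    list(G = grid$G, prob = grid$prob, penetrance = pen,
         prevalence = sum(grid$prob * pen), threshold = threshold),
    class = "penetrance_map"
  )
}

as_pen_map <- function(x) {
  if (inherits(x, "penetrance_map")) return(x)
  if (inherits(x, "liability_spec")) return(raw_pen_map(raw_model(x)))
  stop("expected a liability_spec or penetrance_map", call. = FALSE)
}

#' Population median of the liability distribution
#'
#' Analytic (infinite-population) counterpart of the per-replicate empirical
#' median split: the threshold \eqn{t} with \eqn{P(Y \le t) = 1/2} under the
#' genotype-mixture-of-Gaussians liability, found by bracketed root-finding
#' (residual below 1e-12). Enumeration is capped at 8 loci.
#'
#' @param spec A \code{\link{liability_spec}}.
#' @return The threshold \eqn{t}.
#' @examples
#' population_threshold(liability_spec(0.5, 0)) # = intercept
#' @export
population_threshold <- function(spec) {
  raw_threshold(raw_model(spec))
}

#' Analytic penetrances of a liability-threshold model
#'
#' Enumerates all genotype combinations and returns
#' \eqn{P(D | G) = 1 - \Phi((t - \mu_G)/\sigma)} with \eqn{\mu_G} the full
#' linear predictor (main effects and interaction terms). The
#' probability-weighted mean penetrance is the prevalence, 0.5 by the
#' median-threshold construction.
#'
#' @param spec A \code{\link{liability_spec}}.
#' @param threshold Optional precomputed threshold; defaults to
#'   \code{\link{population_threshold}(spec)}.
#' @return A \code{penetrance_map}: genotype matrix \code{G}, cell
#'   probabilities \code{prob}, \code{penetrance}, \code{prevalence} and
#'   \code{threshold}.
#' @export
analytic_penetrances <- function(spec, threshold = NULL) {
  raw_pen_map(raw_model(spec), threshold)
}

#' @export
print.penetrance_map <- function(x, ...) {
  cat(sprintf("penetrance map: %d genotype cells, prevalence %.6f, threshold %.6f\n",
              nrow(x$G), x$prevalence, x$threshold))
  invisible(x)
}

# Heritability of the penetrance variation explained by a subset of loci:
# sum_g P(g) (P(D|g) - P(D))^2 / (P(D)(1 - P(D))), where g runs over the
# joint genotypes of the subset and P(D|g) marginalises the map over all
# other loci. Subset of size 1 gives the single-locus / marginal form, size
# 2 the two-locus total.
h2_of_subset <- function(map, loci) {
  loci <- as.integer(loci)
  pd <- map$prevalence
  if (pd <= 0 || pd >= 1) {
    stop("degenerate prevalence: heritability undefined", call. = FALSE)
  }
  key <- drop(map$G[, loci, drop = FALSE] %*% 3^(seq_along(loci) - 1))
  pg <- rowsum(map$prob, key)
  pdg_num <- rowsum(map$prob * map$penetrance, key)
  keep <- pg > 0
  pdg <- pdg_num[keep] / pg[keep]
  sum(pg[keep] * (pdg - pd)^2) / (pd * (1 - pd))
}

#' Single-locus (marginal) heritability
#'
#' Proportion of the binary-trait variance explained by one locus:
#' \deqn{H^2_A = \frac{\sum_a P(G_a)\{P(D|G_a) - P(D)\}^2}{P(D)(1 - P(D))}.}
#' \code{h2_marginal} is an alias: the marginal heritability of a locus
#' within a pair is exactly the single-locus form applied to the joint map.
#'
#' @param x A \code{\link{liability_spec}} or a \code{penetrance_map} from
#'   \code{\link{analytic_penetrances}}.
#' @param locus Locus index.
#' @return Heritability as a proportion (not percent).
#' @export
h2_single <- function(x, locus) {
  h2_of_subset(as_pen_map(x), locus)
}

#' @rdname h2_single
#' @export
h2_marginal <- h2_single

#' Multi-locus total heritability
#'
#' Total heritability attributable to a set of loci jointly (the two-locus
#' form generalised to any subset):
#' \deqn{H^2_{AB} = \frac{\sum_{a,b} P(G_{ab})\{P(D|G_{ab}) - P(D)\}^2}
#'   {P(D)(1 - P(D))}.}
#'
#' @inheritParams h2_single
#' @param loci Integer vector of locus indices (any length up to the model
#'   size).
#' @return Heritability as a proportion.
#' @export
h2_group <- function(x, loci) {
  h2_of_subset(as_pen_map(x), loci)
}

#' @rdname h2_group
#' @param pair Length-2 integer vector.
#' @export
h2_pair <- function(x, pair) {
  stopifnot(length(pair) == 2L)
  h2_of_subset(as_pen_map(x), pair)
}

#' Interaction heritability
#'
#' For a pair, the part of the joint heritability not attributable to either
#' marginal effect: \eqn{H^2_{I,AB} = H^2_{AB} - H^2_{M,A} - H^2_{M,B}}.
#' For larger sets the natural extension is used: the joint total minus all
#' marginals and all lower-order interaction components (computed
#' recursively), i.e. the highest-order remainder.
#'
#' @inheritParams h2_group
#' @return Signed heritability component (may be numerically ~0 or slightly
#'   negative in near-additive models).
#' @export
h2_interaction <- function(x, loci) {
  map <- as_pen_map(x)
  loci <- as.integer(loci)
  if (length(loci) < 2L) stop("need at least two loci", call. = FALSE)
  total <- h2_of_subset(map, loci)
  lower <- sum(vapply(loci, function(l) h2_of_subset(map, l), numeric(1)))
  if (length(loci) > 2L) {
    for (k in 2:(length(loci) - 1L)) {
      subsets <- utils::combn(loci, k, simplify = FALSE)
      lower <- lower + sum(vapply(subsets, function(s) {
        h2_interaction(map, s)
      }, numeric(1)))
    }
  }
  total - lower
}

# Shared assembly of a decomposition from a penetrance map (analytic or
# empirical), so the Monte-Carlo oracle exercises the same arithmetic.
decompose_from_map <- function(map, groups, n_loci) {
  marg <- vapply(seq_len(n_loci), function(l) h2_of_subset(map, l),
                 numeric(1))
  rows <- lapply(names(groups), function(nm) {
    loci <- groups[[nm]]
    joint <- h2_of_subset(map, loci)
    msum <- sum(marg[loci])
    data.frame(group = nm, loci = paste(loci, collapse = ","),
               h2 = joint, h2_marginals = msum,
               h2_interaction = joint - msum,
               stringsAsFactors = FALSE)
  })
  groups_df <- do.call(rbind, rows)
  list(prevalence = map$prevalence, threshold = map$threshold,
       marginal = marg, groups = groups_df,
       h2_total = sum(groups_df$h2))
}

default_groups <- function(spec) {
  L <- length(spec$loci)
  if (length(spec$interactions)) {
    # union-find over interaction terms; leftover loci form one main group
    parent <- seq_len(L)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (term in spec$interactions) {
      r <- find(term$loci[1])
      for (j in term$loci[-1]) parent[find(j)] <- r
    }
    root <- vapply(seq_len(L), find, integer(1))
    in_int <- seq_len(L) %in% unlist(lapply(spec$interactions, `[[`, "loci"))
    groups <- list()
    for (r in unique(root[in_int])) {
      members <- which(root == r & in_int)
      groups[[paste0("G", paste(members, collapse = "G"))]] <- members
    }
    main <- which(!in_int)
    if (length(main)) {
      groups[[paste0("G", paste(main, collapse = "G"))]] <- main
    }
    groups
  } else {
    # no interaction terms: consecutive pairs (the conventional reporting
    # grouping for the four-SNP designs), trailing singleton if L is odd
    groups <- list()
    i <- 1L
    while (i <= L) {
      members <- i:min(i + 1L, L)
      groups[[paste0("G", paste(members, collapse = "G"))]] <- members
      i <- i + 2L
    }
    groups
  }
}

#' Analytic heritability decomposition of a liability-threshold model
#'
#' Computes the population-median threshold, the analytic penetrances, the
#' per-locus marginal heritabilities, and for each reporting group the joint
#' total \eqn{H^2}, the sum of its marginals and the interaction remainder
#' (joint minus marginals). The overall total is the sum of the group joint
#' totals; when the groups partition the loci and no interaction crosses
#' groups this matches the conventional
#' \eqn{H^2_{Total} = H^2_{G1G2} + H^2_{G3G4}} reporting.
#'
#' @param spec A \code{\link{liability_spec}}.
#' @param groups Named list of integer vectors of locus indices. Default:
#'   loci sharing an interaction term are grouped together with the
#'   remaining loci as one main-effects group; with no interaction terms,
#'   consecutive pairs.
#' @param threshold Optional precomputed population threshold.
#' @return An object of class \code{h2_decomposition}: \code{prevalence},
#'   \code{threshold}, \code{marginal} (per-locus vector), \code{groups}
#'   (data frame) and \code{h2_total}, all proportions.
#' @examples
#' spec <- liability_spec(rep(0.4, 4), rep(0.2, 4))
#' h2_decompose(spec)
#' @export
h2_decompose <- function(spec, groups = NULL, threshold = NULL) {
  stopifnot(inherits(spec, "liability_spec"))
  if (is.null(groups)) groups <- default_groups(spec)
  groups <- check_groups(groups, length(spec$loci))
  map <- analytic_penetrances(spec, threshold)
  out <- decompose_from_map(map, groups, length(spec$loci))
  names(out$marginal) <- locus_ids(spec$loci)
  class(out) <- "h2_decomposition"
  out
}

check_groups <- function(groups, L) {
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  for (g in groups) {
    if (any(g < 1L | g > L)) {
      stop("grouping references unknown loci", call. = FALSE)
    }
  }
  groups
}

#' @export
print.h2_decomposition <- function(x, ...) {
  cat(sprintf("Heritability decomposition (prevalence %.4f)\n", x$prevalence))
  cat("  per-locus marginal (%):",
      paste(sprintf("%s=%.4f", names(x$marginal), 100 * x$marginal),
            collapse = " "), "\n")
  df <- x$groups
  df$h2 <- 100 * df$h2
  df$h2_marginals <- 100 * df$h2_marginals
  df$h2_interaction <- 100 * df$h2_interaction
  print(df, row.names = FALSE, digits = 4)
  cat(sprintf("  H2_total = %.4f%%\n", 100 * x$h2_total))
  invisible(x)
}

#' Monte-Carlo oracle for the heritability decomposition
#'
#' Recomputes the decomposition from empirical penetrances: simulates
#' \code{n} subjects from the liability model, thresholds at the empirical
#' median, tabulates genotype-cell frequencies and case rates, and applies
#' the same decomposition arithmetic as \code{\link{h2_decompose}}. Block
#' standard errors (from \code{blocks} equal splits) accompany every
#' component so analytic/Monte-Carlo agreement can be asserted in units of
#' Monte-Carlo error.
#'
#' @inheritParams h2_decompose
#' @param n Number of simulated subjects; default 1e6.
#' @param seed Seed for the draw.
#' @param blocks Number of blocks for the standard errors; default 20 (a
#'   10-block split estimates the sd too noisily for 3-sigma checks).
#' @return An \code{h2_decomposition} with an extra \code{se} element
#'   (list: \code{marginal}, \code{groups}, \code{h2_total}).
#' @export
mc_h2_decompose <- function(spec, groups = NULL, n = 1e6, seed = 1,
                            blocks = 20) {
  stopifnot(inherits(spec, "liability_spec"))
  if (is.null(groups)) groups <- default_groups(spec)
  groups <- check_groups(groups, length(spec$loci))
  L <- length(spec$loci)
  set.seed(seed)
  g <- sample_genotypes_hwe(spec$loci, n)
  y <- liability_predictor(spec, g) +
    stats::rnorm(n, 0, sqrt(spec$noise_variance))
  thr <- stats::median(y)
  d <- as.numeric(y > thr)

  empirical_map <- function(idx) {
    key <- drop(g[idx, , drop = FALSE] %*% 3^(0:(L - 1)))
    cnt <- rowsum(rep(1, length(idx)), key)
    dsum <- rowsum(d[idx], key)
    keys <- as.numeric(rownames(cnt))
    # reconstruct genotype rows from the base-3 key
    G <- matrix(0L, length(keys), L)
    k <- keys
    for (i in seq_len(L)) {
      G[, i] <- as.integer(k %% 3)
      k <- k %/% 3
    }
    prob <- as.numeric(cnt) / length(idx)
    pen <- as.numeric(dsum) / as.numeric(cnt)
    structure(list(G = G, prob = prob, penetrance = pen,
                   prevalence = sum(prob * pen), threshold = thr),
              class = "penetrance_map")
  }

  full <- decompose_from_map(empirical_map(seq_len(n)), groups, L)
  block_id <- rep(seq_len(blocks), length.out = n)
  block_vals <- lapply(seq_len(blocks), function(b) {
    decompose_from_map(empirical_map(which(block_id == b)), groups, L)
  })
  se_of <- function(get) {
    vals <- vapply(block_vals, get, numeric(1))
    stats::sd(vals) / sqrt(blocks)
  }
  full$se <- list(
    marginal = vapply(seq_len(L), function(l) {
      se_of(function(v) v$marginal[l])
    }, numeric(1)),
    groups = vapply(seq_len(nrow(full$groups)), function(i) {
      se_of(function(v) v$groups$h2[i])
    }, numeric(1)),
    h2_total = se_of(function(v) v$h2_total)
  )
  names(full$marginal) <- locus_ids(spec$loci)
  class(full) <- "h2_decomposition"
  full
}

#' Heritability relationship curves
#'
#' Evaluates the analytic decomposition along a one-dimensional sweep of a
#' model parameter, reproducing the characteristic effect-size / allele
#' frequency / interaction vs heritability relationships. Axes:
#' \describe{
#'   \item{ES}{main effect of \code{locus} swept over \code{grid}}
#'   \item{MAF}{MAF of \code{locus} swept over \code{grid} in (0, 0.5]}
#'   \item{RAF}{risk allele frequency of \code{locus} swept over [0, 1];
#'     monomorphic endpoints give zero heritability}
#'   \item{interaction}{two-way coefficient between loci 1 and 2 swept over
#'     \code{grid}}
#' }
#' Each row also carries the explained-variance weight of the swept locus,
#' \code{ev_weight} \eqn{= \beta^2 \, 2p(1-p)} (the main effect read as a
#' log odds ratio), so the weight-heritability relationship can be examined
#' directly.
#'
#' @param base_spec A \code{\link{liability_spec}} supplying everything not
#'   swept.
#' @param axis One of \code{"ES"}, \code{"MAF"}, \code{"RAF"},
#'   \code{"interaction"}.
#' @param grid Numeric vector of axis values.
#' @param locus Index of the swept locus (ES/MAF/RAF axes); default the last
#'   locus.
#' @return Data frame: axis value, \code{h2_total} (all loci jointly),
#'   per-locus marginals, \code{h2_interaction}, \code{ev_weight}.
#' @export
h2_curves <- function(base_spec, axis = c("ES", "MAF", "RAF", "interaction"),
                      grid, locus = length(base_spec$loci)) {
  stopifnot(inherits(base_spec, "liability_spec"))
  axis <- match.arg(axis)
  raw0 <- raw_model(base_spec)
  L <- length(raw0$p)
  all_loci <- seq_len(L)
  rows <- lapply(grid, function(v) {
    raw <- raw0
    if (axis == "ES") raw$beta[locus] <- v
    if (axis == "MAF") {
      if (v <= 0 || v > 0.5) stop("MAF grid must lie in (0, 0.5]",
                                  call. = FALSE)
      raw$p[locus] <- v
    }
    if (axis == "RAF") {
      if (v < 0 || v > 1) stop("RAF grid must lie in [0, 1]", call. = FALSE)
      raw$p[locus] <- v
    }
    if (axis == "interaction") {
      if (L < 2) stop("interaction axis needs two loci", call. = FALSE)
      raw$ints <- list(interaction_term(c(1L, 2L), v))
    }
    map <- raw_pen_map(raw)
    marg <- vapply(all_loci, function(l) h2_of_subset(map, l), numeric(1))
    total <- h2_of_subset(map, all_loci)
    p_swept <- raw$p[locus]
    es_swept <- raw$beta[locus]
    out <- data.frame(value = v, h2_total = total,
                      h2_interaction = total - sum(marg),
                      ev_weight = es_swept^2 * 2 * p_swept * (1 - p_swept))
    for (l in all_loci) out[[paste0("h2_marginal_", l)]] <- marg[l]
    out
  })
  df <- do.call(rbind, rows)
  names(df)[1] <- axis
  df
}
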