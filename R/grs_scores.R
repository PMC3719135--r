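#' Odds-ratio weight
#'
#' The OR-GRS weight of a locus is the natural log of its per-allele odds
#' ratio. Protective variants (OR < 1) keep their negative weight.
#'
#' @param odds_ratio Positive odds ratio (vectorised).
#' @return \code{log(odds_ratio)}.
#' @examples
#' or_weight(1.5)
#' or_weight(0.5) # negative: protective
#' @export
or_weight <- function(odds_ratio) {
  if (any(!is.finite(odds_ratio)) || any(odds_ratio <= 0)) {
    stop("'odds_ratio' must be positive and finite", call. = FALSE)
  }
  log(odds_ratio)
}

#' Explained-variance weight
#'
#' Weight proportional to the variance in liability a per-allele log odds
#' ratio explains at a given allele frequency:
#' \deqn{w = (\log OR)^2 \cdot 2 \, \mathrm{MAF} (1 - \mathrm{MAF}),}
#' i.e. the additive genotype variance \eqn{2pq} times the squared effect.
#' Non-negative by construction, zero iff OR = 1, and invariant to
#' OR \eqn{\leftrightarrow} 1/OR inversion.
#'
#' @param odds_ratio Positive odds ratio (vectorised).
#' @param maf Allele frequency in (0, 1); the weight is symmetric in
#'   \code{maf} vs \code{1 - maf}.
#' @return Non-negative weight.
#' @examples
#' ev_weight(1.5, 0.1)
#' ev_weight(1.5, 0.5) > ev_weight(1.5, 0.05)
#' @export
ev_weight <- function(odds_ratio, maf) {
  if (any(!is.finite(odds_ratio)) || any(odds_ratio <= 0)) {
    stop("'odds_ratio' must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(maf)) || any(maf <= 0) || any(maf >= 1)) {
    stop("'maf' must lie in (0, 1)", call. = FALSE)
  }
  log(odds_ratio)^2 * 2 * maf * (1 - maf)
}

#' Per-locus GRS weight set
#'
#' Container pairing locus labels with weights under one of the three score
#' constructions: \code{SC} (simple count; all weights exactly 1), \code{OR}
#' (log odds ratio) or \code{EV} (explained variance).
#'
#' @param method One of \code{"SC"}, \code{"OR"}, \code{"EV"}.
#' @param loci Character vector of locus labels.
#' @param weights Per-locus weights; ignored (forced to 1) for \code{SC}.
#' @param or_estimates Per-locus odds ratios behind the weights (OR/EV only).
#' @param maf_estimates Per-locus MAF estimates (EV only).
#' @param failures Optional character vector naming loci whose weight
#'   estimation failed (non-convergence / separation); their weights are
#'   \code{NA}.
#' @return An object of class \code{grs_weight_set}.
#' @export
grs_weight_set <- function(method = c("SC", "OR", "EV"), loci,
                           weights = NULL, or_estimates = NULL,
                           maf_estimates = NULL, failures = character()) {
  method <- match.arg(method)
  loci <- as.character(loci)
  if (method == "SC") {
    weights <- rep(1, length(loci))
  } else {
    if (is.null(weights) || length(weights) != length(loci)) {
      stop("'weights' must have one value per locus", call. = FALSE)
    }
    if (method == "EV" && any(weights < 0, na.rm = TRUE)) {
      stop("EV weights must be non-negative", call. = FALSE)
    }
  }
  structure(
    list(method = method, loci = loci, weights = as.numeric(weights),
         or_estimates = or_estimates, maf_estimates = maf_estimates,
         failures = failures),
    class = "grs_weight_set"
  )
}

#' @export
print.grs_weight_set <- function(x, ...) {
  cat(sprintf("%s-GRS weight set (%d loci)\n", x$method, length(x$loci)))
  df <- data.frame(locus = x$loci, weight = x$weights)
  if (!is.null(x$or_estimates)) df$OR <- x$or_estimates
  if (!is.null(x$maf_estimates)) df$MAF <- x$maf_estimates
  print(df, row.names = FALSE)
  if (length(x$failures)) {
    cat("estimation failures:", paste(x$failures, collapse = ", "), "\n")
  }
  invisible(x)
}

check_genotypes <- function(genotypes) {
  genotypes <- as.matrix(genotypes)
  if (ncol(genotypes) == 0L) {
    stop("empty locus list: no genotype columns", call. = FALSE)
  }
  if (!all(genotypes %in% c(0L, 1L, 2L))) {
    stop("genotype coding error: values outside {0, 1, 2}", call. = FALSE)
  }
  genotypes
}

#' Simple count genetic risk score
#'
#' Per subject, the number of risk alleles summed over all loci:
#' \eqn{SC_s = \sum_i G_{si}}. Integer-valued in \eqn{[0, 2I]}.
#'
#' @param genotypes Subjects-by-loci matrix of 0/1/2 risk-allele counts, or a
#'   \code{case_control_dataset}.
#' @return Numeric vector of per-subject scores.
#' @examples
#' simple_count_score(rbind(c(2, 1, 0, 1), c(0, 0, 0, 0)))
#' @export
simple_count_score <- function(genotypes) {
  if (inherits(genotypes, "case_control_dataset")) {
    genotypes <- genotypes$genotypes
  }
  g <- check_genotypes(genotypes)
  rowSums(g)
}

#' Weighted genetic risk score
#'
#' Per subject, \eqn{\sum_i w_i G_{si}}; when \code{rescale = TRUE} the sum is
#' rescaled by \eqn{I / \sum_i w_i} so the score is on the scale of an
#' allele count and directly comparable to the simple count score. Rescaling
#' is a positive affine map, so likelihood-ratio p-values, C-statistics and
#' AIC from a downstream logistic fit are identical either way.
#'
#' @param genotypes Subjects-by-loci matrix of 0/1/2 counts, or a
#'   \code{case_control_dataset}; columns must match the weight set's loci
#'   (by name when both are named).
#' @param weight_set A \code{\link{grs_weight_set}}.
#' @param rescale Apply the \eqn{I / \sum w_i} rescaling? Default
#'   \code{TRUE}. Requires \eqn{\sum w_i > 0}.
#' @return Numeric vector of per-subject scores.
#' @examples
#' ws <- grs_weight_set("OR", c("G1", "G2"), weights = c(1, 2))
#' weighted_score(rbind(c(2, 1)), ws, rescale = FALSE) # 4
#' weighted_score(rbind(c(2, 1)), ws)                  # 8/3
#' @export
weighted_score <- function(genotypes, weight_set, rescale = TRUE) {
  stopifnot(inherits(weight_set, "grs_weight_set"))
  if (inherits(genotypes, "case_control_dataset")) {
    genotypes <- genotypes$genotypes
  }
  g <- check_genotypes(genotypes)
  if (ncol(g) != length(weight_set$loci)) {
    stop("weight set does not cover every genotype column", call. = FALSE)
  }
  if (!is.null(colnames(g)) &&
      !identical(colnames(g), weight_set$loci)) {
    if (!all(weight_set$loci %in% colnames(g))) {
      stop("weight set loci do not match genotype columns", call. = FALSE)
    }
    g <- g[, weight_set$loci, drop = FALSE]
  }
  w <- weight_set$weights
  if (anyNA(w)) {
    stop(sprintf("weight set has failed loci (%s); cannot score",
                 paste(weight_set$failures, collapse = ", ")), call. = FALSE)
  }
  s <- drop(g %*% w)
  if (rescale) {
    sw <- sum(w)
    if (sw <= 0) {
      stop(sprintf(
        "cannot rescale: sum of weights is %.4g (must be > 0)", sw),
        call. = FALSE)
    }
    s <- length(w) * s / sw
  }
  s
}

pool_training <- function(training) {
  if (inherits(training, "case_control_dataset")) training <- list(training)
  stopifnot(length(training) > 0,
            all(vapply(training, inherits, TRUE, "case_control_dataset")))
  g <- do.call(rbind, lapply(training, function(d) d$genotypes))
  d <- unlist(lapply(training, function(d) d$status))
  if (all(d == 0L) || all(d == 1L)) {
    stop("training data must contain both cases and controls", call. = FALSE)
  }
  list(genotypes = g, status = d)
}

#' Estimate GRS weights from training data
#'
#' Per-locus odds ratios come from univariate logistic regressions of disease
#' status on the 0/1/2 allele count, fitted on the pooled training
#' replicates; per-locus MAFs are allele frequencies in the same pooled
#' sample. Weights are then \code{\link{or_weight}} or \code{\link{ev_weight}}
#' per method. A locus whose fit does not converge (or separates perfectly)
#' is flagged in \code{failures} with weight \code{NA} and reported with a
#' warning; a monomorphic locus is an error.
#'
#' @param training A \code{case_control_dataset} or list of them (pooled).
#' @param method \code{"OR"} or \code{"EV"}.
#' @return A \code{\link{grs_weight_set}}.
#' @examples
#' spec <- liability_spec(rep(0.4, 4), c(0, 0, 0.5, 0.5))
#' train <- lapply(1:5, function(r) simulate_liability_dataset(spec, r))
#' estimate_grs_weights(train, "OR")
#' @export
estimate_grs_weights <- function(training, method = c("OR", "EV")) {
  method <- match.arg(method)
  pooled <- pool_training(training)
  g <- pooled$genotypes
  d <- pooled$status
  ids <- colnames(g)
  if (is.null(ids)) ids <- paste0("G", seq_len(ncol(g)))
  log_or <- maf <- numeric(ncol(g))
  failures <- character()
  for (i in seq_len(ncol(g))) {
    gi <- g[, i]
    if (stats::var(gi) == 0) {
      stop(sprintf("locus %s is monomorphic in the training data: no odds ratio is estimable",
                   ids[i]), call. = FALSE)
    }
    separated <- FALSE
    fit <- withCallingHandlers(
      stats::glm(d ~ gi, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
          separated <<- TRUE
        }
        invokeRestart("muffleWarning")
      }
    )
    # the glm warning misses milder separation: flag runaway linear
    # predictors too (|eta| ~ 15 puts fitted probabilities at ~3e-7)
    if (max(abs(stats::predict(fit, type = "link"))) > 15) separated <- TRUE
    if (!fit$converged || separated) {
      failures <- c(failures, ids[i])
      log_or[i] <- NA_real_
    } else {
      log_or[i] <- stats::coef(fit)[["gi"]]
    }
    f <- mean(gi) / 2
    maf[i] <- min(f, 1 - f)
  }
  if (length(failures)) {
    warning(sprintf("weight estimation failed at %d locus/loci: %s",
                    length(failures), paste(failures, collapse = ", ")),
            call. = FALSE)
  }
  w <- switch(method,
              OR = log_or,
              EV = ifelse(is.na(log_or), NA_real_,
                          log_or^2 * 2 * maf * (1 - maf)))
  grs_weight_set(method, ids, weights = w, or_estimates = exp(log_or),
                 maf_estimates = maf, failures = failures)
}

#' Compute the score of a named method for a dataset
#'
#' Dispatch helper used by the evaluation harness: \code{SC} needs no weight
#' set; \code{OR} and \code{EV} use the supplied (training-derived) weights.
#'
#' @param dataset A \code{case_control_dataset} or genotype matrix.
#' @param method \code{"SC"}, \code{"OR"} or \code{"EV"}.
#' @param weight_sets Named list of \code{\link{grs_weight_set}} objects
#'   (required entries for the weighted methods requested).
#' @param rescale Passed to \code{\link{weighted_score}}.
#' @return Numeric score vector.
#' @export
grs_score <- function(dataset, method, weight_sets = list(), rescale = TRUE) {
  if (method == "SC") return(simple_count_score(dataset))
  ws <- weight_sets[[method]]
  if (is.null(ws)) {
    stop(sprintf("no weight set supplied for method %s", method),
         call. = FALSE)
  }
  weighted_score(dataset, ws, rescale = rescale)
}
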