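#' Concordance (C) statistic
#'
#' Probability that a randomly chosen case outscores a randomly chosen
#' control, with ties counted half: the area under the ROC curve. Computed
#' from midranks (Mann-Whitney form), which gives exactly the
#' \eqn{(\#concordant + \tfrac12\#ties) / (n_1 n_0)} definition.
#'
#' @param status 0/1 disease status vector.
#' @param scores Per-subject risk scores.
#' @return C-statistic in [0, 1].
#' @examples
#' c_statistic(c(1, 1, 1, 0, 0, 0), c(1, 2, 3, 0, 1, 2))
#' @export
c_statistic <- function(status, scores) {
  stopifnot(length(status) == length(scores))
  n1 <- sum(status == 1)
  n0 <- sum(status == 0)
  if (n1 == 0 || n0 == 0) {
    stop("both cases and controls are required", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[status == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Fit the single-predictor logistic GRS model
#'
#' Maximum-likelihood fit of \eqn{\mathrm{logit}\, P(D = 1) = \alpha + \beta
#' \cdot GRS}, with the likelihood-ratio test against the intercept-only
#' null (1 df), the C-statistic of the score, and AIC
#' (\eqn{2 \cdot 2 - 2 \log L}). A constant score is handled as the null fit
#' (slope 0, LRT 0, C = 0.5) and flagged; perfect separation is flagged via
#' \code{converged = FALSE} with the LRT taken from the profile deviance at
#' the last iteration.
#'
#' @param dataset A \code{case_control_dataset}, or a 0/1 status vector.
#' @param scores Per-subject GRS values aligned with the subjects.
#' @return An object of class \code{grs_fit}: \code{intercept_hat},
#'   \code{slope_hat}, \code{log_likelihood}, \code{lrt_statistic},
#'   \code{lrt_pvalue}, \code{c_statistic}, \code{aic}, \code{converged},
#'   \code{note}.
#' @export
fit_grs_model <- function(dataset, scores) {
  status <- if (inherits(dataset, "case_control_dataset")) dataset$status
            else as.integer(dataset)
  if (length(status) != length(scores)) {
    stop("scores are not aligned to subjects", call. = FALSE)
  }
  if (all(status == 0L) || all(status == 1L)) {
    stop("dataset must contain both cases and controls", call. = FALSE)
  }
  scores <- as.numeric(scores)
  if (stats::var(scores) == 0) {
    p1 <- mean(status)
    ll0 <- sum(status * log(p1) + (1 - status) * log(1 - p1))
    fit <- list(intercept_hat = stats::qlogis(p1), slope_hat = 0,
                log_likelihood = ll0, lrt_statistic = 0, lrt_pvalue = 1,
                c_statistic = 0.5, aic = 4 - 2 * ll0, converged = TRUE,
                note = "constant scores: null fit")
    class(fit) <- "grs_fit"
    return(fit)
  }
  separated <- FALSE
  m <- withCallingHandlers(
    stats::glm(status ~ scores, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        separated <<- TRUE
      }
      invokeRestart("muffleWarning")
    }
  )
  if (max(abs(stats::predict(m, type = "link"))) > 15) separated <- TRUE
  lrt <- max(0, m$null.deviance - m$deviance)
  ll <- as.numeric(stats::logLik(m))
  fit <- list(
    intercept_hat = unname(stats::coef(m)[1]),
    slope_hat = unname(stats::coef(m)[2]),
    log_likelihood = ll,
    lrt_statistic = lrt,
    lrt_pvalue = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
    c_statistic = c_statistic(status, scores),
    aic = m$aic,
    converged = m$converged && !separated,
    note = if (separated) "perfect/quasi-perfect separation" else ""
  )
  class(fit) <- "grs_fit"
  fit
}

#' @export
print.grs_fit <- function(x, ...) {
  cat(sprintf("logit P(D=1) = %.4f + %.4f * GRS\n",
              x$intercept_hat, x$slope_hat))
  cat(sprintf("  LRT = %.4f (p = %.4g), C = %.4f, AIC = %.2f%s\n",
              x$lrt_statistic, x$lrt_pvalue, x$c_statistic, x$aic,
              if (!x$converged) " [not converged]" else ""))
  invisible(x)
}

#' Evaluate GRS methods over a collection of test replicates
#'
#' For each replicate and each requested method, computes the score, fits
#' the logistic model and records the likelihood-ratio p-value, C-statistic
#' and AIC; then aggregates the per-method rejection rate (power under a
#' non-null generator, type-I error under a null one), mean C-statistic and
#' mean AIC. Replicates whose fit is flagged (non-convergence or separation)
#' are retained in the output table and counted in the summary's
#' \code{n_flagged}.
#'
#' @param test List of \code{case_control_dataset} objects.
#' @param methods Character subset of \code{c("SC", "OR", "EV")}.
#' @param weight_sets Named list of \code{\link{grs_weight_set}} for the
#'   weighted methods (typically from \code{\link{estimate_grs_weights}} on
#'   training data).
#' @param alpha Significance level; default 0.05.
#' @param rescale Use rescaled weighted scores? Default \code{TRUE} (the
#'   fits are affine-invariant, so this does not change any reported
#'   metric).
#' @return An object of class \code{grs_evaluation}: \code{fits} (one row
#'   per replicate x method) and \code{summary} (one row per method with
#'   \code{rejection_rate}, exact binomial CI, \code{mean_c},
#'   \code{mean_aic}, \code{n_replicates}, \code{n_flagged},
#'   \code{alpha}).
#' @examples
#' spec <- liability_spec(rep(0.4, 4), rep(0.2, 4), n_replicates = 5)
#' test <- lapply(1:5, function(r) simulate_liability_dataset(spec, r))
#' run_study(test, methods = "SC")
#' @export
run_study <- function(test, methods = c("SC", "OR", "EV"),
                      weight_sets = list(), alpha = 0.05, rescale = TRUE) {
  if (!length(test)) stop("empty replicate list", call. = FALSE)
  methods <- match.arg(methods, c("SC", "OR", "EV"), several.ok = TRUE)
  rows <- list()
  for (d in test) {
    for (m in methods) {
      s <- grs_score(d, m, weight_sets, rescale = rescale)
      f <- fit_grs_model(d, s)
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = d$replicate, method = m,
        lrt_statistic = f$lrt_statistic, p_value = f$lrt_pvalue,
        c_statistic = f$c_statistic, aic = f$aic,
        converged = f$converged, stringsAsFactors = FALSE)
    }
  }
  fits <- do.call(rbind, rows)
  structure(list(fits = fits,
                 summary = summarize_fits(fits, alpha = alpha),
                 alpha = alpha),
            class = "grs_evaluation")
}

#' Aggregate per-replicate fits into method summaries
#'
#' @param fits Data frame with columns \code{method}, \code{p_value},
#'   \code{c_statistic}, \code{aic} (and optionally \code{converged}), one
#'   row per replicate and method.
#' @param alpha Significance level for the rejection rate.
#' @return Data frame, one row per method: \code{rejection_rate} with exact
#'   binomial 95\% CI, \code{mean_c}, \code{mean_aic}, \code{n_replicates},
#'   \code{n_flagged}.
#' @export
summarize_fits <- function(fits, alpha = 0.05) {
  do.call(rbind, lapply(split(fits, fits$method), function(df) {
    n <- nrow(df)
    k <- sum(df$p_value < alpha)
    ci <- stats::binom.test(k, n)$conf.int
    data.frame(method = df$method[1],
               rejection_rate = k / n, ci_low = ci[1], ci_high = ci[2],
               mean_c = mean(df$c_statistic), mean_aic = mean(df$aic),
               n_replicates = n,
               n_flagged = if ("converged" %in% names(df))
                 sum(!df$converged) else 0L,
               alpha = alpha, stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' @export
print.grs_evaluation <- function(x, ...) {
  cat(sprintf("GRS evaluation over %d replicates (alpha = %g)\n",
              max(x$summary$n_replicates), x$alpha))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Tukey-adjusted pairwise method contrasts
#'
#' Fits a two-way linear model of a per-replicate (or per-scenario) metric on
#' method and scenario, then applies Tukey's honest-significant-difference
#' adjustment to the three method pairs. A pair's "winner" is declared when
#' the adjusted p-value is below \code{alpha}: the method with the larger
#' mean when larger is better (power, C-statistic), the smaller mean
#' otherwise (type-I error, AIC).
#'
#' @param metrics Data frame with columns \code{method}, \code{value} and
#'   optionally \code{scenario} (omitted or constant: one-way model, with a
#'   warning when cells are unbalanced).
#' @param larger_is_better Direction of preference for the metric; default
#'   \code{TRUE}.
#' @param alpha Significance level; default 0.05.
#' @return Data frame: \code{pair}, \code{diff}, \code{lwr}, \code{upr},
#'   \code{p_adj}, \code{winner} (\code{""} when not significant).
#' @examples
#' m <- data.frame(method = rep(c("SC", "OR"), each = 20),
#'                 scenario = rep(rep(c("a", "b"), each = 10), 2),
#'                 value = c(rnorm(20, 0.6, 0.01), rnorm(20, 0.7, 0.01)))
#' pairwise_method_contrasts(m)
#' @export
pairwise_method_contrasts <- function(metrics, larger_is_better = TRUE,
                                      alpha = 0.05) {
  stopifnot(all(c("method", "value") %in% names(metrics)))
  if (length(unique(metrics$method)) < 2L) {
    stop("need at least two methods to contrast", call. = FALSE)
  }
  metrics$method <- factor(metrics$method)
  has_scenario <- "scenario" %in% names(metrics) &&
    length(unique(metrics$scenario)) > 1L
  if (has_scenario) {
    metrics$scenario <- factor(metrics$scenario)
    tab <- table(metrics$method, metrics$scenario)
    if (length(unique(as.vector(tab))) > 1L) {
      warning("unbalanced method x scenario cells; contrasts fitted anyway",
              call. = FALSE)
    }
    fit <- stats::aov(value ~ method + scenario, data = metrics)
  } else {
    fit <- stats::aov(value ~ method, data = metrics)
  }
  tk <- stats::TukeyHSD(fit, which = "method")$method
  pairs <- rownames(tk)
  winner <- character(length(pairs))
  for (i in seq_along(pairs)) {
    if (tk[i, "p adj"] < alpha) {
      ab <- strsplit(pairs[i], "-", fixed = TRUE)[[1]]
      # row "A-B" reports mean(A) - mean(B)
      better_first <- (tk[i, "diff"] > 0) == larger_is_better
      winner[i] <- if (better_first) ab[1] else ab[2]
    }
  }
  data.frame(pair = pairs, diff = tk[, "diff"], lwr = tk[, "lwr"],
             upr = tk[, "upr"], p_adj = tk[, "p adj"], winner = winner,
             stringsAsFactors = FALSE, row.names = NULL)
}
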