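#' Write a case-control dataset to CSV
#'
#' One row per subject: \code{subject_id}, \code{D} (0/1), then one integer
#' 0/1/2 column per locus.
#'
#' @param dataset A \code{case_control_dataset}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_dataset_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "case_control_dataset"))
  g <- dataset$genotypes
  df <- data.frame(subject_id = seq_len(nrow(g)), D = dataset$status)
  for (j in seq_len(ncol(g))) df[[colnames(g)[j]]] <- g[, j]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a case-control dataset from CSV
#'
#' Expects the schema of \code{\link{write_dataset_csv}}: header row,
#' \code{subject_id}, \code{D}, then genotype columns.
#'
#' @param path CSV file path.
#' @return A \code{case_control_dataset} (generator tag \code{"file"}).
#' @export
read_dataset_csv <- function(path) {
  df <- utils::read.csv(path)
  req <- c("subject_id", "D")
  if (!all(req %in% names(df))) {
    stop("CSV must have 'subject_id' and 'D' columns plus genotype columns",
         call. = FALSE)
  }
  loci <- setdiff(names(df), req)
  if (!length(loci)) stop("no genotype columns found", call. = FALSE)
  g <- as.matrix(df[, loci, drop = FALSE])
  storage.mode(g) <- "integer"
  g <- check_genotypes(g)
  if (!all(df$D %in% c(0L, 1L))) {
    stop("'D' must be coded 0/1", call. = FALSE)
  }
  new_case_control_dataset(g, df$D, replicate = 0L, seed_used = NA_integer_,
                           generator = "file")
}

#' Serialize a GRS weight set to JSON
#'
#' @param weight_set A \code{\link{grs_weight_set}}.
#' @param path Output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_weight_set_json <- function(weight_set, path) {
  stopifnot(inherits(weight_set, "grs_weight_set"))
  x <- list(method = weight_set$method, loci = weight_set$loci,
            weights = weight_set$weights)
  if (!is.null(weight_set$or_estimates)) {
    x$or_estimates <- weight_set$or_estimates
  }
  if (!is.null(weight_set$maf_estimates)) {
    x$maf_estimates <- weight_set$maf_estimates
  }
  if (length(weight_set$failures)) x$failures <- weight_set$failures
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a GRS weight set from JSON
#'
#' @param path JSON path written by \code{\link{write_weight_set_json}}.
#' @return A \code{\link{grs_weight_set}}.
#' @export
read_weight_set_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  grs_weight_set(x$method, x$loci, weights = x$weights,
                 or_estimates = x$or_estimates,
                 maf_estimates = x$maf_estimates,
                 failures = if (is.null(x$failures)) character()
                            else x$failures)
}

spec_to_list <- function(spec) {
  if (inherits(spec, "liability_spec")) {
    list(generator = "liability",
         loci = lapply(spec$loci, function(l) {
           list(id = l$id, maf = l$maf,
                risk_allele_is_minor = l$risk_allele_is_minor)
         }),
         intercept = spec$intercept, main_effects = spec$main_effects,
         interactions = lapply(spec$interactions, function(t) {
           list(loci = t$loci, coef = t$coef)
         }),
         noise_variance = spec$noise_variance,
         n_cases = spec$n_cases, n_controls = spec$n_controls,
         n_replicates = spec$n_replicates, seed = spec$seed)
  } else if (inherits(spec, "penetrance_spec")) {
    list(generator = "penetrance", k = spec$k, theta = spec$theta,
         mafs = vapply(spec$loci, function(l) l$maf, numeric(1)),
         n_cases = spec$n_cases, n_controls = spec$n_controls,
         n_replicates = spec$n_replicates, seed = spec$seed)
  } else {
    stop("unknown spec class", call. = FALSE)
  }
}
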