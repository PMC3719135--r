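#' Describe a biallelic locus
#'
#' A locus is characterised by its minor allele frequency (MAF) and by which
#' allele is counted as the risk allele in the 0/1/2 genotype coding. When the
#' risk allele is the minor allele (the usual convention here) the risk allele
#' frequency (RAF) equals the MAF; otherwise it is \code{1 - maf}.
#'
#' @param maf Minor allele frequency, in (0, 0.5].
#' @param risk_allele_is_minor Logical; is the counted (risk) allele the minor
#'   one? Default \code{TRUE}.
#' @param id Optional locus label. Defaults to \code{NULL}; labels are filled
#'   in positionally (\code{G1}, \code{G2}, ...) when a list of loci is used.
#' @return An object of class \code{locus_spec}.
#' @examples
#' locus_spec(0.4)
#' locus_spec(0.1, risk_allele_is_minor = FALSE) # RAF = 0.9
#' @export
locus_spec <- function(maf, risk_allele_is_minor = TRUE, id = NULL) {
  if (!is.numeric(maf) || length(maf) != 1L || is.na(maf) ||
      maf <= 0 || maf > 0.5) {
    stop("'maf' must be a single number in (0, 0.5]", call. = FALSE)
  }
  structure(
    list(maf = as.numeric(maf),
         risk_allele_is_minor = isTRUE(risk_allele_is_minor),
         id = id),
    class = "locus_spec"
  )
}

#' Risk allele frequency of a locus
#'
#' @param locus A \code{locus_spec}.
#' @return The frequency of the counted (risk) allele.
#' @export
raf <- function(locus) {
  stopifnot(inherits(locus, "locus_spec"))
  if (locus$risk_allele_is_minor) locus$maf else 1 - locus$maf
}

#' @export
print.locus_spec <- function(x, ...) {
  cat(sprintf("locus%s: MAF %.4g, risk allele %s (RAF %.4g)\n",
              if (is.null(x$id)) "" else paste0(" ", x$id),
              x$maf,
              if (x$risk_allele_is_minor) "minor" else "major",
              raf(x)))
  invisible(x)
}

# Coerce a numeric vector of MAFs (or a single locus_spec, or a list of them)
# into a list of locus_spec with positional ids.
as_loci <- function(x) {
  if (inherits(x, "locus_spec")) x <- list(x)
  if (is.numeric(x)) x <- lapply(x, locus_spec)
  if (!is.list(x) || !all(vapply(x, inherits, TRUE, "locus_spec"))) {
    stop("'loci' must be a numeric vector of MAFs or a list of locus_spec",
         call. = FALSE)
  }
  for (i in seq_along(x)) {
    if (is.null(x[[i]]$id)) x[[i]]$id <- paste0("G", i)
  }
  x
}

# Vector of risk allele frequencies for a loci list.
rafs <- function(loci) vapply(loci, raf, numeric(1))

locus_ids <- function(loci) vapply(loci, function(l) l$id, character(1))

# Deterministic child seed: one root seed per study, a stream per purpose
# (simulation stage), an index per replicate. Arithmetic kept below 2^53 so
# the modulus is exact in doubles; result fits a 32-bit integer.
derive_seed <- function(root, stream = 1L, index = 0L) {
  root <- as.numeric(root) %% 2147483647
  v <- (root * 48271 + as.numeric(stream) * 1299721 +
          as.numeric(index) * 7919) %% 2147483647
  as.integer(v + 1)
}
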