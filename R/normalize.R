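# Detection filtering and TMM / CPM / RPM / RPKM normalization.

#' Drop features undetected in too many samples
#'
#' A feature is "undetected" in a sample when its raw count is exactly zero.
#' The feature is kept iff the number of zero samples is less than or equal to
#' `max_undetected` (strictly-greater counts are removed, i.e. "undetected in
#' over N samples" filters). Feature order is preserved.
#'
#' @param es An [expression_set()] (or plain count matrix).
#' @param max_undetected Maximum tolerated number of zero-count samples.
#' @return Filtered object of the same type.
#' @export
filter_undetected <- function(es, max_undetected) {
  counts <- if (inherits(es, "ExprSet")) es$counts else es
  n <- ncol(counts)
  if (max_undetected < 0 || max_undetected > n)
    contract_error("max_undetected must lie in [0, %d]", n)
  keep <- rowSums(counts == 0) <= max_undetected
  if (inherits(es, "ExprSet")) {
    subset_expression(es, features = which(keep))
  } else {
    counts[keep, , drop = FALSE]
  }
}

#' Trimmed mean of M-values scaling factors
#'
#' Per-sample composition scaling factors: each factor is 2 to the weighted
#' mean of M-values (log2 ratios of library-size-scaled proportions against a
#' reference sample), after trimming the most extreme 30 percent of M-values
#' and 5 percent of average log2 abundances (A-values), with inverse
#' delta-method (binomial) variances as weights. Features with a zero count in
#' either the sample or the reference are excluded pairwise. Factors are
#' rescaled so their geometric mean is exactly 1. When `ref_sample` is
#' omitted, the reference is the sample whose upper-quartile proportion is
#' closest to the mean of upper quartiles.
#'
#' @param es An [expression_set()] or count matrix (features x samples).
#' @param ref_sample Optional reference sample id.
#' @param logratio_trim,abs_trim Trim fractions for M and A values.
#' @return Named numeric vector of scaling factors (geometric mean 1);
#'   multiply raw library sizes by these to obtain effective library sizes.
#' @export
tmm_factors <- function(es, ref_sample = NULL, logratio_trim = 0.3,
                        abs_trim = 0.05) {
  counts <- if (inherits(es, "ExprSet")) es$counts else as.matrix(es)
  if (ncol(counts) < 2) contract_error("TMM needs at least two samples")
  lib <- colSums(counts)
  if (any(lib <= 0)) contract_error("every sample must have a positive library size")
  if (is.null(ref_sample)) {
    f75 <- apply(sweep(counts, 2, lib, "/"), 2, stats::quantile, probs = 0.75)
    ref <- which.min(abs(f75 - mean(f75)))
  } else {
    ref <- match(ref_sample, colnames(counts))
    if (is.na(ref)) contract_error("ref_sample '%s' not found", ref_sample)
  }
  f <- vapply(seq_len(ncol(counts)), function(j) {
    tmm_pair(counts[, j], counts[, ref], lib[j], lib[ref],
             logratio_trim, abs_trim,
             if (!is.null(colnames(counts))) colnames(counts)[j] else j)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

## One sample against the reference. Follows the published TMM recipe:
## doubly trimmed, precision-weighted mean of M-values.
tmm_pair <- function(obs, ref, n_obs, n_ref, logratio_trim, abs_trim, id) {
  keep <- obs > 0 & ref > 0
  if (!any(keep))
    stopf("sample '%s' shares no co-detected features with the reference", id,
          class = "exoscreen_numeric_error")
  p_obs <- obs[keep] / n_obs
  p_ref <- ref[keep] / n_ref
  M <- log2(p_obs / p_ref)
  A <- (log2(p_obs) + log2(p_ref)) / 2
  ## delta-method variance of M (binomial sampling in both libraries)
  v <- (n_obs - obs[keep]) / (n_obs * obs[keep]) +
       (n_ref - ref[keep]) / (n_ref * ref[keep])
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * logratio_trim) + 1
  hiM <- n + 1 - loM
  loA <- floor(n * abs_trim) + 1
  hiA <- n + 1 - loA
  rM <- rank(M)
  rA <- rank(A)
  sel <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  f <- sum(M[sel] / v[sel]) / sum(1 / v[sel])
  if (!is.finite(f)) f <- 0
  2^f
}

#' Effective library sizes
#'
#' @param es An [expression_set()] or count matrix.
#' @param factors TMM factors from [tmm_factors()]; `NULL` means raw library
#'   sizes.
#' @return Named numeric vector of (effective) library sizes.
#' @export
effective_libsize <- function(es, factors = NULL) {
  counts <- if (inherits(es, "ExprSet")) es$counts else es
  lib <- colSums(counts)
  if (!is.null(factors)) {
    if (!is.null(names(factors))) factors <- factors[colnames(counts)]
    lib <- lib * factors
  }
  lib
}

#' Normalized expression (RPM/CPM or RPKM)
#'
#' RPM (equivalently CPM) is `count / effective library size * 1e6`; RPKM
#' additionally divides by the feature length in kilobases. The optional log2
#' transform returns `log2(value + pseudocount)`.
#'
#' @param es An [expression_set()].
#' @param factors TMM factors; `NULL` uses raw library sizes.
#' @param unit `"class"` (the set's own unit), `"RPM"` or `"RPKM"`.
#' @param log2 Return log2-transformed values?
#' @param pseudocount Pseudocount for the log transform (default 1, i.e.
#'   log2(RPM + 1)).
#' @param raw_libsize Ignore `factors` and normalize on raw library sizes.
#' @return Matrix with attribute `unit`.
#' @export
normalized_expression <- function(es, factors = NULL,
                                  unit = c("class", "RPM", "RPKM"),
                                  log2 = FALSE, pseudocount = 1,
                                  raw_libsize = FALSE) {
  stopifnot(inherits(es, "ExprSet"))
  unit <- match.arg(unit)
  if (unit == "class") unit <- es$unit
  lib <- effective_libsize(es, if (raw_libsize) NULL else factors)
  out <- sweep(es$counts, 2, lib, "/") * 1e6
  if (unit == "RPKM") {
    if (is.null(es$lengths))
      contract_error("RPKM requested but class %s carries no feature lengths",
                     es$rna_class)
    out <- out * 1e3 / es$lengths[rownames(out)]
  }
  if (log2) out <- base::log2(out + pseudocount)
  attr(out, "unit") <- if (log2) paste0("log2_", unit) else unit
  out
}
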