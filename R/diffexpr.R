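# Two-group differential expression on count data: negative-binomial exact
# test with a common qCML dispersion (default engine) and a Wilcoxon rank-sum
# alternative on log-normalized values.

#' Define a two-group contrast
#'
#' @param case,control Disjoint character vectors of sample ids, each with at
#'   least two samples. `case` is the group whose higher expression gives a
#'   positive log2 fold change.
#' @param label Free-text label, conventionally `"A"` (normal vs cancer),
#'   `"B"` (normal vs non-adenocarcinoma) or `"C"` (normal vs adenocarcinoma).
#' @return A list of class `contrast`.
#' @export
contrast <- function(case, control, label = "custom") {
  if (length(intersect(case, control)))
    contract_error("case and control samples overlap")
  if (length(case) < 2 || length(control) < 2)
    contract_error("each contrast group needs at least two samples")
  structure(list(case = case, control = control, label = label),
            class = "contrast")
}

#' The three screening contrasts
#'
#' Builds the statistical-phase contrasts from a sample table: A = normal vs
#' all cancer pre-treatment samples, B = normal vs non-adenocarcinoma
#' pre-treatment samples, C = normal vs adenocarcinoma pre-treatment samples.
#'
#' @param samples A validated sample table.
#' @return Named list of [contrast()] objects `A`, `B`, `C`.
#' @export
screening_contrasts <- function(samples) {
  samples <- validate_samples(samples)
  nrm <- samples_of(samples, group = "normal")
  list(A = contrast(samples_of(samples, "cancer", "pre"), nrm, "A"),
       B = contrast(samples_of(samples, "cancer", "pre", "nonAC"), nrm, "B"),
       C = contrast(samples_of(samples, "cancer", "pre", "AC"), nrm, "C"))
}

## Counts scaled to a common (geometric-mean) effective library size, the
## quantile-adjustment that makes group sums comparable across samples.
equalize_counts <- function(counts, eff_lib) {
  common <- exp(mean(log(eff_lib)))
  sweep(counts, 2, common / eff_lib, "*")
}

#' Estimate a common negative-binomial dispersion
#'
#' Maximizes the conditional log-likelihood of the NB model given the group
#' sums, on counts scaled to a common effective library size. The dispersion
#' phi parameterizes the variance as `mu + phi * mu^2` and is clipped to
#' `[1e-6, 10]`.
#'
#' @param es An [expression_set()] or count matrix of filtered counts (no
#'   all-zero features over the contrast samples).
#' @param contrast A [contrast()].
#' @param factors Optional TMM factors used to form effective library sizes.
#' @return Estimated dispersion phi (scalar).
#' @export
estimate_common_dispersion <- function(es, contrast, factors = NULL) {
  counts <- if (inherits(es, "ExprSet")) es$counts else as.matrix(es)
  cols <- c(contrast$case, contrast$control)
  missing <- setdiff(cols, colnames(counts))
  if (length(missing))
    contract_error("contrast samples missing from counts: %s",
                   paste(missing, collapse = ", "))
  counts <- counts[, cols, drop = FALSE]
  if (any(rowSums(counts) == 0))
    contract_error("all-zero features present; run filter_undetected first")
  lib <- effective_libsize(counts, factors[cols])
  pseudo <- equalize_counts(counts, lib)
  groups <- list(pseudo[, contrast$case, drop = FALSE],
                 pseudo[, contrast$control, drop = FALSE])
  cll <- function(log_phi) {
    r <- exp(-log_phi) # 1/phi
    total <- 0
    for (g in groups) {
      ng <- ncol(g)
      z <- rowSums(g)
      total <- total + sum(lgamma(g + r)) + nrow(g) * lgamma(ng * r) -
        sum(lgamma(z + ng * r)) - nrow(g) * ng * lgamma(r)
    }
    total
  }
  opt <- stats::optimize(cll, interval = log(c(1e-6, 10)), maximum = TRUE,
                         tol = 1e-4)
  ## prefer the boundary when the likelihood is monotone (Poisson-like data)
  phi <- exp(opt$maximum)
  if (cll(log(1e-6)) >= opt$objective) phi <- 1e-6
  min(max(phi, 1e-6), 10)
}

#' Negative-binomial exact test
#'
#' Per feature, compares the case and control group sums of counts scaled to
#' a common effective library size. Conditional on the total, the case sum
#' follows (under the null) the NB-split distribution; the two-sided p-value
#' doubles the smaller conditional tail and is capped at 1. The log2 fold
#' change is the pseudocounted ratio of group mean CPM values (positive =
#' higher in the case group).
#'
#' @param es An [expression_set()] or count matrix.
#' @param contrast A [contrast()].
#' @param dispersion Common dispersion phi from
#'   [estimate_common_dispersion()].
#' @param factors Optional TMM factors.
#' @param pseudocount Pseudocount (CPM units) in the fold-change estimator.
#' @return A `DEGTable` data.frame with columns `feature_id`, `log2fc`,
#'   `pvalue`, `mean_case`, `mean_control`, `padj` (Benjamini-Hochberg,
#'   informational only: the screening rules use raw p-values).
#' @export
exact_test <- function(es, contrast, dispersion, factors = NULL,
                       pseudocount = 1) {
  counts <- if (inherits(es, "ExprSet")) es$counts else as.matrix(es)
  cols <- c(contrast$case, contrast$control)
  counts <- counts[, cols, drop = FALSE]
  lib <- effective_libsize(counts, factors[cols])
  pseudo <- equalize_counts(counts, lib)
  n1 <- length(contrast$case)
  n2 <- length(contrast$control)
  s1 <- rowSums(pseudo[, contrast$case, drop = FALSE])
  s2 <- rowSums(pseudo[, contrast$control, drop = FALSE])
  phi <- max(dispersion, 1e-8)
  p <- nb_split_pvalue(s1, s2, n1, n2, phi)

  cpm <- sweep(counts, 2, lib, "/") * 1e6
  mc <- rowMeans(cpm[, contrast$case, drop = FALSE])
  mctl <- rowMeans(cpm[, contrast$control, drop = FALSE])
  lfc <- base::log2((mc + pseudocount) / (mctl + pseudocount))
  data.frame(feature_id = rownames(counts), log2fc = lfc, pvalue = p,
             mean_case = mc, mean_control = mctl,
             padj = stats::p.adjust(p, "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

## Vector of exact-test p-values for group sums s1, s2 of n1, n2 equalized
## libraries under a common dispersion. Each group sum is rounded to the
## integer grid (so the statistic is exactly symmetric under case/control
## swaps); the conditional distribution of the case sum given the total is
## evaluated on a +-6 conditional-sd window (self-normalized; truncation
## error far below the reported precision).
nb_split_pvalue <- function(s1, s2, n1, n2, phi) {
  r1 <- n1 / phi
  r2 <- n2 / phi
  frac <- n1 / (n1 + n2)
  s1 <- round(s1)
  s2 <- round(s2)
  vapply(seq_along(s1), function(i) {
    tt <- s1[i] + s2[i]
    if (tt <= 0) return(1)
    obs <- s1[i]
    mu1 <- tt * frac
    mu2 <- tt - mu1
    v1 <- mu1 + mu1^2 / r1
    v2 <- mu2 + mu2^2 / r2
    cv <- v1 * v2 / (v1 + v2)
    half <- max(16, ceiling(6 * sqrt(cv)))
    lo <- max(0, floor(min(mu1, obs)) - half)
    hi <- min(tt, ceiling(max(mu1, obs)) + half)
    y <- lo:hi
    lp <- stats::dnbinom(y, size = r1, mu = mu1, log = TRUE) +
      stats::dnbinom(tt - y, size = r2, mu = mu2, log = TRUE)
    w <- exp(lp - max(lp))
    z <- sum(w)
    p_low <- sum(w[y <= obs]) / z
    p_high <- sum(w[y >= obs]) / z
    min(1, 2 * min(p_low, p_high))
  }, numeric(1))
}

#' Wilcoxon rank-sum test per feature
#'
#' Alternative engine on a log-normalized expression matrix: a two-sided
#' rank-sum p-value (normal approximation with tie correction) per feature,
#' with the same pseudocounted mean-ratio log2 fold change convention as
#' [exact_test()] computed on the supplied (already normalized, non-logged)
#' values when `expr` is not on the log scale.
#'
#' @param log_expr Matrix of log2-normalized expression (features x samples).
#' @param contrast A [contrast()].
#' @return A `DEGTable` data.frame (`log2fc` here is the difference of group
#'   means on the log2 scale, the rank test's natural effect size).
#' @export
rank_test <- function(log_expr, contrast) {
  if (length(contrast$case) < 2 || length(contrast$control) < 2)
    contract_error("each group needs at least two samples")
  x <- log_expr[, contrast$case, drop = FALSE]
  y <- log_expr[, contrast$control, drop = FALSE]
  res <- vapply(seq_len(nrow(log_expr)),
                function(i) unlist(wilcox_z(x[i, ], y[i, ])[c("z", "p")]),
                numeric(2))
  mc <- rowMeans(x)
  mctl <- rowMeans(y)
  data.frame(feature_id = rownames(log_expr), log2fc = mc - mctl,
             pvalue = pmin(1, res[2, ]), mean_case = mc, mean_control = mctl,
             padj = stats::p.adjust(pmin(1, res[2, ]), "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}
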