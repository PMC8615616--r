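# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

## Canonical RNA class vocabulary. lncRNA and mRNA carry feature lengths and
## are expressed in RPKM; the small-RNA classes are expressed in RPM.
RNA_CLASSES <- c("miRNA", "piRNA", "lncRNA", "snoRNA", "snRNA", "tRNA",
                 "yRNA", "mRNA")
RPKM_CLASSES <- c("lncRNA", "mRNA")

stopf <- function(fmt, ..., class = "exoscreen_error") {
  stop(errorCondition(sprintf(fmt, ...),
                      class = unique(c(class, "exoscreen_error", "error", "condition"))))
}

format_error <- function(fmt, ...) {
  stopf(fmt, ..., class = "exoscreen_format_error")
}

contract_error <- function(fmt, ...) {
  stopf(fmt, ..., class = "exoscreen_contract_error")
}

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
## state afterwards so library functions do not perturb user simulations.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

## Wilcoxon rank-sum statistic with normal approximation and tie correction.
## Exposed internally because the cutoff optimizer needs |z| itself, not just
## the p-value. Returns W (rank-sum based U for x), z and the two-sided p.
wilcox_z <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  n <- n1 + n2
  ties <- table(r)
  v <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (v <= 0) {
    return(list(u = u, z = 0, p = 1))
  }
  z <- (u - mu) / sqrt(v)
  list(u = u, z = z, p = min(1, 2 * stats::pnorm(-abs(z))))
}
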