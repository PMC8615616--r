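# Differential expression: dispersion recovery, exact-test limits and
# symmetries, rank-test agreement with the reference implementation.

make_contrast_cols <- function(n1, n2) {
  contrast(sprintf("c%02d", seq_len(n1)), sprintf("n%02d", seq_len(n2)))
}

sim_two_group <- function(n_features, n1, n2, phi, mu_log = 4, seed = 1) {
  set.seed(seed)
  mu <- exp(rnorm(n_features, mu_log, 1))
  n <- n1 + n2
  m <- if (phi > 0) {
    matrix(rnbinom(n_features * n, mu = mu, size = 1 / phi), n_features, n)
  } else {
    matrix(rpois(n_features * n, lambda = mu), n_features, n)
  }
  dimnames(m) <- list(sprintf("g%04d", seq_len(n_features)),
                      c(sprintf("c%02d", seq_len(n1)),
                        sprintf("n%02d", seq_len(n2))))
  storage.mode(m) <- "double"
  m[rowSums(m) > 0, , drop = FALSE]
}

test_that("common dispersion is recovered from simulation truth", {
  ct <- make_contrast_cols(30, 12)
  ## Poisson data: phi-hat collapses toward zero
  m0 <- sim_two_group(2000, 30, 12, phi = 0, seed = 21)
  expect_lte(estimate_common_dispersion(m0, ct), 0.05)
  ## NB data at phi = 0.4
  m4 <- sim_two_group(2000, 30, 12, phi = 0.4, seed = 22)
  phi_hat <- estimate_common_dispersion(m4, ct)
  expect_gte(phi_hat, 0.3)
  expect_lte(phi_hat, 0.5)
  ## sufficiency: duplicating every feature leaves the estimate unchanged
  m_small <- sim_two_group(200, 30, 12, phi = 0.3, seed = 23)
  dup <- rbind(m_small, m_small)
  rownames(dup) <- sprintf("g%04d", seq_len(nrow(dup)))
  expect_equal(estimate_common_dispersion(m_small, ct),
               estimate_common_dispersion(dup, ct), tolerance = 1e-6)
  ## all-zero features are a contract violation
  mz <- rbind(m_small, zero = 0)
  expect_error(estimate_common_dispersion(mz, ct),
               class = "exoscreen_contract_error")
})

test_that("dispersion is consistent with an independent reference", {
  skip_if_not_installed("edgeR")
  ct <- make_contrast_cols(12, 12)
  m <- sim_two_group(1500, 12, 12, phi = 0.25, seed = 31)
  phi_hat <- estimate_common_dispersion(m, ct)
  d <- edgeR::estimateCommonDisp(
    edgeR::DGEList(m, group = rep(1:2, each = 12)))
  expect_equal(phi_hat, d$common.dispersion, tolerance = 0.1)
})

test_that("the most probable split gets p = 1 and swaps negate log2fc", {
  ct <- make_contrast_cols(6, 6)
  m <- sim_two_group(50, 6, 6, phi = 0.2, seed = 41)
  ## identical group sums with equal sizes on equalized libraries
  m[1, 1:6] <- c(5, 9, 7, 4, 8, 3)
  m[1, 7:12] <- c(5, 9, 7, 4, 8, 3)
  eq <- exp(mean(log(colSums(m)))) / colSums(m) # equal effective libraries
  deg <- exact_test(m, ct, dispersion = 0.2, factors = eq)
  expect_equal(deg$pvalue[1], 1)
  swapped <- exact_test(m, contrast(ct$control, ct$case), dispersion = 0.2,
                        factors = eq)
  expect_equal(swapped$log2fc, -deg$log2fc, tolerance = 1e-12)
  expect_equal(swapped$pvalue, deg$pvalue, tolerance = 1e-10)
  ## swap symmetry holds on unequal libraries too
  deg_u <- exact_test(m, ct, dispersion = 0.2)
  swap_u <- exact_test(m, contrast(ct$control, ct$case), dispersion = 0.2)
  expect_equal(swap_u$pvalue, deg_u$pvalue, tolerance = 1e-10)
})

test_that("the phi -> 0 limit reproduces the binomial split test", {
  ct <- make_contrast_cols(8, 4)
  m <- sim_two_group(300, 8, 4, phi = 0, mu_log = 3, seed = 51)
  ## equalized effective libraries so the group sums stay on the raw grid
  eq <- exp(mean(log(colSums(m)))) / colSums(m)
  deg <- exact_test(m, ct, dispersion = 1e-8, factors = eq)
  pr <- 8 / 12
  p_oracle <- vapply(seq_len(nrow(m)), function(i) {
    s1 <- sum(m[i, ct$case])
    oracle_binom_split(s1, sum(m[i, ]), pr)
  }, numeric(1))
  expect_equal(deg$pvalue, p_oracle, tolerance = 1e-6)
})

test_that("null simulations give calibrated type-I error", {
  ct <- make_contrast_cols(12, 30)
  ## no differential expression: rejection at p < 0.05 stays near nominal
  m <- sim_two_group(2000, 12, 30, phi = 0.4, seed = 61)
  phi_hat <- estimate_common_dispersion(m, ct)
  deg <- exact_test(m, ct, dispersion = phi_hat)
  frac <- mean(deg$pvalue < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
  ## p-values invariant to feature order
  perm <- sample(nrow(m))
  deg_p <- exact_test(m[perm, ], ct, dispersion = phi_hat)
  expect_equal(deg_p$pvalue, deg$pvalue[perm])
})

test_that("increasing the case counts never increases the upper-tail p", {
  ## one-sided monotonicity of the conditional split probability
  ## with the case sum above the balanced split, the doubled tail is the
  ## upper one, and pushing the case counts further up can only shrink it
  p_up <- vapply(seq(70, 150, by = 10), function(s1) {
    exoscreen:::nb_split_pvalue(s1, 60, n1 = 5, n2 = 5, phi = 0.2)
  }, numeric(1))
  expect_true(all(diff(p_up) <= 1e-12))
})

test_that("the rank engine matches the reference Wilcoxon implementation", {
  set.seed(71)
  ct <- make_contrast_cols(12, 30)
  x <- matrix(rnorm(100 * 42), 100, 42,
              dimnames = list(sprintf("g%03d", 1:100),
                              c(ct$case, ct$control)))
  x[3, ] <- round(x[3, ]) # force ties
  deg <- rank_test(x, ct)
  p_ref <- vapply(seq_len(nrow(x)), function(i) {
    suppressWarnings(stats::wilcox.test(x[i, ct$case], x[i, ct$control],
                                        exact = FALSE,
                                        correct = FALSE)$p.value)
  }, numeric(1))
  expect_equal(deg$pvalue, p_ref, tolerance = 1e-8)
  ## all case values strictly greater: U = 360, far tail
  x2 <- x
  x2[1, ct$case] <- x2[1, ct$case] + 100
  expect_lt(rank_test(x2, ct)$pvalue[1], 1e-6)
  ## identical groups: p = 1
  x3 <- x
  x3[1, ] <- 1
  expect_equal(rank_test(x3, ct)$pvalue[1], 1)
})
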