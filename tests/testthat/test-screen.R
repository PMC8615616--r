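# Statistical and biological screening rules.

test_that("the three-contrast rule selects exactly per its definition", {
  ids <- sprintf("g%02d", 1:3)
  a <- deg_stub(ids, c(2.5, 2.5, 2.5), c(0.01, 0.01, 0.01))
  b <- deg_stub(ids, c(2.1, 2.1, 1.0), c(0.01, 0.01, 0.01))
  cc <- deg_stub(ids, c(2.0, -2.1, 3.5), c(0.01, 0.01, 0.01))
  sel <- statistical_select(a, b, cc)
  ## g01: all gates pass, |B+C| = 4.1 > 4; g02: |B+C| = 0; g03: 4.5 > 4
  expect_setequal(sel$selected, c("g01", "g03"))
  expect_true(all(sel$table$pass_a))
  expect_false(sel$table$pass_combined[2])
  ## features absent from B or C fail the combined rule
  sel2 <- statistical_select(a, b[1:2, ], cc[1:2, ])
  expect_setequal(sel2$selected, "g01")
  ## features outside the A universe are a contract violation
  expect_error(statistical_select(a[1:2, ], b, cc),
               class = "exoscreen_contract_error")
})

test_that("the selection rule agrees with a row-wise oracle and is monotone", {
  set.seed(8)
  ids <- sprintf("g%02d", 1:10)
  for (i in 1:50) {
    a <- deg_stub(ids, runif(10, -4, 4), runif(10))
    b <- deg_stub(ids, runif(10, -4, 4), runif(10))
    cc <- deg_stub(ids, runif(10, -4, 4), runif(10))
    pars <- stat_screen_params(lfc_a = runif(1, 0.5, 3),
                               p_max = runif(1, 0.01, 0.5),
                               combined_min = runif(1, 1, 6))
    sel <- statistical_select(a, b, cc, pars)$selected
    expect_setequal(sel, oracle_statistical_select(
      a, b, cc, pars$lfc_a, pars$p_max, pars$combined_min))
    ## relaxing every threshold never removes a selected feature
    relaxed <- stat_screen_params(lfc_a = pars$lfc_a / 2,
                                  p_max = min(1 - 1e-9, pars$p_max * 2),
                                  combined_min = pars$combined_min / 2)
    expect_true(all(sel %in% statistical_select(a, b, cc, relaxed)$selected))
  }
})

test_that("paired responses follow the log-ratio definition", {
  st <- toy_samples(nn = 2, nc = 3)
  pre <- paste0(sprintf("P%02d", 1:3), "_pre")
  post <- paste0(sprintf("P%02d", 1:3), "_post")
  x <- matrix(runif(5 * 6, 1, 100), 5, 6,
              dimnames = list(letters[1:5], c(pre, post)))
  ## post = pre -> all-zero responses
  x[, post] <- x[, pre]
  expect_true(all(paired_response(x, st) == 0))
  ## post = 4 * (pre + pc) - pc -> every response exactly 2
  x[, post] <- 4 * (x[, pre] + 1) - 1
  r <- paired_response(x, st, pseudocount = 1)
  expect_equal(unname(r), matrix(2, 5, 3), tolerance = 1e-12)
  expect_equal(colnames(r), sprintf("P%02d", 1:3))
  ## an incomplete pair is dropped with a warning; none left is an error
  expect_warning(r2 <- paired_response(x[, -6], st), "P03")
  expect_equal(ncol(r2), 2)
  expect_error(suppressWarnings(paired_response(x[, 1:3], st)),
               class = "exoscreen_contract_error")
})

test_that("related counts match their definition and are symmetric", {
  set.seed(9)
  cand <- matrix(rnorm(2 * 30), 2, 30,
                 dimnames = list(c("c1", "c2"), sprintf("P%02d", 1:30)))
  part <- matrix(rnorm(4 * 30), 4, 30,
                 dimnames = list(paste0("m", 1:4), sprintf("P%02d", 1:30)))
  part[1, ] <- cand[1, ] # identical partner -> r = 1
  rel <- related_counts(cand, part, r_min = 0.7)
  expect_equal(attr(rel, "partners")$c1$r[1], 1)
  expect_equal(attr(rel, "partners")$c1$partner_id[1], "m1")
  expect_equal(rel$best_r[1], 1)
  ## symmetry of the correlation in candidate/partner roles
  rel_t <- related_counts(part, cand, r_min = 0.7)
  expect_equal(attr(rel_t, "partners")$m1$r[
    attr(rel_t, "partners")$m1$partner_id == "c1"], 1)
  ## zero-variance rows are warned about and treated as unrelated
  cand[2, ] <- 5
  expect_warning(rel0 <- related_counts(cand, part, r_min = 0.7),
                 "zero-variance")
  expect_equal(rel0$n_related[2], 0L)
})

test_that("cutoff optimization finds a planted change-point", {
  ## 28 candidates mirroring the lncRNA screen: four with many related mRNAs
  ## (small DEG p), the rest at or below 100 (large p); 100 is attained
  n_rel <- c(140, 130, 120, 110, 100, 95, seq(90, 2, length.out = 22))
  names(n_rel) <- sprintf("l%02d", 1:28)
  p <- c(rep(1e-6, 4), rep(0.04, 24)) * exp(runif(28, 0, 0.1))
  names(p) <- names(n_rel)
  res <- optimize_cutoff(round(n_rel), p)
  expect_equal(res$cutoff, 100)
  expect_setequal(res$high, sprintf("l%02d", 1:4))
  ## perfectly ordered p-values with a gap: cutoff lands at the gap
  n2 <- c(a = 50, b = 40, c = 30, d = 5, e = 4, f = 3)
  p2 <- c(a = 1e-8, b = 1e-7, c = 1e-6, d = 0.5, e = 0.6, f = 0.7)
  res2 <- optimize_cutoff(n2, p2)
  expect_equal(res2$cutoff, 5)
  ## invariance to candidate order and to monotone transforms of the counts
  perm <- sample(length(n_rel))
  res_p <- optimize_cutoff(round(n_rel)[perm], p)
  expect_setequal(res_p$high, res$high)
  res_m <- optimize_cutoff(round(n_rel)^2 + 3, p)
  expect_setequal(res_m$high, res$high)
  expect_equal(res_m$separation, res$separation)
  ## no admissible partition
  expect_error(optimize_cutoff(c(x = 1, y = 1), c(x = 0.1, y = 0.2)),
               class = "exoscreen_contract_error")
})

test_that("the biological branch rule follows class size and strong correlates", {
  ids13 <- sprintf("mi%02d", 1:13)
  rel13 <- data.frame(feature_id = ids13, n_related = 0L, best_r = 0)
  small <- biological_select(ids13, rel13)
  expect_equal(small$branch, "small")
  expect_setequal(small$final, ids13) # all 13 forwarded for review
  ## large branch: 28 candidates, 4 above the cutoff with |best r| >= 0.9
  ids28 <- sprintf("l%02d", 1:28)
  rel28 <- data.frame(feature_id = ids28,
                      n_related = c(140, 130, 120, 110, rep(3, 24)),
                      best_r = c(0.95, -0.93, 0.92, 0.91, rep(0.5, 24)))
  cut <- list(cutoff = 100, separation = 4,
              high = ids28[1:4], low = ids28[-(1:4)])
  large <- biological_select(ids28, rel28, cut)
  expect_equal(large$branch, "large")
  expect_setequal(large$final, ids28[1:4]) # negative strong r counts too
  ## high group present but nothing strongly correlated -> empty with a note
  rel_weak <- transform(rel28, best_r = 0.5)
  empty <- biological_select(ids28, rel_weak, cut)
  expect_length(empty$final, 0)
  expect_match(empty$notes, "no high candidate")
  ## missing cutoff on the large branch is a contract violation
  expect_error(biological_select(ids28, rel28, NULL),
               class = "exoscreen_contract_error")
  ## exactly 20 goes to the small branch
  ids20 <- sprintf("s%02d", 1:20)
  expect_equal(biological_select(ids20, rel13[1:13, ])$branch, "small")
})
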