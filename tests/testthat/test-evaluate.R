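# MDS, cluster diagnosis, hierarchical clustering, subgroup flagging,
# ROC/AUC, panels, OLS helper.

test_that("classical MDS reconstructs exact low-dimensional configurations", {
  ## 3 collinear points with gaps 1 and 2
  pts <- matrix(c(0, 1, 3), ncol = 1)
  emb <- classical_mds(t(pts), dim = 1, samples_in = "columns")
  expect_equal(unname(as.vector(dist(emb$points))), c(1, 3, 2),
               tolerance = 1e-9) # gaps 1 and 2 -> pairwise distances 1, 3, 2
  ## points already in 2D embed isometrically
  set.seed(12)
  p2 <- matrix(rnorm(20), 10, 2)
  emb2 <- classical_mds(p2, dim = 2, samples_in = "rows")
  expect_equal(as.vector(dist(emb2$points)), as.vector(dist(p2)),
               tolerance = 1e-9)
  expect_lt(max(abs(colMeans(emb2$points))), 1e-9) # centered
  expect_true(all(diff(emb2$eig) <= 1e-9))         # decreasing eigenvalues
})

test_that("MDS agrees with an eigendecomposition oracle and is contractive", {
  set.seed(13)
  x <- matrix(rnorm(20 * 40), 40, 20) # 40 features x 20 samples
  emb <- classical_mds(x, dim = 2)
  oracle <- oracle_mds_points(t(x), dim = 2)
  expect_equal(as.vector(dist(emb$points)), as.vector(dist(oracle)),
               tolerance = 1e-8)
  ## projection: embedded distances never exceed the originals
  expect_true(all(dist(emb$points) <= dist(t(x)) + 1e-9))
})

test_that("k-means diagnosis recovers separated groups and reports counts", {
  set.seed(14)
  labels <- rep(c("cancer", "normal"), c(30, 12))
  blobs <- rbind(matrix(rnorm(60, 5), 30, 2), matrix(rnorm(24, -5), 12, 2))
  d <- kmeans_diagnose(blobs, k = 2, labels)
  expect_equal(d$sensitivity, 1)
  expect_equal(d$specificity, 1)
  expect_true(d$informative)
  ## 25 of 30 cancers in the cancer cluster, all normals correct:
  ## sensitivity 25/30 = 0.833, specificity 1 (the study's reporting style)
  blobs2 <- blobs
  blobs2[26:30, ] <- matrix(rnorm(10, -5), 5, 2) # 5 cancers sit with normals
  d2 <- kmeans_diagnose(blobs2, k = 2, labels)
  expect_equal(d2$tp, 25)
  expect_equal(d2$sensitivity, 25 / 30, tolerance = 1e-12)
  expect_equal(d2$specificity, 1)
  ## k = 3 merges the two cancer-majority clusters
  blobs3 <- rbind(matrix(rnorm(30, 9), 15, 2), matrix(rnorm(30, 3), 15, 2),
                  matrix(rnorm(24, -6), 12, 2))
  d3 <- kmeans_diagnose(blobs3, k = 3, labels)
  expect_equal(d3$sensitivity, 1)
  expect_equal(d3$specificity, 1)
  ## shuffled labels are non-informative
  d4 <- kmeans_diagnose(blobs, k = 2, sample(labels))
  expect_false(d4$informative)
  expect_error(kmeans_diagnose(blobs[1:2, ], k = 3, labels[1:2]),
               class = "exoscreen_contract_error")
})

test_that("hierarchical clustering matches a naive agglomerative oracle", {
  set.seed(15)
  x <- matrix(rnorm(10 * 6), 10, 6,
              dimnames = list(letters[1:10], LETTERS[1:6]))
  hc <- hcluster_order(x)
  expect_equal(hc$row_tree$height, oracle_hclust_heights(x),
               tolerance = 1e-10)
  ## two identical rows merge first at height zero
  x2 <- x
  x2[2, ] <- x2[1, ]
  hc2 <- hcluster_order(x2)
  expect_equal(hc2$row_tree$height[1], 0)
  expect_setequal(abs(hc2$row_tree$merge[1, ]), c(1, 2))
  ## planted 2 + 2 structure merges within pairs first
  y <- rbind(a = c(0, 0), b = c(0.1, 0), c = c(10, 10), d = c(10.1, 10))
  hc3 <- hcluster_order(y)
  first_two <- lapply(1:2, function(i) sort(abs(hc3$row_tree$merge[i, ])))
  expect_setequal(lapply(first_two, paste, collapse = "-"),
                  c("1-2", "3-4"))
})

test_that("subgroup flagging finds a planted overexpression block", {
  set.seed(16)
  n <- 30
  x <- matrix(rnorm(7 * n, 5, 0.5), 7, n,
              dimnames = list(paste0("sno", 1:7), sprintf("P%02d", 1:n)))
  x[, 1:12] <- x[, 1:12] + 4
  fl <- flag_subgroup(x)
  expect_true(fl$flagged)
  expect_setequal(fl$samples, sprintf("P%02d", 1:12))
  ## null matrices stay unflagged in nearly every draw
  unflagged <- vapply(1:10, function(i) {
    z <- matrix(rnorm(7 * n, 5, 0.5), 7, n,
                dimnames = list(paste0("sno", 1:7), sprintf("P%02d", 1:n)))
    !flag_subgroup(z)$flagged
  }, logical(1))
  expect_gte(sum(unflagged), 9)
  ## uniformly overexpressed: everything is returned but not flagged
  u <- matrix(rnorm(7 * n, 9, 0.3), 7, n,
              dimnames = list(paste0("sno", 1:7), sprintf("P%02d", 1:n)))
  fu <- flag_subgroup(u)
  expect_false(fu$flagged)
  expect_length(fu$samples, n)
  ## constant matrix: warning, empty subgroup
  k <- matrix(1, 3, n, dimnames = list(letters[1:3], sprintf("P%02d", 1:n)))
  expect_warning(fk <- flag_subgroup(k), "degenerate")
  expect_length(fk$samples, 0)
})

test_that("ROC analysis matches pair counting and handles ties", {
  ## hand example: 3 of 4 case/control pairs concordant -> AUC 0.75
  r <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c("normal", "normal", "cancer",
                                         "cancer"))
  expect_equal(r$auc, 0.75)
  expect_equal(r$auc, r$auc_rank)
  ## perfectly separated scores
  rp <- roc_auc(c(1, 2, 3, 11, 12), rep(c("normal", "cancer"), c(3, 2)))
  expect_equal(rp$auc, 1)
  expect_equal(rp$youden_sensitivity, 1)
  expect_equal(rp$youden_specificity, 1)
  ## identical scores: tie convention gives AUC 0.5
  rt <- roc_auc(rep(2, 10), rep(c("normal", "cancer"), 5))
  expect_equal(rt$auc, 0.5)
  ## random instances up to n = 200, with ties, against the pair oracle
  set.seed(17)
  for (i in 1:20) {
    n <- sample(4:200, 1)
    lab <- sample(c("normal", "cancer"), n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    sc <- round(rnorm(n), sample(0:2, 1)) # rounding forces ties
    rr <- roc_auc(sc, lab)
    expect_equal(rr$auc, oracle_auc_pairs(sc, lab), tolerance = 1e-12)
    expect_equal(rr$auc, rr$auc_rank, tolerance = 1e-12)
    expect_true(all(diff(rr$tpr) >= 0) && all(diff(rr$fpr) >= 0))
  }
  expect_error(roc_auc(1:3, rep("cancer", 3)),
               class = "exoscreen_contract_error")
})

test_that("ROC agrees with the pROC reference on a random instance", {
  skip_if_not_installed("pROC")
  set.seed(18)
  lab <- rep(c("normal", "cancer"), c(20, 25))
  sc <- rnorm(45) + (lab == "cancer")
  r <- roc_auc(sc, lab)
  pr <- pROC::roc(response = lab, predictor = sc, levels = c("normal",
                                                             "cancer"),
                  direction = "<", quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
})

test_that("panel scores orient, tolerate collinearity and combine markers", {
  set.seed(19)
  lab <- rep(c("normal", "cancer"), c(12, 30))
  ## single feature lower in cancer: orientation flips so AUC >= 0.5
  x1 <- matrix(rnorm(42) - 2 * (lab == "cancer"), 1, 42,
               dimnames = list("f1", sprintf("s%02d", 1:42)))
  ps1 <- panel_score(x1, lab)
  expect_gte(roc_auc(ps1$scores, lab)$auc, 0.5)
  ## a duplicated feature leaves the panel AUC unchanged
  x2 <- rbind(x1, f2 = x1[1, ])
  expect_equal(roc_auc(panel_score(x2, lab)$scores, lab)$auc,
               roc_auc(ps1$scores, lab)$auc, tolerance = 1e-9)
  ## three informative markers: the logistic panel dominates each singleton
  x3 <- rbind(a = rnorm(42) + 1.2 * (lab == "cancer"),
              b = rnorm(42) + 1.2 * (lab == "cancer"),
              c = rnorm(42) - 1.2 * (lab == "cancer"))
  colnames(x3) <- sprintf("s%02d", 1:42)
  panel_auc <- roc_auc(panel_score(x3, lab)$scores, lab)$auc
  single_aucs <- vapply(rownames(x3), function(f)
    roc_auc(panel_score(x3[f, , drop = FALSE], lab)$scores, lab)$auc,
    numeric(1))
  expect_gte(panel_auc, max(single_aucs))
  ## constant features are dropped with a warning
  x4 <- rbind(x3, k = 1)
  expect_warning(ps4 <- panel_score(x4, lab), "constant")
  expect_setequal(ps4$features, c("a", "b", "c"))
})

test_that("panel search ranks deterministically and finds complements", {
  set.seed(20)
  lab <- rep(c("normal", "cancer"), c(12, 30))
  ## marker 'dom' separates everything; 'h1'/'h2' each cover half the cancers
  dom <- c(rnorm(12, 0), rnorm(30, 6))
  h1 <- c(rnorm(12, 0), rnorm(15, 6), rnorm(15, 0))
  h2 <- c(rnorm(12, 0), rnorm(15, 0), rnorm(15, 6))
  x <- rbind(dom = dom, h1 = h1, h2 = h2)
  colnames(x) <- sprintf("s%02d", 1:42)
  ranked <- panel_search(x, lab, max_size = 2)
  expect_equal(ranked[1, "sensitivity"], 1)
  expect_equal(ranked[1, "specificity"], 1)
  size1 <- ranked[ranked$size == 1, ]
  expect_equal(size1$panel[1], "dom") # dominant singleton ranked first
  ## the complementary pair outranks each of its singletons
  pair_row <- which(ranked$panel == "h1+h2")
  expect_lt(pair_row, which(ranked$panel == "h1"))
  expect_lt(pair_row, which(ranked$panel == "h2"))
  ## determinism
  ranked2 <- panel_search(x, lab, max_size = 2)
  expect_identical(ranked, ranked2)
  expect_error(panel_search(x[0, , drop = FALSE], lab),
               class = "exoscreen_contract_error")
})

test_that("the OLS helper reports exact fits and null fits", {
  fit <- linear_r2(1:10, 2 * (1:10) + 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r2, 1)
  ## symmetric hand data: the best fit has zero slope, so R^2 = 0
  fit0 <- linear_r2(c(0, 1, 2), c(0, 1, 0))
  expect_equal(fit0$slope, 0)
  expect_equal(fit0$r2, 0, tolerance = 1e-12)
  ## y independent of x: R^2 concentrates near 1/(n-1)
  set.seed(21)
  r2s <- replicate(200, linear_r2(rnorm(20), rnorm(20))$r2)
  expect_equal(mean(r2s), 1 / 19, tolerance = 0.02)
  expect_error(linear_r2(rep(1, 5), rnorm(5)),
               class = "exoscreen_contract_error")
})
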