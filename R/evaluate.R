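# Diagnostic evaluation: classical MDS, k-means cluster diagnosis,
# hierarchical clustering orders, patient-subgroup flagging, ROC/AUC, and
# marker-panel scoring and search.

#' Classical (metric) multidimensional scaling of samples
#'
#' Euclidean distances between samples (columns by default), double-centered
#' Gram matrix, top-`dim` eigenvectors scaled by the square root of their
#' eigenvalues. Negative eigenvalues are truncated at zero; when fewer than
#' `dim` positive eigenvalues exist, the available dimensions are returned
#' with a warning.
#'
#' @param x Matrix, typically log2-normalized expression (features x
#'   samples).
#' @param dim Number of embedding dimensions (default 2).
#' @param samples_in `"columns"` (default) or `"rows"`.
#' @return List of class `mds_embedding` with `points` (samples x dim,
#'   column-centered) and `eig` (all eigenvalues, decreasing).
#' @export
classical_mds <- function(x, dim = 2, samples_in = c("columns", "rows")) {
  samples_in <- match.arg(samples_in)
  pts <- if (samples_in == "columns") t(x) else x
  if (nrow(pts) < dim + 1)
    contract_error("need at least dim + 1 = %d samples", dim + 1)
  d <- stats::dist(pts)
  fit <- stats::cmdscale(d, k = dim, eig = TRUE)
  got <- ncol(fit$points)
  if (got < dim)
    warnf("only %d positive MDS dimensions available (requested %d)", got, dim)
  structure(list(points = fit$points, eig = fit$eig), class = "mds_embedding")
}

#' Diagnose samples by k-means clustering of an embedding
#'
#' Clusters the embedded samples with `k` means (many random restarts, best
#' within-cluster sum of squares kept), maps every cluster to its majority
#' true label, and -- with k = 3 -- merges the cancer-majority clusters for
#' diagnosis. Sensitivity is the fraction of cancer samples assigned to a
#' cancer cluster; specificity the fraction of normal samples assigned to a
#' normal cluster.
#'
#' @param embedding An [classical_mds()] result (or a samples x dims matrix).
#' @param k Number of clusters, 2 or 3.
#' @param labels Character vector (`"normal"`/`"cancer"`) per sample.
#' @param n_restarts Random restarts for k-means.
#' @param seed Seed for the restarts (RNG state is restored afterwards).
#' @return List of class `cluster_diagnosis`: `assignments`, `cluster_labels`,
#'   `sensitivity`, `specificity`, counts `tp`/`fn`/`tn`/`fp`, and
#'   `informative` (Youden index above 0.25).
#' @export
kmeans_diagnose <- function(embedding, k = 2, labels, n_restarts = 50,
                            seed = 0) {
  pts <- if (inherits(embedding, "mds_embedding")) embedding$points else
    as.matrix(embedding)
  if (k > nrow(pts)) contract_error("k = %d exceeds the sample count", k)
  if (length(labels) != nrow(pts))
    contract_error("labels must have one entry per sample")
  if (!all(labels %in% c("normal", "cancer")))
    contract_error("labels must be 'normal' or 'cancer'")
  km <- with_local_seed(seed,
    stats::kmeans(pts, centers = k, nstart = n_restarts, iter.max = 100))
  cl <- km$cluster
  cluster_labels <- vapply(seq_len(k), function(g) {
    n_cancer <- sum(labels[cl == g] == "cancer")
    n_normal <- sum(cl == g) - n_cancer
    if (n_cancer >= n_normal) "cancer" else "normal" # majority; ties -> cancer
  }, character(1))
  pred <- cluster_labels[cl]
  tp <- sum(pred == "cancer" & labels == "cancer")
  fn <- sum(pred == "normal" & labels == "cancer")
  tn <- sum(pred == "normal" & labels == "normal")
  fp <- sum(pred == "cancer" & labels == "normal")
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  structure(list(assignments = cl, cluster_labels = cluster_labels,
                 sensitivity = sens, specificity = spec,
                 tp = tp, fn = fn, tn = tn, fp = fp,
                 informative = isTRUE(sens + spec - 1 > 0.25)),
            class = "cluster_diagnosis")
}

#' Hierarchical clustering orders for heatmap export
#'
#' Agglomerative clustering of rows and columns; leaf orders are the
#' deterministic `stats::hclust` orders.
#'
#' @param x Matrix (e.g. log2-normalized expression).
#' @param linkage Agglomeration method (default `"complete"`).
#' @param metric Distance metric (default `"euclidean"`).
#' @return List with `row_order`, `col_order`, `row_tree`, `col_tree` and the
#'   reordered matrix `ordered`.
#' @export
hcluster_order <- function(x, linkage = "complete", metric = "euclidean") {
  if (nrow(x) < 2) contract_error("need at least two rows to cluster")
  rt <- stats::hclust(stats::dist(x, method = metric), method = linkage)
  ct <- if (ncol(x) >= 2)
    stats::hclust(stats::dist(t(x), method = metric), method = linkage)
  ro <- rt$order
  co <- if (is.null(ct)) seq_len(ncol(x)) else ct$order
  list(row_order = ro, col_order = co, row_tree = rt, col_tree = ct,
       ordered = x[ro, co, drop = FALSE])
}

#' Flag a homogeneously overexpressed sample subgroup
#'
#' Splits the cancer samples into two k-means clusters over the supplied
#' feature set and nominates the higher-mean cluster as the subgroup,
#' provided at least `min_fraction_high` of its sample-by-feature values
#' exceed the overall median and the clusters are separated by at least
#' `min_separation` on the log2 scale. A near-degenerate split returns all
#' samples unflagged; a separated but inhomogeneous split returns an empty
#' subgroup.
#'
#' @param expr_log Log2 expression of the feature set (features x cancer
#'   samples), at least two features.
#' @param min_fraction_high Homogeneity requirement (default 0.75).
#' @param min_separation Minimum between-cluster mean difference (log2 units).
#' @param n_restarts,seed k-means restarts and seed.
#' @return List with `samples` (subgroup sample ids), `flagged` (logical),
#'   `fraction_high`, `separation` and `reason`.
#' @export
flag_subgroup <- function(expr_log, min_fraction_high = 0.75,
                          min_separation = 1, n_restarts = 20, seed = 0) {
  if (nrow(expr_log) < 2) contract_error("need at least two features")
  if (stats::sd(expr_log) == 0 || anyNA(expr_log)) {
    warnf("degenerate (constant or missing) expression matrix; no subgroup")
    return(list(samples = character(0), flagged = FALSE,
                fraction_high = NA_real_, separation = 0,
                reason = "degenerate matrix"))
  }
  km <- with_local_seed(seed,
    stats::kmeans(t(expr_log), centers = 2, nstart = n_restarts,
                  iter.max = 100))
  m <- tapply(colMeans(expr_log), km$cluster, mean)
  high <- as.integer(names(which.max(m)))
  sepn <- abs(diff(range(m)))
  high_cols <- km$cluster == high
  frac <- mean(expr_log[, high_cols, drop = FALSE] > stats::median(expr_log))
  if (sepn < min_separation) {
    return(list(samples = colnames(expr_log), flagged = FALSE,
                fraction_high = frac, separation = sepn,
                reason = "no discriminative split: clusters nearly coincide"))
  }
  if (frac < min_fraction_high) {
    return(list(samples = character(0), flagged = FALSE,
                fraction_high = frac, separation = sepn,
                reason = sprintf("high cluster not homogeneous (%.2f < %.2f)",
                                 frac, min_fraction_high)))
  }
  list(samples = colnames(expr_log)[high_cols], flagged = TRUE,
       fraction_high = frac, separation = sepn,
       reason = sprintf("homogeneously overexpressed in %d of %d samples",
                        sum(high_cols), ncol(expr_log)))
}

#' ROC curve and AUC
#'
#' ROC over all score thresholds (tied scores collapse into one threshold),
#' trapezoidal AUC cross-checked internally against the rank (Mann-Whitney)
#' formulation, and the Youden-optimal operating point (ties resolved toward
#' higher specificity).
#'
#' @param scores Numeric scores, higher = more cancer-like.
#' @param labels `"normal"`/`"cancer"` per score (or logical, TRUE =
#'   positive).
#' @param positive Positive-class label.
#' @return List of class `roc_result`: `thresholds`, `tpr`, `fpr`, `auc`,
#'   `auc_rank`, `youden_sensitivity`, `youden_specificity`,
#'   `youden_threshold`.
#' @export
roc_auc <- function(scores, labels, positive = "cancer") {
  pos <- if (is.logical(labels)) labels else labels == positive
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0)
    contract_error("both classes must be present for a ROC curve")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- pos[ord]
  ends <- cumsum(rle(s)$lengths)            # block ends of tied scores
  tpr <- c(0, cumsum(y)[ends] / n1)
  fpr <- c(0, cumsum(!y)[ends] / n0)
  thresholds <- c(Inf, s[ends])
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  r <- rank(scores)
  u <- sum(r[pos]) - n1 * (n1 + 1) / 2
  auc_rank <- u / (n1 * n0)
  j <- tpr - fpr
  best <- which(j == max(j))
  best <- best[which.min(fpr[best])]        # ties -> higher specificity
  structure(list(thresholds = thresholds, tpr = tpr, fpr = fpr,
                 auc = auc, auc_rank = auc_rank,
                 youden_sensitivity = tpr[best],
                 youden_specificity = 1 - fpr[best],
                 youden_threshold = thresholds[best]),
            class = "roc_result")
}

#' Combined panel score
#'
#' One feature: its log expression, sign-oriented so the cancer group scores
#' higher (AUC at least 0.5). Several features: the linear score of an
#' unregularized maximum-likelihood logistic model; complete separation is
#' tolerated (iterations capped) and flagged.
#'
#' @param expr_log Log2 expression of the panel features (features x
#'   samples).
#' @param labels `"normal"`/`"cancer"` per sample.
#' @return List with `scores` (per sample), `coefficients`, `features` and
#'   `separation_flagged`.
#' @export
panel_score <- function(expr_log, labels, positive = "cancer") {
  if (is.null(dim(expr_log)))
    expr_log <- matrix(expr_log, nrow = 1,
                       dimnames = list("feature", names(expr_log)))
  keep <- apply(expr_log, 1, stats::sd) > 0
  if (!all(keep)) {
    warnf("dropping %d constant panel feature(s)", sum(!keep))
    expr_log <- expr_log[keep, , drop = FALSE]
  }
  if (!nrow(expr_log)) contract_error("no non-constant panel feature left")
  y <- as.integer(labels == positive)
  if (nrow(expr_log) == 1) {
    x <- expr_log[1, ]
    flip <- roc_auc(x, labels, positive)$auc < 0.5
    return(list(scores = if (flip) -x else x,
                coefficients = stats::setNames(if (flip) -1 else 1,
                                               rownames(expr_log)),
                features = rownames(expr_log), separation_flagged = FALSE))
  }
  df <- data.frame(t(expr_log))
  fit <- suppressWarnings(
    stats::glm(y ~ ., data = df, family = stats::binomial(),
               control = stats::glm.control(maxit = 50)))
  sep <- !fit$converged || any(abs(stats::coef(fit)) > 1e3, na.rm = TRUE)
  list(scores = stats::setNames(as.numeric(stats::predict(fit, type = "link")),
                                colnames(expr_log)),
       coefficients = stats::coef(fit),
       features = rownames(expr_log), separation_flagged = sep)
}

#' Search marker panels
#'
#' Evaluates feature panels up to `max_size` (exhaustively while the number
#' of panels stays within `exhaustive_budget`, greedy forward selection
#' beyond), ranking by k-means cluster diagnosis (sensitivity + specificity)
#' of the panel's MDS embedding, then by in-sample logistic-score AUC, then
#' lexicographically -- a deterministic ordering.
#'
#' @param expr_log Log2 expression of all candidate features (features x
#'   samples).
#' @param labels `"normal"`/`"cancer"` per sample.
#' @param max_size Largest panel size (default 3).
#' @param exhaustive_budget Maximum number of panels evaluated exhaustively.
#' @param n_restarts,seed k-means restarts and seed per panel.
#' @return Data.frame of panels ranked best-first: `panel`, `size`,
#'   `sensitivity`, `specificity`, `auc`.
#' @export
panel_search <- function(expr_log, labels, max_size = 3,
                         exhaustive_budget = 2000, n_restarts = 25,
                         seed = 0) {
  feats <- rownames(expr_log)
  if (!length(feats)) contract_error("empty candidate feature set")
  max_size <- min(max_size, length(feats))
  n_panels <- sum(choose(length(feats), seq_len(max_size)))
  combos <- if (n_panels <= exhaustive_budget) {
    unlist(lapply(seq_len(max_size), function(k)
      utils::combn(sort(feats), k, simplify = FALSE)), recursive = FALSE)
  } else {
    greedy_panels(expr_log, labels, max_size, n_restarts, seed)
  }
  rows <- lapply(combos, function(ids)
    cbind(data.frame(panel = paste(ids, collapse = "+"), size = length(ids),
                     stringsAsFactors = FALSE),
          evaluate_panel(expr_log[ids, , drop = FALSE], labels, n_restarts,
                         seed)))
  out <- do.call(rbind, rows)
  out <- out[order(-(out$sensitivity + out$specificity), -out$auc, out$panel),
             , drop = FALSE]
  rownames(out) <- NULL
  out
}

evaluate_panel <- function(expr_log, labels, n_restarts, seed) {
  emb <- if (nrow(expr_log) == 1) {
    matrix(expr_log[1, ], ncol = 1)
  } else {
    classical_mds(expr_log, dim = min(2, nrow(expr_log) - 1))$points
  }
  diag <- kmeans_diagnose(emb, k = 2, labels, n_restarts = n_restarts,
                          seed = seed)
  auc <- tryCatch(
    roc_auc(panel_score(expr_log, labels)$scores, labels)$auc,
    error = function(e) NA_real_)
  data.frame(sensitivity = diag$sensitivity, specificity = diag$specificity,
             auc = auc)
}

## Greedy forward selection: grow the best panel one feature at a time,
## keeping every prefix in the evaluated set.
greedy_panels <- function(expr_log, labels, max_size, n_restarts, seed) {
  feats <- sort(rownames(expr_log))
  chosen <- character(0)
  panels <- lapply(feats, function(f) f)
  for (size in seq_len(max_size)) {
    cand <- setdiff(feats, chosen)
    if (!length(cand)) break
    scores <- vapply(cand, function(f) {
      ev <- evaluate_panel(expr_log[c(chosen, f), , drop = FALSE], labels,
                           n_restarts, seed)
      ev$sensitivity + ev$specificity + ifelse(is.na(ev$auc), 0, ev$auc / 1e3)
    }, numeric(1))
    chosen <- c(chosen, cand[order(-scores, cand)[1]])
    panels <- c(panels, list(chosen))
  }
  unique(panels)
}

#' Ordinary least squares with R-squared
#'
#' @param x,y Numeric vectors, `n >= 3`; `x` must not be constant.
#' @return List with `slope`, `intercept` and `r2` (1 - SSE/SST).
#' @export
linear_r2 <- function(x, y) {
  if (length(x) < 3 || length(x) != length(y))
    contract_error("need n >= 3 paired observations")
  if (stats::sd(x) == 0) contract_error("x is constant")
  fit <- stats::lm.fit(cbind(1, x), y)
  sse <- sum(fit$residuals^2)
  sst <- sum((y - mean(y))^2)
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       r2 = if (sst > 0) 1 - sse / sst else NA_real_)
}
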