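# Independent oracles, each coded naively and directly from the published
# formulas or by brute force, used to cross-check the package implementations.

## Naive TMM: per-sample loop, sort-based double trimming, precision-weighted
## mean of M-values; reference = sample whose upper-quartile proportion is
## closest to the mean upper quartile.
oracle_tmm <- function(counts, logratio_trim = 0.3, abs_trim = 0.05) {
  lib <- colSums(counts)
  props <- sweep(counts, 2, lib, "/")
  uq <- apply(props, 2, quantile, probs = 0.75)
  ref <- which.min(abs(uq - mean(uq)))
  fac <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    ok <- counts[, j] > 0 & counts[, ref] > 0
    M <- log2(props[ok, j] / props[ok, ref])
    A <- 0.5 * log2(props[ok, j] * props[ok, ref])
    w <- (lib[j] - counts[ok, j]) / (lib[j] * counts[ok, j]) +
      (lib[ref] - counts[ok, ref]) / (lib[ref] * counts[ok, ref])
    if (max(abs(M)) < 1e-6) {
      fac[j] <- 1
      next
    }
    n <- length(M)
    ## tie-averaged rank, built from sorted positions (exact-value ties)
    avg_rank <- function(v) {
      r <- numeric(n)
      r[order(v)] <- seq_len(n)
      for (val in unique(v[duplicated(v)])) {
        idx <- which(v == val)
        r[idx] <- mean(r[idx])
      }
      r
    }
    rM <- avg_rank(M)
    rA <- avg_rank(A)
    loM <- floor(n * logratio_trim) + 1
    loA <- floor(n * abs_trim) + 1
    sel <- rM >= loM & rM <= n + 1 - loM & rA >= loA & rA <= n + 1 - loA
    fac[j] <- 2^(sum(M[sel] / w[sel]) / sum(1 / w[sel]))
  }
  fac / exp(mean(log(fac)))
}

## Two-sided binomial exact test of a group-sum split given the total,
## doubling the smaller tail (the Poisson/phi->0 limit of the NB split test).
oracle_binom_split <- function(s1, total, pr) {
  p_low <- pbinom(s1, total, pr)
  p_high <- 1 - pbinom(s1 - 1, total, pr)
  min(1, 2 * min(p_low, p_high))
}

## Union-find.
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

## Brute-force minimum spanning forest weight: enumerate all edge subsets of
## tree size per component. Practical for <= ~20 edges.
oracle_mst_weight <- function(edges, nodes) {
  if (!nrow(edges)) return(0)
  ## component discovery
  parent <- uf_new(length(nodes))
  idx <- function(v) match(v, nodes)
  for (e in seq_len(nrow(edges))) {
    a <- uf_find(parent, idx(edges$from[e]))
    b <- uf_find(parent, idx(edges$to[e]))
    if (a != b) parent[a] <- b
  }
  comp <- vapply(seq_along(nodes), function(i) uf_find(parent, i), integer(1))
  total <- 0
  for (cc in unique(comp)) {
    members <- which(comp == cc)
    if (length(members) < 2) next
    in_comp <- idx(edges$from) %in% members & idx(edges$to) %in% members
    esub <- edges[in_comp, , drop = FALSE]
    k <- length(members) - 1
    best <- Inf
    for (sel in combn(nrow(esub), k, simplify = FALSE)) {
      p <- uf_new(length(members))
      mi <- function(v) match(idx(v), members)
      ok <- TRUE
      for (e in sel) {
        a <- uf_find(p, mi(esub$from[e]))
        b <- uf_find(p, mi(esub$to[e]))
        if (a == b) {
          ok <- FALSE
          break
        }
        p[a] <- b
      }
      if (ok) best <- min(best, sum(esub$weight[sel]))
    }
    total <- total + best
  }
  total
}

## Kruskal's algorithm (second MST algorithm) -- total weight only.
oracle_kruskal_weight <- function(edges, nodes) {
  if (!nrow(edges)) return(0)
  ord <- order(edges$weight)
  parent <- uf_new(length(nodes))
  idx <- function(v) match(v, nodes)
  total <- 0
  for (e in ord) {
    a <- uf_find(parent, idx(edges$from[e]))
    b <- uf_find(parent, idx(edges$to[e]))
    if (a != b) {
      parent[a] <- b
      total <- total + edges$weight[e]
    }
  }
  total
}

## Naive O(n^3) agglomerative clustering; returns merge heights in order.
oracle_hclust_heights <- function(x, method = "complete") {
  n <- nrow(x)
  d <- as.matrix(dist(x))
  diag(d) <- Inf
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  link <- function(ci, cj) {
    dd <- d[ci, cj, drop = FALSE]
    if (method == "complete") max(dd) else min(dd)
  }
  while (length(clusters) > 1) {
    best <- c(Inf, 0, 0)
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        h <- link(clusters[[i]], clusters[[j]])
        if (h < best[1]) best <- c(h, i, j)
      }
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}

## AUC by exhaustive concordant-pair counting (ties count one half).
oracle_auc_pairs <- function(scores, labels, positive = "cancer") {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

## Classical MDS from first principles: eigendecomposition of the
## double-centered squared-distance matrix.
oracle_mds_points <- function(pts, dim = 2) {
  d2 <- as.matrix(dist(pts))^2
  n <- nrow(d2)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% d2 %*% J
  ee <- eigen(B, symmetric = TRUE)
  keep <- seq_len(dim)
  sweep(ee$vectors[, keep, drop = FALSE], 2,
        sqrt(pmax(ee$values[keep], 0)), "*")
}

## Row-wise application of the three-contrast selection rule, written as a
## plain loop over features.
oracle_statistical_select <- function(deg_a, deg_b, deg_c, lfc_a, p_max,
                                      combined_min) {
  sel <- character(0)
  for (i in seq_len(nrow(deg_a))) {
    id <- deg_a$feature_id[i]
    jb <- which(deg_b$feature_id == id)
    jc <- which(deg_c$feature_id == id)
    if (!length(jb) || !length(jc)) next
    if (abs(deg_a$log2fc[i]) > lfc_a && deg_a$pvalue[i] < p_max &&
        abs(deg_b$log2fc[jb] + deg_c$log2fc[jc]) > combined_min) {
      sel <- c(sel, id)
    }
  }
  sel
}
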