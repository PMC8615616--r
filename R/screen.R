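# The two-phase screen: statistical selection across three contrasts, then
# biological selection driven by treatment-response correlations.

#' Thresholds for the statistical screening phase
#'
#' @param lfc_a |log2FC| gate for the normal-vs-cancer contrast A (default 2).
#' @param lfc_bc |log2FC| threshold recorded for contrasts B and C
#'   individually (default 1.5; informational unless `gate = "all"`).
#' @param p_max Raw p-value gate for contrast A (default 0.05), the "DEG
#'   p-value" used throughout the rest of the screen.
#' @param combined_min Gate on |log2FC(B) + log2FC(C)| (default 4).
#' @param gate `"combined"` (default): a feature passes iff it passes the A
#'   gates and the combined B+C rule. `"all"` additionally enforces the
#'   per-contrast B and C gates (|log2FC| > `lfc_bc`, p < `p_max`).
#' @return A list of class `stat_screen_params`.
#' @export
stat_screen_params <- function(lfc_a = 2, lfc_bc = 1.5, p_max = 0.05,
                               combined_min = 4,
                               gate = c("combined", "all")) {
  gate <- match.arg(gate)
  if (any(c(lfc_a, lfc_bc, p_max, combined_min) <= 0))
    contract_error("all statistical screening thresholds must be positive")
  structure(list(lfc_a = lfc_a, lfc_bc = lfc_bc, p_max = p_max,
                 combined_min = combined_min, gate = gate),
            class = "stat_screen_params")
}

#' Statistical selection across the three contrasts
#'
#' A feature is selected when it passes contrast A (`|log2fc| > lfc_a` and
#' `p < p_max`) and the combined rule `|log2fc_B + log2fc_C| > combined_min`.
#' Features absent from the B or C table fail the combined rule. The
#' per-contrast B/C thresholds are recorded per feature but do not gate the
#' default selection.
#'
#' @param deg_a,deg_b,deg_c `DEGTable` data.frames from [exact_test()] or
#'   [rank_test()]; `deg_b`/`deg_c` features must be a subset of `deg_a`'s.
#' @param params A [stat_screen_params()].
#' @return List with `selected` (character ids) and `table` (per-feature rule
#'   provenance).
#' @export
statistical_select <- function(deg_a, deg_b, deg_c,
                               params = stat_screen_params()) {
  universe <- deg_a$feature_id
  extra <- setdiff(c(deg_b$feature_id, deg_c$feature_id), universe)
  if (length(extra))
    contract_error("features outside the contrast-A universe: %s",
                   paste(utils::head(extra, 5), collapse = ", "))
  ib <- match(universe, deg_b$feature_id)
  ic <- match(universe, deg_c$feature_id)
  lfc_b <- deg_b$log2fc[ib]
  lfc_c <- deg_c$log2fc[ic]
  p_b <- deg_b$pvalue[ib]
  p_c <- deg_c$pvalue[ic]
  pass_a <- abs(deg_a$log2fc) > params$lfc_a & deg_a$pvalue < params$p_max
  comb <- abs(lfc_b + lfc_c)
  pass_comb <- !is.na(comb) & comb > params$combined_min
  pass_b <- !is.na(lfc_b) & abs(lfc_b) > params$lfc_bc & p_b < params$p_max
  pass_c <- !is.na(lfc_c) & abs(lfc_c) > params$lfc_bc & p_c < params$p_max
  selected <- if (params$gate == "combined") {
    pass_a & pass_comb
  } else {
    pass_a & pass_comb & pass_b & pass_c
  }
  tab <- data.frame(feature_id = universe, log2fc_a = deg_a$log2fc,
                    pvalue_a = deg_a$pvalue, log2fc_b = lfc_b,
                    log2fc_c = lfc_c, combined_bc = comb,
                    pass_a = pass_a, pass_b = pass_b, pass_c = pass_c,
                    pass_combined = pass_comb, selected = selected,
                    row.names = NULL, stringsAsFactors = FALSE)
  list(selected = universe[selected], table = tab)
}

#' Per-patient paired treatment-response log2 fold changes
#'
#' For every cancer patient with both a pre- and a post-treatment sample,
#' computes `log2((post + pc) / (pre + pc))` on normalized expression.
#' Patients missing a timepoint are dropped with a warning.
#'
#' @param norm_expr Normalized (non-logged) expression matrix whose columns
#'   include the patients' pre and post samples.
#' @param samples A validated sample table.
#' @param pseudocount Pseudocount `pc` in normalized units.
#' @return Response matrix (features x patients), column names = patient ids.
#' @export
paired_response <- function(norm_expr, samples, pseudocount = 1) {
  samples <- validate_samples(samples)
  cc <- samples[samples$group == "cancer", ]
  pre <- cc[cc$timepoint == "pre", ]
  post <- cc[cc$timepoint == "post", ]
  pre <- pre[pre$sample_id %in% colnames(norm_expr), ]
  post <- post[post$sample_id %in% colnames(norm_expr), ]
  patients <- intersect(pre$patient_id, post$patient_id)
  dropped <- setdiff(unique(cc$patient_id), patients)
  if (length(dropped))
    warnf("dropping %d patient(s) without a complete pre/post pair: %s",
          length(dropped), paste(dropped, collapse = ", "))
  if (!length(patients))
    contract_error("no patient has a complete pre/post sample pair")
  pre_cols <- pre$sample_id[match(patients, pre$patient_id)]
  post_cols <- post$sample_id[match(patients, post$patient_id)]
  out <- base::log2((norm_expr[, post_cols, drop = FALSE] + pseudocount) /
                    (norm_expr[, pre_cols, drop = FALSE] + pseudocount))
  colnames(out) <- patients
  out
}

#' Count strongly correlated partners per candidate
#'
#' Pearson-correlates every candidate's response profile against every
#' partner's across patients, and counts partners with `|r| >= r_min` (only
#' positive correlations when `signed = TRUE`). Zero-variance rows yield undefined
#' correlations, which are treated as not related (with a warning).
#'
#' @param candidates,partners Response matrices (features x patients) sharing
#'   patient columns, e.g. rows of [paired_response()] output.
#' @param r_min Correlation magnitude threshold.
#' @param signed Count only positive correlations?
#' @return Data.frame (one row per candidate) with `n_related` and `best_r`
#'   (the signed r of largest magnitude); attribute `partners` holds, per
#'   candidate, partner ids and r sorted by decreasing |r|.
#' @export
related_counts <- function(candidates, partners, r_min, signed = FALSE) {
  if (!identical(colnames(candidates), colnames(partners)))
    contract_error("candidate and partner matrices must share patient columns")
  cvar <- apply(candidates, 1, stats::var)
  pvar <- apply(partners, 1, stats::var)
  n_zv <- sum(cvar == 0) + sum(pvar == 0)
  if (n_zv > 0)
    warnf("%d zero-variance response row(s); their correlations are treated as not related",
          n_zv)
  r <- suppressWarnings(stats::cor(t(candidates), t(partners)))
  r[!is.finite(r)] <- 0
  detail <- lapply(seq_len(nrow(candidates)), function(i) {
    ri <- r[i, ]
    ord <- order(abs(ri), decreasing = TRUE)
    data.frame(partner_id = colnames(r)[ord], r = ri[ord],
               related = if (signed) ri[ord] >= r_min else abs(ri[ord]) >= r_min,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  names(detail) <- rownames(candidates)
  out <- data.frame(
    feature_id = rownames(candidates),
    n_related = vapply(detail, function(d) sum(d$related), integer(1)),
    best_r = vapply(detail, function(d) if (nrow(d)) d$r[1] else 0, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "partners") <- detail
  attr(out, "r_min") <- r_min
  out
}

#' Optimize the related-partner cutoff
#'
#' Scans every threshold `t` among the distinct related-partner counts,
#' splitting candidates into `{n_related > t}` versus `{n_related <= t}` (both
#' sides at least `min_side` members), and returns the `t` that maximizes the
#' separation of `-log10(DEG p-value)` between the two groups. Separation is
#' the |z| of a two-sided Wilcoxon rank-sum statistic by default, or the
#' absolute difference of group means.
#'
#' @param n_related Named integer vector, related-partner count per candidate
#'   (names = candidate ids), e.g. from [related_counts()].
#' @param deg_pvalues Named numeric vector of DEG p-values (contrast A) for
#'   the same candidates.
#' @param min_side Minimum group size on each side of the cutoff.
#' @param statistic `"wilcoxon_z"` or `"mean_diff"`.
#' @return List with `cutoff`, `separation`, `high` and `low` id vectors, and
#'   a `table` of every admissible threshold (ties broken toward the smallest
#'   cutoff).
#' @export
optimize_cutoff <- function(n_related, deg_pvalues, min_side = 2,
                            statistic = c("wilcoxon_z", "mean_diff")) {
  statistic <- match.arg(statistic)
  ids <- names(n_related)
  if (is.null(ids) || !all(ids %in% names(deg_pvalues)))
    contract_error("n_related and deg_pvalues must be named over the same candidates")
  nl10 <- -log10(pmax(deg_pvalues[ids], 1e-300))
  cuts <- sort(unique(n_related))
  rows <- lapply(cuts, function(t) {
    hi <- n_related > t
    if (sum(hi) < min_side || sum(!hi) < min_side) return(NULL)
    sep <- if (statistic == "wilcoxon_z") {
      abs(wilcox_z(nl10[hi], nl10[!hi])$z)
    } else {
      abs(mean(nl10[hi]) - mean(nl10[!hi]))
    }
    data.frame(cutoff = t, separation = sep, n_high = sum(hi),
               n_low = sum(!hi))
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab) || !nrow(tab))
    contract_error("no admissible cutoff partitions the candidates (need >= %d per side)",
                   min_side)
  best <- tab$cutoff[which.max(tab$separation)] # which.max -> smallest on ties
  list(cutoff = best,
       separation = max(tab$separation),
       high = ids[n_related > best],
       low = ids[n_related <= best],
       statistic = statistic,
       table = tab)
}

#' Biological selection of a class's candidates
#'
#' Small classes (at most `small_max` initially selected features) are
#' forwarded whole for network and category review; larger classes keep only
#' the candidates above the optimized cutoff whose strongest partner
#' correlation reaches `r_strong`.
#'
#' @param initial Character ids from the statistical screen.
#' @param related [related_counts()] output for those candidates.
#' @param cutoff_result [optimize_cutoff()] output (required on the large
#'   branch).
#' @param r_strong Strong-correlate magnitude threshold (default 0.9).
#' @param small_max Largest class size taking the small branch (default 20;
#'   exactly 20 is assigned to the small branch).
#' @param class_role Optional label recorded in the result.
#' @return List with `branch` (`"small"`/`"large"`), `final` ids and `notes`.
#' @export
biological_select <- function(initial, related, cutoff_result = NULL,
                              r_strong = 0.9, small_max = 20,
                              class_role = NULL) {
  if (length(initial) <= small_max) {
    return(list(branch = "small", final = initial, class_role = class_role,
                notes = sprintf(
                  "%d candidates (<= %d): all forwarded for network/category review",
                  length(initial), small_max)))
  }
  if (is.null(cutoff_result))
    contract_error("large branch (%d candidates) requires a cutoff result",
                   length(initial))
  idx <- match(cutoff_result$high, related$feature_id)
  strong <- cutoff_result$high[abs(related$best_r[idx]) >= r_strong]
  notes <- sprintf(
    "large branch: cutoff %s kept %d high candidates, %d with |best r| >= %.2f",
    format(cutoff_result$cutoff), length(cutoff_result$high), length(strong),
    r_strong)
  if (!length(strong))
    notes <- paste(notes, "- no high candidate reaches the strong-correlate threshold")
  list(branch = "large", final = strong, cutoff = cutoff_result$cutoff,
       separation = cutoff_result$separation, class_role = class_role,
       notes = notes)
}
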