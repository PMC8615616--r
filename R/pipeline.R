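# End-to-end orchestration: simulate/load -> filter -> TMM -> three-contrast
# DE -> statistical selection -> paired responses -> correlation screening ->
# networks -> subgroup flagging -> integration (MDS, k-means diagnosis,
# panel search, ROC).

#' Pipeline parameters
#'
#' Collects every tunable of the two-phase screen. Correlation thresholds
#' default to the study conventions: relatedness at |r| >= 0.8 for miRNA and
#' 0.7 elsewhere, strong correlates at |r| >= 0.9, and the small-class branch
#' at 20 initially selected features. The detection filters default to the
#' study proportions (over 12 of 42 statistical-phase samples, over 30 of 60
#' biological-phase samples), rescaled to the actual cohort sizes.
#'
#' @param stat_params A [stat_screen_params()].
#' @param r_min Named per-class relatedness thresholds; the `default` entry
#'   covers unlisted classes.
#' @param r_strong Strong-correlate threshold for the large branch.
#' @param small_max Largest initial selection taking the small branch.
#' @param engine DE engine, `"exact"` (NB exact test) or `"rank"` (Wilcoxon).
#' @param max_undetected_stat,max_undetected_bio Detection-filter caps;
#'   `NULL` = study proportions of the cohort's sample counts.
#' @param pseudocount Pseudocount used in fold changes, responses and log
#'   transforms (normalized units).
#' @param signed_correlations Count only positively correlated partners.
#' @param k_diagnosis Clusters for the MDS diagnosis (2 or 3).
#' @param panel_max_size Largest marker panel searched.
#' @param seed Seed for the clustering restarts (analysis-side randomness
#'   only; the cohort has its own seed).
#' @return A list of class `pipeline_params`.
#' @export
pipeline_params <- function(stat_params = stat_screen_params(),
                            r_min = c(miRNA = 0.8, default = 0.7),
                            r_strong = 0.9,
                            small_max = 20,
                            engine = c("exact", "rank"),
                            max_undetected_stat = NULL,
                            max_undetected_bio = NULL,
                            pseudocount = 1,
                            signed_correlations = FALSE,
                            k_diagnosis = 2,
                            panel_max_size = 3,
                            seed = 0) {
  engine <- match.arg(engine)
  structure(list(stat_params = stat_params, r_min = r_min,
                 r_strong = r_strong, small_max = small_max, engine = engine,
                 max_undetected_stat = max_undetected_stat,
                 max_undetected_bio = max_undetected_bio,
                 pseudocount = pseudocount,
                 signed_correlations = signed_correlations,
                 k_diagnosis = k_diagnosis, panel_max_size = panel_max_size,
                 seed = seed),
            class = "pipeline_params")
}

r_min_for <- function(params, class) {
  r <- params$r_min
  if (!is.null(names(r)) && class %in% names(r)) return(unname(r[[class]]))
  if (!is.null(names(r)) && "default" %in% names(r)) return(unname(r[["default"]]))
  unname(r[[1]])
}

## Partner classes per candidate class: ncRNA candidates are screened against
## mRNA responses; mRNA candidates against miRNA + piRNA + lncRNA responses.
partner_classes_for <- function(class, available) {
  if (class == "mRNA") intersect(c("miRNA", "piRNA", "lncRNA"), available)
  else intersect("mRNA", available)
}

#' Run the full two-phase screen
#'
#' @param cohort A cohort list (`expression`, `samples`, optionally `truth`),
#'   e.g. from [generate_cohort()] or [read_cohort()]. When `NULL`, a
#'   synthetic cohort is generated from `sim_config`.
#' @param params A [pipeline_params()].
#' @param sim_config A [sim_config()] used when `cohort` is `NULL`.
#' @param categories Optional [read_categories()] map for network category
#'   percentages.
#' @param out_dir Optional directory: per-class DEG tables, screen report
#'   JSON and network edge lists are written there.
#' @return A `ScreenReport` list: per-class statistical and biological
#'   screening provenance (initial ids, branch, cutoff, separation, final
#'   ids), the flagged snoRNA subgroup, and the integration results (cluster
#'   diagnosis, best panel, ROC).
#' @export
run_pipeline <- function(cohort = NULL, params = pipeline_params(),
                         sim_config = exoscreen::sim_config(),
                         categories = NULL, out_dir = NULL) {
  if (is.null(cohort)) cohort <- generate_cohort(sim_config)
  samples <- validate_samples(cohort$samples)
  classes <- names(cohort$expression)

  stat_ids <- samples_of(samples, timepoint = "pre") # normal + cancer pre
  bio_ids <- samples_of(samples, group = "cancer")   # pre + post
  n_stat <- length(stat_ids)
  n_bio <- length(bio_ids)
  max_ud_stat <- params$max_undetected_stat
  if (is.null(max_ud_stat)) max_ud_stat <- round(n_stat * 12 / 42)
  max_ud_bio <- params$max_undetected_bio
  if (is.null(max_ud_bio)) max_ud_bio <- round(n_bio * 30 / 60)
  contrasts <- screening_contrasts(samples)

  class_results <- list()
  responses <- list()
  stat_norm_log <- list()
  for (k in classes) {
    es <- cohort$expression[[k]]

    ## ---- statistical phase: 42-sample universe -------------------------
    es_stat <- subset_expression(es, samples = stat_ids)
    es_stat <- filter_undetected(es_stat, max_ud_stat)
    if (nrow(es_stat$counts) < 2) {
      class_results[[k]] <- list(rna_class = k, n_filtered = nrow(es_stat$counts),
                                 initial = character(0), branch = "empty",
                                 final = character(0),
                                 notes = "fewer than two detected features")
      next
    }
    fac_stat <- tmm_factors(es_stat)
    degs <- lapply(contrasts, function(ct) {
      if (params$engine == "exact") {
        phi <- estimate_common_dispersion(es_stat, ct, factors = fac_stat)
        deg <- exact_test(es_stat, ct, dispersion = phi, factors = fac_stat,
                          pseudocount = params$pseudocount)
        attr(deg, "dispersion") <- phi
        deg
      } else {
        rank_test(normalized_expression(es_stat, fac_stat, unit = "RPM",
                                        log2 = TRUE,
                                        pseudocount = params$pseudocount),
                  ct)
      }
    })
    sel <- statistical_select(degs$A, degs$B, degs$C, params$stat_params)
    stat_norm_log[[k]] <- normalized_expression(
      es_stat, fac_stat, log2 = TRUE, pseudocount = params$pseudocount)

    ## ---- biological phase: paired responses over the 60 cancer samples --
    es_bio <- subset_expression(es, samples = bio_ids)
    es_bio <- filter_undetected(es_bio, max_ud_bio)
    resp <- NULL
    if (nrow(es_bio$counts) >= 2) {
      fac_bio <- tmm_factors(es_bio)
      norm_bio <- normalized_expression(es_bio, fac_bio, unit = "RPM")
      resp <- paired_response(norm_bio, samples,
                              pseudocount = params$pseudocount)
    }
    responses[[k]] <- resp

    class_results[[k]] <- list(rna_class = k,
                               n_filtered = nrow(es_stat$counts),
                               initial = sel$selected,
                               stat_table = sel$table,
                               deg_a = degs$A)
    if (!is.null(out_dir)) {
      ok <- dir.exists(out_dir) ||
        dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      for (lab in names(degs))
        write_tsv(degs[[lab]], file.path(out_dir,
                                         sprintf("deg_%s_%s.tsv", k, lab)))
    }
  }

  ## ---- correlation screening per class --------------------------------
  for (k in classes) {
    res <- class_results[[k]]
    if (is.null(res$initial)) next
    initial <- res$initial
    resp <- responses[[k]]
    pclasses <- partner_classes_for(k, classes)
    partner_resp <- do.call(rbind, responses[pclasses])
    cand_rows <- intersect(initial, rownames(resp))
    res$branch <- NA_character_
    res$final <- character(0)
    res$cutoff <- NULL
    if (!length(initial)) {
      res$branch <- "none"
      res$notes <- "statistical screen selected nothing"
    } else if (is.null(resp) || !length(cand_rows) ||
               is.null(partner_resp) || !nrow(partner_resp)) {
      res$branch <- "small"
      res$final <- initial
      res$notes <- "no response data for correlation screening; initial set forwarded"
    } else {
      rmin <- r_min_for(params, k)
      rel <- related_counts(resp[cand_rows, , drop = FALSE], partner_resp,
                            r_min = rmin,
                            signed = params$signed_correlations)
      res$related <- rel
      if (length(initial) <= params$small_max) {
        bio <- biological_select(initial, rel, NULL,
                                 r_strong = params$r_strong,
                                 small_max = params$small_max, class_role = k)
      } else {
        pa <- stats::setNames(res$deg_a$pvalue, res$deg_a$feature_id)
        cut <- tryCatch(
          optimize_cutoff(stats::setNames(rel$n_related, rel$feature_id),
                          pa[rel$feature_id]),
          exoscreen_contract_error = function(e) NULL)
        bio <- if (is.null(cut)) {
          list(branch = "large", final = character(0),
               notes = "no admissible cutoff partition; nothing selected")
        } else {
          biological_select(initial, rel, cut, r_strong = params$r_strong,
                            small_max = params$small_max, class_role = k)
        }
        res$cutoff <- bio$cutoff
        res$separation <- bio$separation
      }
      res$branch <- bio$branch
      res$final <- bio$final
      res$notes <- bio$notes
      ## network over the final (or, on an empty final, the initial) set
      net_ids <- if (length(bio$final)) bio$final else cand_rows
      net_ids <- intersect(net_ids, rownames(resp))
      if (length(net_ids)) {
        rel_partner_ids <- unique(unlist(lapply(
          attr(rel, "partners")[net_ids],
          function(d) d$partner_id[d$related])))
        graph <- build_graph(resp[net_ids, , drop = FALSE],
                             partner_resp[intersect(rel_partner_ids,
                                                    rownames(partner_resp)), ,
                                          drop = FALSE],
                             r_min = rmin)
        graph <- prim_mst(graph)
        res$network <- list(n_nodes = nrow(graph$nodes),
                            n_edges = nrow(graph$edges),
                            mst_weight = graph$total_weight)
        if (!is.null(categories)) {
          res$categories <- tryCatch(
            category_percentage(graph, categories),
            exoscreen_contract_error = function(e) NULL)
        }
        if (!is.null(out_dir))
          export_edges(graph, file.path(out_dir,
                                        sprintf("network_%s.tsv", k)))
      }
    }
    class_results[[k]] <- res
  }

  ## ---- snoRNA subgroup flagging ---------------------------------------
  subgroup <- list(patients = character(0), features = character(0),
                   flagged = FALSE)
  if ("snoRNA" %in% classes && length(class_results$snoRNA$initial) >= 4) {
    cancer_pre <- samples_of(samples, "cancer", "pre")
    sn_log <- stat_norm_log$snoRNA[
      intersect(class_results$snoRNA$initial,
                rownames(stat_norm_log$snoRNA)),
      cancer_pre, drop = FALSE]
    subgroup <- find_snorna_subgroup(sn_log, samples, seed = params$seed)
  }

  ## ---- integration ----------------------------------------------------
  integration <- integrate_selection(cohort, class_results, subgroup,
                                     samples, stat_ids, params)

  report <- list(
    parameters = list(engine = params$engine,
                      stat_params = unclass(params$stat_params),
                      r_min = as.list(params$r_min),
                      r_strong = params$r_strong,
                      small_max = params$small_max,
                      max_undetected_stat = max_ud_stat,
                      max_undetected_bio = max_ud_bio,
                      pseudocount = params$pseudocount,
                      k_diagnosis = params$k_diagnosis,
                      seed = params$seed,
                      cohort_seed = cohort$config$seed,
                      version = as.character(utils::packageVersion("exoscreen"))),
    classes = lapply(class_results, function(res) {
      list(rna_class = res$rna_class, n_filtered = res$n_filtered,
           n_initial = length(res$initial), initial = res$initial,
           branch = res$branch, cutoff = res$cutoff,
           separation = res$separation, final = res$final,
           network = res$network, categories = res$categories,
           notes = res$notes)
    }),
    subgroup = subgroup,
    integration = integration)
  if (!is.null(out_dir)) {
    ok <- dir.exists(out_dir) ||
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report(report, file.path(out_dir, "screen_report.json"))
  }
  report
}

## The subgroup step mirrors the heatmap reading of the statistical phase:
## the cancer samples are split into two clusters on row-centered profiles of
## the selected snoRNAs (centering removes the overall normal-vs-cancer
## level so the split follows within-cancer structure), the snoRNA block is
## the features at least `min_feature_sep` log2 units apart between the two
## sample clusters, and flag_subgroup then verifies that this block is
## homogeneously overexpressed in one cluster.
find_snorna_subgroup <- function(sn_log, samples, min_feature_sep = 2,
                                 seed = 0) {
  out <- list(patients = character(0), features = character(0),
              flagged = FALSE)
  if (nrow(sn_log) < 4 || ncol(sn_log) < 4) return(out)
  centered <- sn_log - rowMeans(sn_log)
  km <- with_local_seed(seed,
    stats::kmeans(t(centered), centers = 2, nstart = 20, iter.max = 100))
  d <- rowMeans(sn_log[, km$cluster == 1, drop = FALSE]) -
    rowMeans(sn_log[, km$cluster == 2, drop = FALSE])
  feats <- rownames(sn_log)[abs(d) >= min_feature_sep]
  if (length(feats) < 2) return(out)
  fl <- flag_subgroup(sn_log[feats, , drop = FALSE], seed = seed)
  if (fl$flagged && length(fl$samples) < ncol(sn_log)) {
    out <- list(
      patients = samples$patient_id[match(fl$samples, samples$sample_id)],
      features = feats, flagged = TRUE,
      fraction_high = fl$fraction_high, separation = fl$separation)
  }
  out
}

## Integration over the finally selected features of all classes (plus the
## flagged subgroup snoRNAs): log2 CPM on raw library sizes, MDS + k-means
## diagnosis over the statistical-phase samples, panel search, ROC of the
## top panel.
integrate_selection <- function(cohort, class_results, subgroup, samples,
                                stat_ids, params) {
  sel <- lapply(class_results, function(res) res$final)
  pool <- unique(c(unlist(sel, use.names = FALSE), subgroup$features))
  if (length(pool) < 1)
    return(list(n_features = 0,
                notes = "no feature survived the biological screen"))
  mats <- lapply(names(cohort$expression), function(k) {
    es <- cohort$expression[[k]]
    ids <- intersect(pool, rownames(es$counts))
    if (!length(ids)) return(NULL)
    ## raw-count CPM integrates the classes on a common scale
    m <- normalized_expression(subset_expression(es, samples = stat_ids),
                               factors = NULL, unit = "RPM", log2 = TRUE,
                               pseudocount = params$pseudocount)
    m[ids, , drop = FALSE]
  })
  expr <- do.call(rbind, mats)
  labels <- samples$group[match(stat_ids, samples$sample_id)]

  diag <- NULL
  if (nrow(expr) >= 2) {
    emb <- classical_mds(expr, dim = 2)
    ## a flagged patient subgroup adds a third sample cluster (normal /
    ## subgroup cancers / other cancers), so diagnose with k = 3 and merge
    ## the cancer-majority clusters
    k_use <- if (any(subgroup$features %in% rownames(expr)))
      max(params$k_diagnosis, 3) else params$k_diagnosis
    diag <- kmeans_diagnose(emb, k = k_use, labels, seed = params$seed)
  }
  panels <- panel_search(expr, labels, max_size = params$panel_max_size,
                         seed = params$seed)
  top <- panels[1, ]
  top_ids <- strsplit(top$panel, "+", fixed = TRUE)[[1]]
  ps <- panel_score(expr[top_ids, , drop = FALSE], labels)
  roc <- roc_auc(ps$scores, labels)
  list(n_features = nrow(expr), features = rownames(expr),
       diagnosis = if (!is.null(diag))
         list(sensitivity = diag$sensitivity,
              specificity = diag$specificity,
              tp = diag$tp, fn = diag$fn, tn = diag$tn, fp = diag$fp),
       best_panel = list(features = top_ids,
                         sensitivity = top$sensitivity,
                         specificity = top$specificity,
                         auc = roc$auc,
                         youden_sensitivity = roc$youden_sensitivity,
                         youden_specificity = roc$youden_specificity),
       panels_evaluated = nrow(panels))
}
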