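# Synthetic cohort generator. Emulates the statistical structure the two-phase
# screen assumes: a normal group, a cancer group sampled before and two weeks
# into chemoradiotherapy, negative-binomial counts over eight RNA classes,
# planted normal-vs-cancer markers, a planted patient subgroup with
# co-overexpressed snoRNAs, and planted correlations between candidate RNAs'
# and partner RNAs' per-patient treatment-response log2 fold changes.

#' Configuration for the synthetic cohort generator
#'
#' Defaults encode the study conditions the generator emulates: 12 normal
#' samples, 30 cancer patients (6 adenocarcinoma) sampled pre- and
#' post-treatment, eight RNA classes with class-specific feature counts,
#' markers shifted by 3 log2 units in all cancer samples, and candidate RNAs
#' whose treatment responses correlate with planted partner RNAs at Pearson
#' rho = 0.9.
#'
#' @param n_normal,n_cancer,n_ac Cohort sizes: healthy controls, cancer
#'   patients, and the adenocarcinoma subset of the patients.
#' @param class_sizes Named integer vector, features per RNA class.
#' @param n_markers_per_class Planted normal-vs-cancer markers per class
#'   (alternating up/down in cancer).
#' @param marker_log2fc Planted marker effect on the log2 scale; the default 3
#'   exceeds the |log2FC| > 2 selection gate.
#' @param marker_relax Fraction by which marker effects relax toward normal in
#'   post-treatment samples (0.5 leaves half of the effect).
#' @param nb_dispersion Negative-binomial dispersion phi (variance
#'   mu + phi * mu^2), shared within a class.
#' @param lib_size_range Two integers; per-sample library sizes are uniform in
#'   this range.
#' @param response_corr Target Pearson correlation between a planted
#'   candidate's paired response log2FC and each of its partners', in [0, 1].
#' @param candidate_classes Classes that receive planted response candidates.
#' @param n_candidates_per_class Planted candidates per candidate class (taken
#'   from that class's up-markers).
#' @param n_partner_mrnas mRNA partners planted per ncRNA candidate.
#' @param n_partner_ncrnas ncRNA partners (split over miRNA, piRNA, lncRNA)
#'   planted per mRNA candidate.
#' @param n_snorna_subgroup Number of cancer patients in the planted snoRNA
#'   subgroup (0 disables it).
#' @param n_subgroup_features snoRNA features overexpressed in that subgroup.
#' @param subgroup_log2fc log2 overexpression of the subgroup features in the
#'   subgroup patients' samples.
#' @param ac_log2fc Optional extra log2 shift of marker features in
#'   adenocarcinoma samples (0 by default: pathology carries no planted
#'   expression effect).
#' @param seed Integer seed; the cohort is a pure function of the config.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_normal = 12L, n_cancer = 30L, n_ac = 6L,
                       class_sizes = c(miRNA = 800L, piRNA = 2000L,
                                       lncRNA = 3000L, snoRNA = 400L,
                                       snRNA = 900L, tRNA = 1500L,
                                       yRNA = 300L, mRNA = 8000L),
                       n_markers_per_class = 30L,
                       marker_log2fc = 3,
                       marker_relax = 0.5,
                       nb_dispersion = 0.1,
                       lib_size_range = c(100000L, 200000L),
                       response_corr = 0.9,
                       candidate_classes = c("miRNA", "lncRNA", "snoRNA",
                                             "mRNA"),
                       n_candidates_per_class = 2L,
                       n_partner_mrnas = 150L,
                       n_partner_ncrnas = 30L,
                       n_snorna_subgroup = 12L,
                       n_subgroup_features = 7L,
                       subgroup_log2fc = 4,
                       ac_log2fc = 0,
                       seed = 1L) {
  cfg <- list(n_normal = as.integer(n_normal), n_cancer = as.integer(n_cancer),
              n_ac = as.integer(n_ac), class_sizes = class_sizes,
              n_markers_per_class = as.integer(n_markers_per_class),
              marker_log2fc = marker_log2fc, marker_relax = marker_relax,
              nb_dispersion = nb_dispersion,
              lib_size_range = as.integer(lib_size_range),
              response_corr = response_corr,
              candidate_classes = candidate_classes,
              n_candidates_per_class = as.integer(n_candidates_per_class),
              n_partner_mrnas = as.integer(n_partner_mrnas),
              n_partner_ncrnas = as.integer(n_partner_ncrnas),
              n_snorna_subgroup = as.integer(n_snorna_subgroup),
              n_subgroup_features = as.integer(n_subgroup_features),
              subgroup_log2fc = subgroup_log2fc, ac_log2fc = ac_log2fc,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (is.null(names(cfg$class_sizes)) ||
      !all(names(cfg$class_sizes) %in% RNA_CLASSES))
    contract_error("class_sizes must be named with known RNA classes")
  if (any(cfg$class_sizes <= 0))
    contract_error("all class sizes must be positive")
  if (cfg$n_ac > cfg$n_cancer)
    contract_error("n_ac must not exceed n_cancer")
  if (cfg$n_normal < 2 || cfg$n_cancer < 2)
    contract_error("need at least two normal and two cancer samples")
  if (cfg$response_corr < 0 || cfg$response_corr > 1)
    contract_error("response_corr must lie in [0, 1]")
  if (!is.finite(cfg$marker_log2fc))
    contract_error("marker_log2fc must be finite")
  if (cfg$nb_dispersion < 0)
    contract_error("nb_dispersion must be non-negative")
  if (length(cfg$lib_size_range) != 2 || any(cfg$lib_size_range <= 0) ||
      diff(cfg$lib_size_range) < 0)
    contract_error("lib_size_range must be an increasing positive pair")
  missing_cand <- setdiff(cfg$candidate_classes, names(cfg$class_sizes))
  if (length(missing_cand))
    contract_error("class_sizes missing candidate class(es): %s",
                   paste(missing_cand, collapse = ", "))
  if (cfg$n_snorna_subgroup > 0) {
    if (!"snoRNA" %in% names(cfg$class_sizes))
      contract_error("class_sizes missing snoRNA, required for the planted subgroup")
    if (cfg$n_snorna_subgroup > cfg$n_cancer)
      contract_error("n_snorna_subgroup must not exceed n_cancer")
  }
  plan_plant(cfg) # errors if class sizes cannot host the planted structure
  invisible(cfg)
}

## Deterministic placement of the planted structure. Markers occupy the first
## n_markers features of every class (odd indices up, even down); candidates
## are the first up-markers of the candidate classes; partner features are
## carved from the top end of the partner classes; the subgroup snoRNAs sit
## right after the snoRNA markers.
plan_plant <- function(cfg) {
  classes <- names(cfg$class_sizes)
  plan <- list()
  for (k in classes) {
    G <- cfg$class_sizes[[k]]
    nm <- min(cfg$n_markers_per_class, G)
    idx <- seq_len(nm)
    plan[[k]] <- list(marker_idx = idx,
                      marker_dir = ifelse(idx %% 2 == 1, "up", "down"),
                      candidate_idx = integer(0),
                      partner_idx = integer(0),
                      subgroup_idx = integer(0))
  }
  reserved_top <- stats::setNames(rep(0L, length(classes)), classes)
  take_top <- function(class, n) {
    G <- cfg$class_sizes[[class]]
    lo <- G - reserved_top[[class]] - n + 1L
    if (lo <= max(plan[[class]]$marker_idx, plan[[class]]$subgroup_idx, 0L))
      contract_error("class %s too small for planted partner features", class)
    reserved_top[[class]] <<- reserved_top[[class]] + n
    seq(lo, lo + n - 1L)
  }
  if ("snoRNA" %in% classes && cfg$n_snorna_subgroup > 0 &&
      cfg$n_subgroup_features > 0) {
    nm <- length(plan$snoRNA$marker_idx)
    hi <- nm + cfg$n_subgroup_features
    if (hi > cfg$class_sizes[["snoRNA"]])
      contract_error("snoRNA class too small for the planted subgroup features")
    plan$snoRNA$subgroup_idx <- seq(nm + 1L, hi)
  }
  cand_classes <- intersect(cfg$candidate_classes, classes)
  partners <- list()
  cand_no <- 0L
  for (k in cand_classes) {
    up <- plan[[k]]$marker_idx[plan[[k]]$marker_dir == "up"]
    if (length(up) < cfg$n_candidates_per_class)
      contract_error("class %s has too few up-markers for its candidates", k)
    cand <- up[seq_len(cfg$n_candidates_per_class)]
    plan[[k]]$candidate_idx <- cand
    for (ci in seq_along(cand)) {
      cand_no <- cand_no + 1L
      if (k == "mRNA") {
        pclasses <- intersect(c("miRNA", "piRNA", "lncRNA"), classes)
        if (!length(pclasses))
          contract_error("no ncRNA partner classes available for mRNA candidates")
        per <- ceiling(cfg$n_partner_ncrnas / length(pclasses))
        pset <- lapply(pclasses, function(pc) {
          data.frame(class = pc, idx = take_top(pc, per),
                     stringsAsFactors = FALSE)
        })
        pset <- do.call(rbind, pset)[seq_len(cfg$n_partner_ncrnas), ]
      } else {
        if (!"mRNA" %in% classes)
          contract_error("class_sizes missing mRNA, required for candidate partners")
        pset <- data.frame(class = "mRNA",
                           idx = take_top("mRNA", cfg$n_partner_mrnas),
                           stringsAsFactors = FALSE)
      }
      partners[[cand_no]] <- list(class = k, idx = cand[ci], partners = pset,
                                  latent = cand_no)
    }
  }
  list(classes = plan, candidates = partners)
}

feature_ids <- function(class, G) sprintf("%s_%05d", class, seq_len(G))

#' Generate a synthetic cohort
#'
#' Draws negative-binomial count matrices for every configured RNA class over
#' `n_normal + 2 * n_cancer` samples (normal, cancer pre-treatment, cancer
#' post-treatment; pre/post share patient ids). Marker features are shifted by
#' `marker_log2fc` in all cancer samples and relax toward normal after
#' treatment; subgroup snoRNAs are overexpressed only in the designated
#' patients; each planted candidate and its partner features share a latent
#' per-patient treatment response whose weight is chosen analytically
#' (accounting for the expected count-level noise) so realized response
#' correlations land near `response_corr`.
#'
#' @param config A [sim_config()].
#' @return List with elements `expression` (named list of [expression_set()]
#'   per class), `samples` (validated sample table) and `truth` (planted
#'   ground-truth record).
#' @export
generate_cohort <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  validate_sim_config(config)
  plan <- plan_plant(config)
  set.seed(config$seed)

  nN <- config$n_normal; nC <- config$n_cancer; nAC <- config$n_ac
  patients <- sprintf("P%02d", seq_len(nC))
  pathology <- ifelse(seq_len(nC) <= nAC, "AC", "nonAC")
  normals <- sprintf("N%02d", seq_len(nN))
  samples <- rbind(
    data.frame(sample_id = normals, patient_id = normals, group = "normal",
               timepoint = "pre", pathology = "none",
               stringsAsFactors = FALSE),
    data.frame(sample_id = paste0(patients, "_pre"), patient_id = patients,
               group = "cancer", timepoint = "pre", pathology = pathology,
               stringsAsFactors = FALSE),
    data.frame(sample_id = paste0(patients, "_post"), patient_id = patients,
               group = "cancer", timepoint = "post", pathology = pathology,
               stringsAsFactors = FALSE))
  samples <- validate_samples(samples)

  ## Subgroup patients: proportional overlap with the AC subset so the
  ## subgroup features remain detectable in every screening contrast.
  sub_patients <- character(0)
  if (config$n_snorna_subgroup > 0) {
    k_ac <- min(nAC, round(nAC * config$n_snorna_subgroup / nC))
    idx <- c(if (k_ac > 0) seq(nAC - k_ac + 1L, nAC),
             seq(nAC + 1L, length.out = config$n_snorna_subgroup - k_ac))
    sub_patients <- patients[idx]
  }

  n_lat <- length(plan$candidates)
  latent <- if (n_lat > 0)
    matrix(stats::rnorm(n_lat * nC), n_lat, nC,
           dimnames = list(NULL, patients)) else NULL

  nS <- nN + 2L * nC
  col_pre <- nN + seq_len(nC)          # cancer pre columns, patient order
  col_post <- nN + nC + seq_len(nC)    # cancer post columns, patient order
  mean_lib <- mean(config$lib_size_range)
  phi <- config$nb_dispersion
  rho <- min(config$response_corr, 0.99)

  expression <- list()
  truth_markers <- list()
  truth_partners <- list()
  classes <- names(config$class_sizes)
  all_ids <- lapply(classes, function(k)
    feature_ids(k, config$class_sizes[[k]]))
  names(all_ids) <- classes

  for (k in classes) {
    G <- config$class_sizes[[k]]
    ids <- all_ids[[k]]
    pk <- plan$classes[[k]]
    b <- stats::rnorm(G, 4, 2)
    planted <- unique(c(pk$marker_idx, pk$subgroup_idx,
                        unlist(lapply(plan$candidates, function(cd)
                          cd$partners$idx[cd$partners$class == k]))))
    if (length(planted))
      b[planted] <- stats::rnorm(length(planted), 6.5, 0.5)
    lengths <- NULL
    if (k %in% RPKM_CLASSES)
      lengths <- stats::setNames(
        round(exp(stats::runif(G, log(200), log(20000)))), ids)
    lib <- round(stats::runif(nS, config$lib_size_range[1],
                              config$lib_size_range[2]))

    M <- matrix(b, G, nS)
    ## markers: shifted in every cancer sample, relaxing after treatment
    if (length(pk$marker_idx)) {
      d <- ifelse(pk$marker_dir == "up", 1, -1) * config$marker_log2fc
      M[pk$marker_idx, col_pre] <- M[pk$marker_idx, col_pre] + d
      M[pk$marker_idx, col_post] <- M[pk$marker_idx, col_post] +
        d * (1 - config$marker_relax)
      if (config$ac_log2fc != 0 && nAC > 0) {
        ac_cols <- c(col_pre[seq_len(nAC)], col_post[seq_len(nAC)])
        M[pk$marker_idx, ac_cols] <- M[pk$marker_idx, ac_cols] +
          config$ac_log2fc
      }
    }
    ## subgroup snoRNAs: overexpressed only in the subgroup patients
    if (k == "snoRNA" && length(pk$subgroup_idx) && length(sub_patients)) {
      sub_cols <- c(col_pre[match(sub_patients, patients)],
                    col_post[match(sub_patients, patients)])
      M[pk$subgroup_idx, sub_cols] <- M[pk$subgroup_idx, sub_cols] +
        config$subgroup_log2fc
    }
    ## planted treatment-response correlations: shared latent per candidate,
    ## applied half to the pre sample (-a/2 u) and half to the post sample
    ## (+a/2 u) so the paired log2FC carries the full a*u swing while each
    ## sample's mean moves only half of it. The weight a solves
    ## a^2 / (a^2 + noise(a)) = rho, where noise(a) is the delta-method
    ## count-level variance of a paired log2FC at the feature's baseline
    ## mean; the Poisson terms are inflated by E[2^(a/2 u)] because the
    ## swing modulates its own mean (fixed-point iteration, converges for
    ## the half-split construction).
    base_total <- sum(2^b)
    for (cd in plan$candidates) {
      rows <- integer(0)
      if (cd$class == k) rows <- cd$idx
      rows <- c(rows, cd$partners$idx[cd$partners$class == k])
      if (!length(rows)) next
      mu_base <- pmax(2^b[rows] / base_total * mean_lib, 1e-8)
      ## per-sample log-variance of an NB(mu, phi) count: the Poisson-gamma
      ## decomposition gives trigamma(1/phi) for the biological part and
      ## E[1/lambda] = 1/(mu (1 - phi)) for the counting part
      gvar <- if (phi > 1e-12) trigamma(1 / phi) else 0
      pshrink <- max(1 - phi, 0.5)
      a <- sqrt(rho / (1 - rho) *
                  (2 * gvar + 2 / (mu_base * pshrink)) / log(2)^2)
      for (it in 1:8) {
        infl <- exp((a / 2 * log(2))^2 / 2)
        noise <- (2 * gvar + 2 * infl / (mu_base * pshrink)) / log(2)^2
        a <- pmin(sqrt(rho / (1 - rho) * noise), 4)
      }
      half <- (a / 2) %o% latent[cd$latent, ]
      M[rows, col_pre] <- M[rows, col_pre] - half
      M[rows, col_post] <- M[rows, col_post] + half
    }

    w <- 2^M
    mu <- sweep(w, 2, colSums(w), "/") * rep(lib, each = G)
    counts <- if (phi > 1e-12) {
      matrix(stats::rnbinom(G * nS, mu = mu, size = 1 / phi), G, nS)
    } else {
      matrix(stats::rpois(G * nS, lambda = mu), G, nS)
    }
    dimnames(counts) <- list(ids, samples$sample_id)
    storage.mode(counts) <- "double"
    expression[[k]] <- expression_set(counts, k, lengths = lengths)

    if (length(pk$marker_idx))
      truth_markers[[k]] <- data.frame(feature_id = ids[pk$marker_idx],
                                       direction = pk$marker_dir,
                                       stringsAsFactors = FALSE)
  }

  for (cd in plan$candidates) {
    cid <- all_ids[[cd$class]][cd$idx]
    truth_partners[[cid]] <- list(
      class = cd$class,
      partner_ids = mapply(function(pc, pi) all_ids[[pc]][pi],
                           cd$partners$class, cd$partners$idx,
                           USE.NAMES = FALSE),
      partner_classes = cd$partners$class,
      rho = config$response_corr)
  }
  sub_features <- if (length(plan$classes$snoRNA$subgroup_idx))
    all_ids$snoRNA[plan$classes$snoRNA$subgroup_idx] else character(0)

  truth <- list(planted_markers = truth_markers,
                planted_partners = truth_partners,
                snorna_subgroup_patients = sub_patients,
                snorna_subgroup_features = sub_features)
  list(expression = expression, samples = samples, truth = truth,
       config = config)
}

#' Write a cohort to disk / read it back
#'
#' Writes one counts TSV per class (plus a lengths TSV for RPKM classes), a
#' sample sheet TSV and a ground-truth JSON, so the cohort round-trips through
#' the package readers losslessly.
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir` (write) or a cohort list (read), with `truth = NULL` when no
#'   ground-truth file is present.
#' @export
write_cohort <- function(cohort, dir) {
  if (!length(cohort$expression))
    contract_error("cohort has an empty expression class map")
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok) stopf("cannot create directory %s", dir, class = "exoscreen_io_error")
  for (k in names(cohort$expression)) {
    es <- cohort$expression[[k]]
    lp <- if (es$unit == "RPKM") file.path(dir, sprintf("lengths_%s.tsv", k))
    write_expression(es, file.path(dir, sprintf("counts_%s.tsv", k)),
                     lengths_path = lp)
  }
  write_tsv(as.data.frame(cohort$samples), file.path(dir, "samples.tsv"))
  if (!is.null(cohort$truth))
    jsonlite::write_json(cohort$truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  files <- list.files(dir, pattern = "^counts_.*\\.tsv$")
  if (!length(files)) format_error("no counts_<class>.tsv files in %s", dir)
  classes <- sub("^counts_(.*)\\.tsv$", "\\1", files)
  classes <- intersect(RNA_CLASSES, classes) # canonical order
  expression <- lapply(classes, function(k) {
    lp <- file.path(dir, sprintf("lengths_%s.tsv", k))
    read_expression(file.path(dir, sprintf("counts_%s.tsv", k)), k,
                    lengths_path = if (file.exists(lp)) lp)
  })
  names(expression) <- classes
  truth_path <- file.path(dir, "ground_truth.json")
  truth <- if (file.exists(truth_path))
    jsonlite::read_json(truth_path, simplifyVector = TRUE)
  list(expression = expression,
       samples = read_samples(file.path(dir, "samples.tsv")),
       truth = truth)
}
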