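# Shared fixtures, generated in code at test time.

## A scaled-down cohort configuration for fast unit tests. The full-size
## study conditions (sim_config() defaults) are exercised by the acceptance
## suite.
small_sim_config <- function(seed = 3, ...) {
  args <- list(class_sizes = c(miRNA = 60L, piRNA = 80L, lncRNA = 100L,
                               snoRNA = 50L, snRNA = 60L, tRNA = 60L,
                               yRNA = 50L, mRNA = 400L),
               n_markers_per_class = 8L,
               n_partner_mrnas = 30L,
               n_partner_ncrnas = 9L,
               lib_size_range = c(20000L, 40000L),
               seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

## Random NB count matrix with unique ids.
random_counts <- function(n_features, n_samples, mu_log_mean = 4,
                          phi = 0.2, prefix = "f") {
  mu <- exp(rnorm(n_features, mu_log_mean, 1))
  m <- matrix(rnbinom(n_features * n_samples, mu = mu, size = 1 / phi),
              n_features, n_samples,
              dimnames = list(sprintf("%s%03d", prefix, seq_len(n_features)),
                              sprintf("s%02d", seq_len(n_samples))))
  storage.mode(m) <- "double"
  m
}

## Minimal valid sample sheet: nn normals, nc cancer patients with pre/post.
toy_samples <- function(nn = 4, nc = 6, n_ac = 2) {
  patients <- sprintf("P%02d", seq_len(nc))
  path <- ifelse(seq_len(nc) <= n_ac, "AC", "nonAC")
  validate_samples(rbind(
    data.frame(sample_id = sprintf("N%02d", seq_len(nn)),
               patient_id = sprintf("N%02d", seq_len(nn)),
               group = "normal", timepoint = "pre", pathology = "none"),
    data.frame(sample_id = paste0(patients, "_pre"), patient_id = patients,
               group = "cancer", timepoint = "pre", pathology = path),
    data.frame(sample_id = paste0(patients, "_post"), patient_id = patients,
               group = "cancer", timepoint = "post", pathology = path)))
}

## DEG table stub.
deg_stub <- function(ids, lfc, p) {
  data.frame(feature_id = ids, log2fc = lfc, pvalue = p,
             mean_case = 2^lfc, mean_control = 1,
             stringsAsFactors = FALSE)
}
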