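#' Expression set for one RNA class
#'
#' Lightweight container for a single RNA class: an integer count matrix
#' (features x samples), the class label, and, for the length-normalized
#' classes (lncRNA and mRNA), per-feature lengths in nucleotides. The
#' expression unit is implied by the class: RPKM for lncRNA/mRNA, RPM
#' otherwise.
#'
#' @param counts Numeric matrix of non-negative integer read counts with
#'   unique feature rownames and unique sample colnames.
#' @param rna_class One of `"miRNA"`, `"piRNA"`, `"lncRNA"`, `"snoRNA"`,
#'   `"snRNA"`, `"tRNA"`, `"yRNA"`, `"mRNA"`.
#' @param lengths Named vector of positive feature lengths (nt). Required for
#'   the RPKM classes (lncRNA, mRNA) and must be absent otherwise.
#' @param unit Expression unit, `"RPM"` or `"RPKM"`. Defaults to the class
#'   convention and rarely needs to be supplied.
#'
#' @return An object of class `ExprSet`: a list with elements `counts`,
#'   `rna_class`, `lengths` and `unit`.
#' @export
expression_set <- function(counts, rna_class, lengths = NULL, unit = NULL) {
  rna_class <- match.arg(rna_class, RNA_CLASSES)
  if (!is.matrix(counts) || !is.numeric(counts))
    format_error("counts for class %s must be a numeric matrix", rna_class)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    format_error("counts for class %s must have feature rownames and sample colnames",
                 rna_class)
  if (anyDuplicated(rownames(counts)))
    format_error("duplicate feature ids in class %s: %s", rna_class,
                 paste(unique(rownames(counts)[duplicated(rownames(counts))]),
                       collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    format_error("duplicate sample ids in class %s", rna_class)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    format_error("counts for class %s must be non-negative integers", rna_class)
  if (is.null(unit)) unit <- if (rna_class %in% RPKM_CLASSES) "RPKM" else "RPM"
  unit <- match.arg(unit, c("RPM", "RPKM"))
  if (unit == "RPKM") {
    if (is.null(lengths))
      format_error("class %s uses RPKM and requires feature lengths", rna_class)
    lengths <- lengths[rownames(counts)]
    if (anyNA(lengths) || any(lengths <= 0))
      format_error("lengths for class %s must cover every feature and be positive",
                   rna_class)
    lengths <- stats::setNames(as.numeric(lengths), rownames(counts))
  } else if (!is.null(lengths)) {
    format_error("class %s uses RPM; lengths must not be supplied", rna_class)
  }
  structure(list(counts = counts, rna_class = rna_class,
                 lengths = lengths, unit = unit),
            class = "ExprSet")
}

#' @export
print.ExprSet <- function(x, ...) {
  cat(sprintf("ExprSet: %s, %d features x %d samples, unit %s\n",
              x$rna_class, nrow(x$counts), ncol(x$counts), x$unit))
  invisible(x)
}

#' @export
dim.ExprSet <- function(x) dim(x$counts)

#' Subset an expression set
#'
#' @param x An [expression_set()].
#' @param features,samples Character vectors (or indices) of features/samples
#'   to keep; `NULL` keeps all.
#' @return A new `ExprSet`.
#' @export
subset_expression <- function(x, features = NULL, samples = NULL) {
  stopifnot(inherits(x, "ExprSet"))
  counts <- x$counts
  if (!is.null(features)) counts <- counts[features, , drop = FALSE]
  if (!is.null(samples)) counts <- counts[, samples, drop = FALSE]
  lengths <- if (!is.null(x$lengths)) x$lengths[rownames(counts)] else NULL
  expression_set(counts, x$rna_class, lengths = lengths, unit = x$unit)
}

#' Validate a sample sheet
#'
#' Checks the cohort design table: sample/patient ids, `group` in
#' normal/cancer, `timepoint` in pre/post, `pathology` in AC/nonAC/none.
#' Normal samples must be pre-treatment with pathology `none`; every cancer
#' patient must have exactly one pre-treatment sample and at most one
#' post-treatment sample, with constant pathology.
#'
#' @param samples A data.frame with columns `sample_id`, `patient_id`,
#'   `group`, `timepoint`, `pathology`.
#' @return The validated data.frame (invisibly classed `sample_table`).
#' @export
validate_samples <- function(samples) {
  need <- c("sample_id", "patient_id", "group", "timepoint", "pathology")
  if (!is.data.frame(samples) || !all(need %in% names(samples)))
    format_error("sample sheet must contain columns: %s",
                 paste(need, collapse = ", "))
  samples <- as.data.frame(samples)[need]
  for (col in need) samples[[col]] <- as.character(samples[[col]])
  if (anyDuplicated(samples$sample_id))
    format_error("duplicate sample ids in sample sheet")
  if (!all(samples$group %in% c("normal", "cancer")))
    format_error("group must be 'normal' or 'cancer'")
  if (!all(samples$timepoint %in% c("pre", "post")))
    format_error("timepoint must be 'pre' or 'post'")
  if (!all(samples$pathology %in% c("AC", "nonAC", "none")))
    format_error("pathology must be 'AC', 'nonAC' or 'none'")
  nrm <- samples[samples$group == "normal", ]
  if (any(nrm$timepoint != "pre") || any(nrm$pathology != "none"))
    format_error("normal samples must have timepoint 'pre' and pathology 'none'")
  cc <- samples[samples$group == "cancer", ]
  if (nrow(cc)) {
    if (any(cc$pathology == "none"))
      format_error("cancer samples must have pathology 'AC' or 'nonAC'")
    for (p in unique(cc$patient_id)) {
      rows <- cc[cc$patient_id == p, ]
      if (sum(rows$timepoint == "pre") != 1)
        format_error("cancer patient %s must have exactly one pre sample", p)
      if (sum(rows$timepoint == "post") > 1)
        format_error("cancer patient %s has more than one post sample", p)
      if (length(unique(rows$pathology)) != 1)
        format_error("cancer patient %s has inconsistent pathology", p)
    }
  }
  class(samples) <- c("sample_table", "data.frame")
  invisible(samples)
}

#' Select sample ids from a sample table
#'
#' @param samples A validated sample table.
#' @param group,timepoint,pathology Optional filters; `NULL` keeps all.
#' @return Character vector of matching sample ids.
#' @export
samples_of <- function(samples, group = NULL, timepoint = NULL,
                       pathology = NULL) {
  keep <- rep(TRUE, nrow(samples))
  if (!is.null(group)) keep <- keep & samples$group %in% group
  if (!is.null(timepoint)) keep <- keep & samples$timepoint %in% timepoint
  if (!is.null(pathology)) keep <- keep & samples$pathology %in% pathology
  samples$sample_id[keep]
}
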