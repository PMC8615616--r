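# Readers and writers for the tabular artifacts the pipeline touches.
# Canonical dialect: UTF-8 TSV without quoting; count matrices have the
# feature id in the first column and sample ids in the header.

#' Read a count matrix for one RNA class
#'
#' @param path TSV file: first column feature ids, remaining columns integer
#'   counts per sample.
#' @param rna_class RNA class label, see [expression_set()].
#' @param lengths_path Optional two-column TSV (`feature_id`, `length_nt`);
#'   required for the RPKM classes (lncRNA, mRNA).
#' @return An [expression_set()].
#' @export
read_expression <- function(path, rna_class, lengths_path = NULL) {
  if (!file.exists(path)) format_error("count file not found: %s", path)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) format_error("count file %s has no sample columns", path)
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids))
    format_error("duplicate feature ids in %s: %s", path,
                 paste(unique(ids[duplicated(ids)]), collapse = ", "))
  mat <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(mat) || anyNA(mat))
    format_error("non-numeric or missing count cells in %s", path)
  if (any(mat < 0) || any(mat != round(mat)))
    format_error("counts in %s must be non-negative integers", path)
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  lengths <- NULL
  if (!is.null(lengths_path)) {
    if (!file.exists(lengths_path))
      format_error("lengths file not found: %s", lengths_path)
    lt <- utils::read.delim(lengths_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    lengths <- stats::setNames(as.numeric(lt[[2]]), as.character(lt[[1]]))
  }
  expression_set(mat, rna_class, lengths = lengths)
}

#' Write a count matrix
#'
#' @param es An [expression_set()].
#' @param path Output TSV path.
#' @param lengths_path Optional path for the companion lengths TSV (written
#'   only for RPKM classes).
#' @return `path`, invisibly.
#' @export
write_expression <- function(es, path, lengths_path = NULL) {
  stopifnot(inherits(es, "ExprSet"))
  tab <- data.frame(feature_id = rownames(es$counts), es$counts,
                    check.names = FALSE)
  write_tsv(tab, path)
  if (!is.null(lengths_path) && !is.null(es$lengths)) {
    write_tsv(data.frame(feature_id = names(es$lengths),
                         length_nt = as.integer(es$lengths)), lengths_path)
  }
  invisible(path)
}

#' Read a sample sheet
#'
#' @param path TSV with columns `sample_id`, `patient_id`, `group`,
#'   `timepoint`, `pathology`.
#' @return A validated sample table, see [validate_samples()].
#' @export
read_samples <- function(path) {
  if (!file.exists(path)) format_error("sample sheet not found: %s", path)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_samples(tab)
}

#' Read a gene-to-category annotation map
#'
#' Stand-in for a pathway knowledge base: a two-column TSV mapping a feature
#' id to semicolon-separated category labels.
#'
#' @param path TSV path.
#' @return Named list: feature id -> character vector of category labels.
#' @export
read_categories <- function(path) {
  if (!file.exists(path)) format_error("category map not found: %s", path)
  tab <- utils::read.delim(path, header = FALSE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) format_error("category map %s must have two columns", path)
  ## tolerate an optional header row
  if (identical(tolower(tab[1, 1]), "feature_id")) tab <- tab[-1, , drop = FALSE]
  ids <- as.character(tab[[1]])
  labs <- strsplit(as.character(tab[[2]]), ";", fixed = TRUE)
  labs <- lapply(labs, function(x) {
    x <- trimws(x)
    x <- x[nzchar(x)]
    if (!length(x)) format_error("empty category label set in %s", path)
    x
  })
  stats::setNames(labs, ids)
}

#' Write any rectangular report as TSV
#'
#' @param tab A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(tab, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) format_error("directory does not exist: %s", dir)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Write / read a screening report as JSON
#'
#' @param report A list (e.g. the result of [run_pipeline()]).
#' @param path JSON path.
#' @return `path` (write) or the report list (read).
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  if (!file.exists(path)) format_error("report not found: %s", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
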