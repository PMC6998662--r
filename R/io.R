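#' Read and validate a sample metadata table
#'
#' One row per serum sample. Columns: `sample_id`, `subject_id`, `group`
#' (case/control), `sex`, `age_at_donation` (years), `bdg` (blood donor
#' group, a technical batch label), `smoking`, `stage`, `histology`, and
#' `time_to_diagnosis` (months before diagnosis; empty for controls).
#' Controls must carry `stage = histology = "not_applicable"` and no
#' `time_to_diagnosis`; cases must have a time to diagnosis within the
#' follow-up span.
#'
#' @param path Path to a tab-separated file with the columns above.
#' @param span_months Follow-up span used to bound case times (default 120).
#' @return A tibble of validated sample records.
#' @examples
#' coh <- simulate_cohort(n_rnas = 12, margins = toy_margins(), seed = 1)
#' f <- tempfile(fileext = ".tsv")
#' write_sample_table(coh$samples, f)
#' identical(read_sample_table(f), dplyr::arrange(coh$samples, sample_id))
#' @export
read_sample_table <- function(path, span_months = 120) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  tbl <- readr::read_tsv(
    path,
    col_types = readr::cols(
      sample_id = "c", subject_id = "c", group = "c", sex = "c",
      age_at_donation = "d", bdg = "c", smoking = "c", stage = "c",
      histology = "c", time_to_diagnosis = "d"
    ),
    progress = FALSE
  )
  prob <- readr::problems(tbl)
  if (nrow(prob) > 0) {
    abort(sprintf("malformed sample table: parse failure at line %d (%s)",
                  prob$row[1] + 1L, prob$expected[1]))
  }
  missing_cols <- setdiff(sample_table_cols(), names(tbl))
  if (length(missing_cols)) {
    abort(paste0("sample table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  validate_samples(tbl[sample_table_cols()], span_months = span_months)
}

#' Validate a sample table against the cohort invariants
#'
#' @param samples A data frame shaped as in [read_sample_table()].
#' @inheritParams read_sample_table
#' @return The validated tibble (invisibly the same data).
#' @export
validate_samples <- function(samples, span_months = 120) {
  samples <- tibble::as_tibble(samples)
  check_enum(samples$group, group_levels(), "group")
  check_enum(samples$sex, sex_levels(), "sex")
  check_enum(samples$smoking, smoking_levels(), "smoking")
  check_enum(samples$stage, stage_levels(), "stage")
  check_enum(samples$histology, histology_levels(), "histology")
  if (anyDuplicated(samples$sample_id)) {
    abort("duplicated sample_id values in sample table")
  }
  is_case <- samples$group == "case"
  if (any(is_case & is.na(samples$time_to_diagnosis))) {
    abort("case sample(s) without time_to_diagnosis")
  }
  bad_t <- is_case & (samples$time_to_diagnosis < 0 |
                        samples$time_to_diagnosis > span_months)
  if (any(bad_t, na.rm = TRUE)) {
    abort(sprintf("case time_to_diagnosis outside [0, %s] months", span_months))
  }
  if (any(!is_case & !is.na(samples$time_to_diagnosis))) {
    abort("control sample(s) carry a time_to_diagnosis")
  }
  if (any(!is_case & (samples$stage != "not_applicable" |
                        samples$histology != "not_applicable"))) {
    abort("controls must have stage and histology 'not_applicable'")
  }
  if (any(is_case & (samples$stage == "not_applicable" |
                       samples$histology == "not_applicable"))) {
    abort("cases must carry a stage and histology")
  }
  samples
}

#' Write a sample table
#'
#' Rows are emitted in lexicographic `sample_id` order; missing values are
#' empty cells.
#'
#' @inheritParams validate_samples
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(samples, path) {
  samples <- dplyr::arrange(tibble::as_tibble(samples), .data$sample_id)
  readr::write_tsv(samples[sample_table_cols()], path, na = "", progress = FALSE)
  invisible(path)
}

#' Read a count matrix of RNA features by sample
#'
#' The file's first two columns are `rna_id` and `rna_class` (one of the ten
#' circulating RNA classes, see [rna_classes()]); the remaining columns are
#' non-negative integer counts, one column per sample.
#'
#' @param path Path to a tab-separated count file.
#' @return A tibble with columns `rna_id`, `rna_class`, then one integer
#'   column per sample (the package's count-matrix layout).
#' @export
read_count_matrix <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    rna_id = "c", rna_class = "c", .default = "d"
  ), progress = FALSE)
  if (!all(c("rna_id", "rna_class") %in% names(tbl))) {
    abort("count matrix must start with columns rna_id, rna_class")
  }
  validate_counts(tbl)
}

#' Validate a count-matrix tibble
#'
#' @param counts A tibble in the layout of [read_count_matrix()].
#' @return The validated tibble, count columns coerced to integer.
#' @export
validate_counts <- function(counts) {
  counts <- tibble::as_tibble(counts)
  check_enum(counts$rna_class, rna_classes(), "rna_class")
  if (anyDuplicated(counts$rna_id)) abort("duplicated rna_id values")
  value_cols <- setdiff(names(counts), c("rna_id", "rna_class"))
  if (!length(value_cols)) abort("count matrix has no sample columns")
  for (cl in value_cols) {
    x <- counts[[cl]]
    if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x != floor(x))) {
      abort(sprintf("sample column `%s` must hold non-negative integer counts", cl))
    }
    counts[[cl]] <- as.integer(x)
  }
  counts
}

#' Write a count matrix
#'
#' @inheritParams validate_counts
#' @param path Output path (tab-separated). Rows are ordered by `rna_id`.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(counts, path) {
  counts <- dplyr::arrange(tibble::as_tibble(counts), .data$rna_id)
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}

# internal: count tibble -> integer matrix (RNA x sample)
count_mat <- function(counts, sample_ids = NULL) {
  value_cols <- setdiff(names(counts), c("rna_id", "rna_class"))
  if (!is.null(sample_ids)) {
    missing <- setdiff(sample_ids, value_cols)
    if (length(missing)) {
      abort(paste0("count matrix lacks sample column(s): ",
                   paste(head(missing, 5), collapse = ", ")))
    }
    value_cols <- sample_ids
  }
  m <- as.matrix(counts[value_cols])
  rownames(m) <- counts$rna_id
  storage.mode(m) <- "double"
  m
}

#' Filter out RNAs with low read support
#'
#' Retains an RNA if and only if it has at least `min_reads` reads in at
#' least `min_fraction` of the samples (boundaries inclusive). Kept rows are
#' unchanged; the sample set is never altered. The defaults reproduce the
#' standard serum small-RNA filter of at least 5 reads in at least 20% of
#' samples.
#'
#' @inheritParams validate_counts
#' @param min_reads Minimum read count for a sample to support an RNA.
#' @param min_fraction Minimum fraction of samples that must support it.
#' @return The filtered count tibble.
#' @examples
#' cm <- tibble::tibble(rna_id = c("a", "b"), rna_class = "miRNA",
#'                      s1 = c(9L, 0L), s2 = c(7L, 1L))
#' filter_low_counts(cm, min_reads = 5, min_fraction = 0.5)
#' @export
filter_low_counts <- function(counts, min_reads = 5, min_fraction = 0.20) {
  assert_scalar_number(min_reads, "min_reads", min = 0)
  assert_scalar_number(min_fraction, "min_fraction", min = 1e-12, max = 1)
  counts <- tibble::as_tibble(counts)
  m <- count_mat(counts)
  if (nrow(m) == 0L || ncol(m) == 0L) abort("cannot filter an empty count matrix")
  keep <- rowMeans(m >= min_reads) >= min_fraction
  counts[keep, , drop = FALSE]
}
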