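#' Study configuration
#'
#' Bundles the design constants of the prediagnostic analysis: the 10-year
#' (120-month) follow-up span split into seven fixed time windows, the
#' 17-month sliding window advanced in 2.5-month steps, per-window case
#' quotas (27 cases with 5 controls each for the stage-mixed analysis;
#' 9/14/18 cases for the early, locally advanced and advanced stage-specific
#' analyses), 20 bootstrap iterations, the low-count filter (at least 5 reads
#' in at least 20% of samples), the 0.05 adjusted-p significance cutoff and
#' the >60 target-prediction score cutoff.
#'
#' @param ... Named overrides of the defaults listed above, e.g.
#'   `study_config(n_bootstrap = 5)`. Unknown names are an error.
#' @return A named list with class `"study_config"`.
#' @examples
#' cfg <- study_config()
#' cfg$n_fixed_windows                 # 7
#' study_config(control_ratio = 3)$control_ratio
#' @export
study_config <- function(...) {
  cfg <- list(
    span_months = 120,
    n_fixed_windows = 7L,
    sliding_width_months = 17,
    sliding_step_months = 2.5,
    phase2_cases_per_window = 27L,
    control_ratio = 5L,
    phase3_cases = c(early = 9L, locally_advanced = 14L, advanced = 18L),
    n_bootstrap = 20L,
    filter_min_reads = 5,
    filter_min_fraction = 0.20,
    alpha = 0.05,
    target_score_cutoff = 60,
    rng_seed = 1L
  )
  overrides <- list(...)
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(cfg))
    if (length(unknown) || is.null(names(overrides)) || any(names(overrides) == "")) {
      abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
    }
    cfg <- modifyList(cfg, overrides)
  }
  validate_config(cfg)
  structure(cfg, class = "study_config")
}

validate_config <- function(cfg) {
  assert_scalar_number(cfg$span_months, "span_months", min = 1)
  assert_scalar_number(cfg$n_fixed_windows, "n_fixed_windows", min = 1)
  assert_scalar_number(cfg$sliding_width_months, "sliding_width_months", min = 1e-9)
  assert_scalar_number(cfg$sliding_step_months, "sliding_step_months",
                       min = 1e-9, max = cfg$sliding_width_months)
  assert_scalar_number(cfg$phase2_cases_per_window, "phase2_cases_per_window", min = 1)
  assert_scalar_number(cfg$control_ratio, "control_ratio", min = 1)
  if (!is.numeric(cfg$phase3_cases) || length(cfg$phase3_cases) != 3L ||
      any(cfg$phase3_cases < 1)) {
    abort("`phase3_cases` must be three positive counts (early, locally_advanced, advanced)")
  }
  assert_scalar_number(cfg$n_bootstrap, "n_bootstrap", min = 1)
  assert_scalar_number(cfg$filter_min_reads, "filter_min_reads", min = 0)
  assert_scalar_number(cfg$filter_min_fraction, "filter_min_fraction", min = 1e-12, max = 1)
  if (cfg$alpha <= 0 || cfg$alpha >= 1) abort("`alpha` must be in (0, 1)")
  assert_scalar_number(cfg$target_score_cutoff, "target_score_cutoff", min = 0, max = 100)
  invisible(cfg)
}

#' Read a study configuration from a YAML or JSON file
#'
#' Keys absent from the file keep their [study_config()] defaults; unknown
#' keys raise an error so typos cannot silently change an analysis.
#'
#' @param path Path to a YAML (or JSON, which YAML subsumes) mapping.
#' @return A `study_config` object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) abort("config file must contain a mapping of keys to values")
  if ("phase3_cases" %in% names(raw)) raw$phase3_cases <- unlist(raw$phase3_cases)
  do.call(study_config, raw)
}
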