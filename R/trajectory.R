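#' Run one analysis phase of the prediagnostic pipeline
#'
#' Phase 1 analyses all samples at once (no smoking restriction; missing
#' smoking is kept as an explicit `"unknown"` level). Phases 2 and 3 run the
#' seven fixed time windows and phase 4 the sliding windows; in these phases
#' cases and controls are restricted to current/former smokers, each
#' window's cases are drawn stage-balanced ([select_window_samples()]) with
#' optimally matched controls, and the covariate-adjusted negative-binomial
#' Wald test is applied per window. A window whose selection or matching
#' fails is reported as skipped and the run continues.
#'
#' @param samples Sample table (cases and controls).
#' @param counts Count tibble; the low-count filter of `cfg` is applied once
#'   across the supplied samples before any window is analysed.
#' @param phase 1, 2, 3 or 4.
#' @param cfg A [study_config()].
#' @param stage_filter Optional stage subset for the analysed cases
#'   (required for phase 3).
#' @param histology_filter Optional histology subset for the analysed cases.
#' @param seed Integer seed; every window derives its own child seed.
#' @param n_cases Case quota per window. Defaults: 27 for phase 2; the
#'   stage-specific quota (9/14/18) for phases 3 and 4 run on a single
#'   stage; 27 otherwise.
#' @param ratio_k Controls per case (default from `cfg`).
#' @param spec [match_spec()] used inside windows (default: optimal age
#'   matching exact on sex).
#' @param windows Optional window tibble overriding the phase's default
#'   (e.g. `make_fixed_windows(120, 5)` for the 2-year robustness variant).
#' @return A tibble (class `phase_summaries`), one row per window: window
#'   coordinates, sample counts, `n_tested`, `n_de` (RNAs with
#'   `padj < cfg$alpha`), `skipped`/`reason`, and a `de` list-column holding
#'   the significant RNAs (`rna_id`, `rna_class`, `log2fc`, `padj`).
#' @export
run_phase <- function(samples, counts, phase, cfg = study_config(),
                      stage_filter = NULL, histology_filter = NULL,
                      seed = 1L, n_cases = NULL, ratio_k = cfg$control_ratio,
                      spec = match_spec(exact_vars = "sex"), windows = NULL) {
  if (!phase %in% 1:4) abort("`phase` must be 1, 2, 3 or 4")
  if (phase == 3 && is.null(stage_filter)) {
    abort("phase 3 requires a `stage_filter`")
  }
  counts <- filter_low_counts(counts, cfg$filter_min_reads, cfg$filter_min_fraction)

  keep_case <- samples$group == "case"
  if (!is.null(stage_filter)) keep_case <- keep_case & samples$stage %in% stage_filter
  if (!is.null(histology_filter)) keep_case <- keep_case & samples$histology %in% histology_filter
  samples <- samples[keep_case | samples$group == "control", , drop = FALSE]

  if (phase == 1) {
    res <- run_de(counts, samples)
    win <- tibble::tibble(label = "all", start_months = 0,
                          end_months = cfg$span_months,
                          center_months = cfg$span_months / 2)
    return(summarise_windows(list(summarise_one(win, res, samples, cfg)), cfg, phase))
  }

  if (is.null(windows)) {
    windows <- if (phase == 4) {
      make_sliding_windows(cfg$sliding_width_months, cfg$sliding_step_months,
                           cfg$span_months)
    } else {
      make_fixed_windows(cfg$span_months, cfg$n_fixed_windows)
    }
  }
  if (is.null(n_cases)) {
    n_cases <- if (phase %in% c(3, 4) && length(stage_filter) == 1 &&
                     stage_filter %in% names(cfg$phase3_cases)) {
      cfg$phase3_cases[[stage_filter]]
    } else {
      cfg$phase2_cases_per_window
    }
  }

  rows <- lapply(seq_len(nrow(windows)), function(i) {
    win <- windows[i, ]
    wseed <- derive_seed(seed, paste0("window", win$label))
    sel <- tryCatch(
      select_window_samples(samples, win, n_cases = n_cases, ratio_k = ratio_k,
                            spec = spec, seed = wseed, smokers_only = TRUE),
      error = function(e) e)
    if (inherits(sel, "error")) {
      return(skipped_row(win, conditionMessage(sel)))
    }
    sub <- samples[samples$sample_id %in% c(sel$case_ids, sel$control_ids), ]
    res <- tryCatch(run_de(counts, sub), error = function(e) e)
    if (inherits(res, "error")) {
      return(skipped_row(win, conditionMessage(res)))
    }
    summarise_one(win, res, sub, cfg)
  })
  summarise_windows(rows, cfg, phase)
}

summarise_one <- function(win, res, sub, cfg) {
  sig <- res[!is.na(res$padj) & res$padj < cfg$alpha,
             c("rna_id", "rna_class", "log2fc", "padj")]
  tibble::tibble(
    label = win$label, start_months = win$start_months,
    end_months = win$end_months, center_months = win$center_months,
    n_cases = sum(sub$group == "case"),
    n_controls = sum(sub$group == "control"),
    n_tested = sum(!is.na(res$pvalue)),
    n_de = nrow(sig),
    skipped = FALSE, reason = NA_character_,
    de = list(tibble::as_tibble(sig))
  )
}

skipped_row <- function(win, reason) {
  tibble::tibble(
    label = win$label, start_months = win$start_months,
    end_months = win$end_months, center_months = win$center_months,
    n_cases = 0L, n_controls = 0L, n_tested = 0L, n_de = NA_integer_,
    skipped = TRUE, reason = reason, de = list(empty_de())
  )
}

empty_de <- function() {
  tibble::tibble(rna_id = character(), rna_class = character(),
                 log2fc = numeric(), padj = numeric())
}

summarise_windows <- function(rows, cfg, phase) {
  out <- dplyr::bind_rows(rows)
  class(out) <- c("phase_summaries", class(out))
  attr(out, "alpha") <- cfg$alpha
  attr(out, "phase") <- phase
  out
}

#' @export
glance.phase_summaries <- function(x, ...) {
  run <- x[!x$skipped, ]
  tibble::tibble(
    n_windows = nrow(x),
    n_skipped = sum(x$skipped),
    total_de = sum(run$n_de),
    median_de = median(run$n_de),
    peak_center_months = ifelse(nrow(run) && any(run$n_de > 0),
                                run$center_months[which.max(run$n_de)],
                                NA_real_)
  )
}

#' Bootstrap the per-window signal of a stage-specific analysis
#'
#' Reruns the phase-3 fixed-window analysis `n_iter` times; in each
#' iteration new cases are drawn (without replacement within the iteration)
#' and new controls rematched, and the per-window count of significant RNAs
#' is recorded. Summarises the dispersion of that signal per window.
#'
#' @inheritParams run_phase
#' @param stage The analysed stage (`"early"`, `"locally_advanced"`,
#'   `"advanced"`).
#' @param n_iter Number of resampling iterations (default from `cfg`).
#' @return A tibble (class `bootstrap_summary`), one row per window:
#'   `n_iter` completed iterations and mean/sd/min/max of `n_de` (sd is `NA`
#'   when a window completed fewer than 2 iterations).
#' @export
bootstrap_phase3 <- function(samples, counts, stage, cfg = study_config(),
                             seed = 1L, n_iter = cfg$n_bootstrap, ...) {
  runs <- lapply(seq_len(n_iter), function(it) {
    s <- run_phase(samples, counts, phase = 3, cfg = cfg, stage_filter = stage,
                   seed = derive_seed(seed, paste0("bootstrap", it)), ...)
    s$iteration <- it
    s
  })
  all <- dplyr::bind_rows(lapply(runs, function(s) {
    s[c("label", "center_months", "n_de", "skipped", "iteration")]
  }))
  out <- all |>
    dplyr::group_by(.data$label, .data$center_months) |>
    dplyr::summarise(
      n_iter = sum(!.data$skipped),
      mean_n_de = mean(.data$n_de[!.data$skipped]),
      sd_n_de = ifelse(sum(!.data$skipped) >= 2,
                       sd(.data$n_de[!.data$skipped]), NA_real_),
      min_n_de = suppressWarnings(min(.data$n_de[!.data$skipped])),
      max_n_de = suppressWarnings(max(.data$n_de[!.data$skipped])),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      min_n_de = ifelse(is.finite(.data$min_n_de), .data$min_n_de, NA_real_),
      max_n_de = ifelse(is.finite(.data$max_n_de), .data$max_n_de, NA_real_)
    ) |>
    dplyr::arrange(.data$center_months)
  class(out) <- c("bootstrap_summary", class(out))
  attr(out, "stage") <- stage
  out
}

#' Build an RNA-class signal trajectory from window summaries
#'
#' Orders the (non-skipped) windows by center time and tabulates the number
#' of significant RNAs per circulating RNA class in each window, plus the
#' total. Permuting the input rows does not change the result.
#'
#' @param summaries A `phase_summaries` tibble from [run_phase()].
#' @return A tibble (class `serotraj_trajectory`): `center_months`, `total`,
#'   and one count column per RNA class.
#' @export
build_trajectory <- function(summaries) {
  if (nrow(summaries) < 1) abort("`summaries` must contain at least one window")
  run <- summaries[!summaries$skipped, ]
  run <- run[order(run$center_months), ]
  counts_by_class <- lapply(run$de, function(d) {
    tab <- table(factor(d$rna_class, levels = rna_classes()))
    as.integer(tab)
  })
  mat <- do.call(rbind, counts_by_class)
  if (is.null(mat)) mat <- matrix(0L, 0, length(rna_classes()))
  colnames(mat) <- rna_classes()
  out <- tibble::tibble(center_months = run$center_months, total = run$n_de)
  out <- dplyr::bind_cols(out, tibble::as_tibble(mat))
  class(out) <- c("serotraj_trajectory", class(out))
  out
}

#' Detect signal peaks in a trajectory
#'
#' Local maxima of the total significant-RNA series with height at least
#' `min_height`, kept greedily in decreasing height order subject to a
#' pairwise separation of at least `min_separation_months` between peak
#' centers.
#'
#' @param traj A trajectory from [build_trajectory()].
#' @param min_height Minimum series value for a peak (default 1).
#' @param min_separation_months Minimum distance between reported peaks.
#' @return Numeric vector of peak center times (months before diagnosis),
#'   in decreasing height order.
#' @export
detect_peaks <- function(traj, min_height = 1, min_separation_months = 12) {
  t_series <- traj$total
  n <- length(t_series)
  if (n < 3) abort("trajectory must contain at least 3 windows")
  left <- c(-Inf, t_series[-n])
  right <- c(t_series[-1], -Inf)
  is_peak <- t_series >= left & t_series >= right &
    (t_series > left | t_series > right) & t_series >= min_height
  cand <- which(is_peak)
  cand <- cand[order(-t_series[cand], traj$center_months[cand])]
  kept <- numeric(0)
  for (i in cand) {
    ct <- traj$center_months[i]
    if (all(abs(ct - kept) >= min_separation_months)) kept <- c(kept, ct)
  }
  kept
}

#' RNAs recurring across time windows
#'
#' Lists RNAs significant in at least `min_windows` windows of one run,
#' with the windows and effect directions in which they appeared.
#'
#' @inheritParams build_trajectory
#' @param min_windows Minimum number of windows an RNA must appear in.
#' @return A tibble: `rna_id`, `rna_class`, `n_windows`, `windows`
#'   (list-column of window labels) and `signs` (list-column of per-window
#'   log2 fold-change signs).
#' @export
recurrent_rnas <- function(summaries, min_windows = 2L) {
  run <- summaries[!summaries$skipped, ]
  long <- dplyr::bind_rows(lapply(seq_len(nrow(run)), function(i) {
    d <- run$de[[i]]
    if (nrow(d) == 0) return(NULL)
    d$window <- run$label[i]
    d
  }))
  if (is.null(long) || nrow(long) == 0) {
    return(tibble::tibble(rna_id = character(), rna_class = character(),
                          n_windows = integer(), windows = list(),
                          signs = list()))
  }
  long |>
    dplyr::group_by(.data$rna_id, .data$rna_class) |>
    dplyr::summarise(
      n_windows = dplyr::n(),
      windows = list(.data$window),
      signs = list(sign(.data$log2fc)),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_windows >= min_windows) |>
    dplyr::arrange(dplyr::desc(.data$n_windows), .data$rna_id)
}
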