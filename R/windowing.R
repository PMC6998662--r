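#' Fixed prediagnostic time windows
#'
#' Splits the follow-up span into `n_windows` contiguous half-open windows
#' `[k * span/n, (k+1) * span/n)` measured in months before diagnosis. The
#' default seven windows over 120 months are ~17.1 months wide (the
#' "0-1.4", "1.5-2.8", ... year intervals).
#'
#' @param span_months Follow-up span in months.
#' @param n_windows Number of windows (>= 1).
#' @return A tibble with columns `label`, `start_months`, `end_months`,
#'   `center_months`.
#' @examples
#' make_fixed_windows(120, 7)
#' @export
make_fixed_windows <- function(span_months = 120, n_windows = 7L) {
  assert_scalar_number(span_months, "span_months", min = 1e-9)
  if (n_windows < 1) abort("`n_windows` must be >= 1")
  w <- span_months / n_windows
  start <- (seq_len(n_windows) - 1) * w
  tibble::tibble(
    label = sprintf("W%02d", seq_len(n_windows)),
    start_months = start,
    end_months = start + w,
    center_months = start + w / 2
  )
}

#' Sliding prediagnostic time windows
#'
#' Windows `[i*step, i*step + width)` for `i = 0 .. floor((span - width)/step)`.
#' The defaults (17-month width, 2.5-month step over 120 months) yield 42
#' overlapping windows; consecutive windows overlap by `width - step`.
#'
#' @param width_months Window width in months.
#' @param step_months Step size in months (0 < step <= width).
#' @param span_months Follow-up span in months.
#' @return A tibble as in [make_fixed_windows()].
#' @examples
#' nrow(make_sliding_windows(17, 2.5, 120))  # 42
#' @export
make_sliding_windows <- function(width_months = 17, step_months = 2.5,
                                 span_months = 120) {
  if (step_months <= 0) abort("`step_months` must be > 0")
  if (step_months > width_months) abort("`step_months` must be <= `width_months`")
  if (width_months > span_months) abort("`width_months` must be <= `span_months`")
  n <- 1L + floor((span_months - width_months) / step_months + 1e-9)
  start <- (seq_len(n) - 1) * step_months
  tibble::tibble(
    label = sprintf("S%03d", seq_len(n)),
    start_months = start,
    end_months = start + width_months,
    center_months = start + width_months / 2
  )
}

# largest-remainder allocation of n draws toward equal proportions over the
# strata sizes `avail` (named); backfills from strata with spare capacity
allocate_balanced <- function(avail, n) {
  s <- length(avail)
  if (sum(avail) < n) {
    abort(sprintf("insufficient cases: need %d, only %d available", n, sum(avail)))
  }
  quota <- rep(n / s, s)
  take <- pmin(floor(quota), avail)
  rem <- quota - floor(quota)
  # distribute remainders by largest remainder, then backfill shortfalls
  while (sum(take) < n) {
    room <- avail - take
    cand <- which(room > 0)
    pick <- cand[order(-rem[cand], cand)][1]
    take[pick] <- take[pick] + 1L
    rem[pick] <- rem[pick] - 1
  }
  setNames(as.integer(take), names(avail))
}

#' Select a window's cases and matched controls
#'
#' Draws `n_cases` case samples whose time to diagnosis falls in
#' `[start_months, end_months)`, allocated toward equal proportions of
#' `balance_var` (largest-remainder rule, backfilling from over-represented
#' strata when a stratum is short, with uniform sampling within stratum),
#' then selects `ratio_k` controls per case by optimal age matching.
#' Controls carry no prediagnostic time, so any control is eligible for any
#' window; within one window no control is used twice.
#'
#' @param samples A sample table; both cases and controls.
#' @param window One row of a window tibble (has `start_months`,
#'   `end_months`).
#' @param n_cases Case quota for the window.
#' @param ratio_k Controls per case.
#' @param balance_var Case covariate balanced toward equal proportions
#'   (default `"stage"`).
#' @param spec A [match_spec()] for the control matching; its `ratio_k` is
#'   overridden by `ratio_k`.
#' @param seed Integer seed for the case draw.
#' @param smokers_only Restrict cases and controls to current/former smokers
#'   (the rule for the windowed phases; set FALSE for all-sample analyses).
#' @return A list with class `"window_selection"`: `window`, `case_ids`,
#'   `control_ids`, `stage_composition`, `histology_composition`, `match`.
#' @export
select_window_samples <- function(samples, window, n_cases, ratio_k = 5L,
                                  balance_var = "stage",
                                  spec = match_spec(exact_vars = "sex",
                                                    ratio_k = ratio_k),
                                  seed = 1L, smokers_only = TRUE) {
  spec$ratio_k <- as.integer(ratio_k)
  if (smokers_only) samples <- samples[is_smoker(samples$smoking), , drop = FALSE]
  cases <- samples[samples$group == "case" &
                     !is.na(samples$time_to_diagnosis) &
                     samples$time_to_diagnosis >= window$start_months &
                     samples$time_to_diagnosis < window$end_months, ,
                   drop = FALSE]
  if (nrow(cases) < n_cases) {
    abort(sprintf("window [%g, %g) holds %d eligible cases, %d requested",
                  window$start_months, window$end_months, nrow(cases), n_cases))
  }
  strata <- split(cases$sample_id, cases[[balance_var]])
  take <- allocate_balanced(lengths(strata), n_cases)
  chosen <- withr::with_seed(seed, {
    unlist(lapply(names(strata), function(s) {
      if (take[[s]] == 0) return(character())
      sample(strata[[s]], take[[s]])
    }), use.names = FALSE)
  })
  sel_cases <- cases[match(sort(chosen), cases$sample_id), ]
  pool <- samples[samples$group == "control", , drop = FALSE]
  m <- optimal_match(sel_cases, pool, spec)
  structure(list(
    window = window,
    case_ids = sel_cases$sample_id,
    control_ids = m$pairs$control_id,
    stage_composition = table(sel_cases$stage),
    histology_composition = table(sel_cases$histology),
    match = m
  ), class = "window_selection")
}

#' @export
print.window_selection <- function(x, ...) {
  cat(sprintf("<window_selection> [%g, %g) months: %d cases, %d controls\n",
              x$window$start_months, x$window$end_months,
              length(x$case_ids), length(x$control_ids)))
  invisible(x)
}
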