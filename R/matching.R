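#' Matching specification
#'
#' @param exact_vars Covariates on which matched controls must agree exactly
#'   with their case (column names of the sample table, e.g. `"sex"`).
#' @param ratio_k Controls per case (>= 1).
#' @param caliper_years Optional maximum case-control age difference; pairs
#'   beyond the caliper are inadmissible.
#' @return A list with class `"match_spec"`.
#' @export
match_spec <- function(exact_vars = c("sex", "bdg"), ratio_k = 5L,
                       caliper_years = NULL) {
  assert_scalar_number(ratio_k, "ratio_k", min = 1)
  if (!is.null(caliper_years)) {
    assert_scalar_number(caliper_years, "caliper_years", min = 1e-9)
  }
  structure(list(exact_vars = exact_vars, ratio_k = as.integer(ratio_k),
                 caliper_years = caliper_years), class = "match_spec")
}

new_match_result <- function(pairs, total_distance, balance) {
  structure(list(pairs = pairs, total_distance = total_distance,
                 balance = balance), class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d cases, %d controls, total age distance %.3f years\n",
              dplyr::n_distinct(x$pairs$case_id), nrow(x$pairs),
              x$total_distance))
  invisible(x)
}

#' @export
tidy.match_result <- function(x, ...) x$pairs

#' @export
glance.match_result <- function(x, ...) {
  tibble::tibble(
    n_cases = dplyr::n_distinct(x$pairs$case_id),
    n_controls = nrow(x$pairs),
    total_distance = x$total_distance,
    smd_age_before = x$balance$smd_before[x$balance$covariate == "age_at_donation"],
    smd_age_after = x$balance$smd_after[x$balance$covariate == "age_at_donation"]
  )
}

balance_report <- function(cases, pool, matched_controls) {
  tibble::tibble(
    covariate = "age_at_donation",
    smd_before = smd(cases$age_at_donation, pool$age_at_donation),
    smd_after = smd(cases$age_at_donation, matched_controls$age_at_donation)
  )
}

#' Frequency-match controls to cases within strata
#'
#' Cases are stratified by the cross-classification of `strata_vars` plus
#' age in 5-year bins; within each stratum, `ratio_k` controls per case are
#' sampled uniformly without replacement, so the case:control ratio is the
#' same for every stratum.
#'
#' @param cases,control_pool Sample tibbles (rows of a sample table).
#' @param strata_vars Stratifying covariates (default sex and blood donor
#'   group); age is always added, binned in 5-year bins.
#' @param ratio_k Controls per case.
#' @param seed Integer seed for the within-stratum sampling.
#' @return A `match_result`; `pairs` is a long tibble (`case_id`,
#'   `control_id`, `stratum`) in which controls of a stratum are allocated
#'   round-robin to its cases.
#' @export
frequency_match <- function(cases, control_pool, strata_vars = c("sex", "bdg"),
                            ratio_k = 5L, seed = 1L) {
  assert_scalar_number(ratio_k, "ratio_k", min = 1)
  stratum_of <- function(df) {
    lab <- do.call(paste, c(df[strata_vars], sep = "|"))
    paste(lab, 5 * floor(df$age_at_donation / 5), sep = "|age")
  }
  cs <- stratum_of(cases)
  ps <- stratum_of(control_pool)
  withr::with_seed(seed, {
    pairs <- dplyr::bind_rows(lapply(unique(cs), function(st) {
      case_ids <- cases$sample_id[cs == st]
      avail <- control_pool$sample_id[ps == st]
      need <- ratio_k * length(case_ids)
      if (length(avail) < need) {
        abort(sprintf(
          "deficient stratum '%s': need %d controls, only %d available (short %d)",
          st, need, length(avail), need - length(avail)))
      }
      chosen <- sample(avail, need)
      tibble::tibble(case_id = rep(case_ids, each = ratio_k),
                     control_id = chosen, stratum = st)
    }))
  })
  matched <- control_pool[match(pairs$control_id, control_pool$sample_id), ]
  dist <- sum(abs(cases$age_at_donation[match(pairs$case_id, cases$sample_id)] -
                    matched$age_at_donation))
  new_match_result(pairs, dist, balance_report(cases, control_pool, matched))
}

#' Optimal 1:k case-control matching on age
#'
#' Selects `ratio_k` controls per case minimising the total absolute age
#' difference, subject to exact agreement on `exact_vars` and an optional
#' age caliper. Each case is replicated `k` times and the problem is solved
#' exactly as a min-cost bipartite assignment (Hungarian algorithm); no
#' control is used twice. Ties are broken deterministically by lexicographic
#' (case_id, control_id) order.
#'
#' @param cases,control_pool Sample tibbles.
#' @param spec A [match_spec()].
#' @param seed Unused (the solution is deterministic); kept so callers can
#'   treat both matchers uniformly.
#' @return A `match_result` with the achieved minimum `total_distance`.
#' @examples
#' coh <- simulate_cohort(n_rnas = 12, margins = toy_margins(), seed = 2)
#' cases <- dplyr::filter(coh$samples, group == "case")[1:3, ]
#' pool <- dplyr::filter(coh$samples, group == "control")
#' m <- optimal_match(cases, pool, match_spec(exact_vars = "sex", ratio_k = 2))
#' m$total_distance
#' @export
optimal_match <- function(cases, control_pool, spec = match_spec(), seed = NULL) {
  k <- spec$ratio_k
  cases <- dplyr::arrange(tibble::as_tibble(cases), .data$sample_id)
  control_pool <- dplyr::arrange(tibble::as_tibble(control_pool), .data$sample_id)
  n_c <- nrow(cases)
  n_p <- nrow(control_pool)
  if (n_p < k * n_c) {
    abort(sprintf("infeasible matching: %d controls needed, %d in pool",
                  k * n_c, n_p))
  }
  cost <- abs(outer(cases$age_at_donation, control_pool$age_at_donation, "-"))
  admissible <- matrix(TRUE, n_c, n_p)
  for (v in spec$exact_vars) {
    admissible <- admissible & outer(cases[[v]], control_pool[[v]], "==")
  }
  if (!is.null(spec$caliper_years)) {
    admissible <- admissible & (cost <= spec$caliper_years)
  }
  if (any(rowSums(admissible) < k)) {
    short <- cases$sample_id[rowSums(admissible) < k][1]
    abort(sprintf("infeasible matching: case %s has fewer than %d admissible controls",
                  short, k))
  }
  big <- sum(cost[admissible]) + max(cost) * k * n_c + 1
  cost[!admissible] <- big
  rows <- rep(seq_len(n_c), each = k)   # case replicated k times
  sol <- clue::solve_LSAP(cost[rows, , drop = FALSE])
  picked <- as.integer(sol)
  used_cost <- cost[cbind(rows, picked)]
  if (any(used_cost >= big)) {
    abort("infeasible matching: no assignment satisfies the exact/caliper constraints")
  }
  pairs <- tibble::tibble(
    case_id = cases$sample_id[rows],
    control_id = control_pool$sample_id[picked],
    age_distance = used_cost
  )
  pairs <- dplyr::arrange(pairs, .data$case_id, .data$control_id)
  matched <- control_pool[match(pairs$control_id, control_pool$sample_id), ]
  case_rows <- cases[match(pairs$case_id, cases$sample_id), ]
  for (v in spec$exact_vars) {
    stopifnot(all(case_rows[[v]] == matched[[v]]))
  }
  new_match_result(pairs, sum(used_cost),
                   balance_report(cases, control_pool, matched))
}
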