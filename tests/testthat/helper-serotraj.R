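# shared fixtures and independent oracles, all built in code

.cache <- new.env(parent = emptyenv())

# small cohort reused across files (computed once per run)
cached_cohort <- function(name = "default", builder = NULL) {
  if (is.null(.cache[[name]])) {
    .cache[[name]] <- if (is.null(builder)) {
      simulate_cohort(n_rnas = 40,
                      margins = toy_margins(cases_per_cell = 10,
                                            n_controls = 120),
                      seed = 101)
    } else {
      builder()
    }
  }
  .cache[[name]]
}

# Exact min-cost assignment oracle: assign each of n rows (cases, possibly
# replicated) to a distinct column (control) minimising total cost, by
# dynamic programming over control subsets. Independent of the package's
# Hungarian-solver route.
brute_force_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m, m <= 14)
  f <- rep(Inf, 2^m)
  f[1] <- 0
  popcount <- vapply(0:(2^m - 1), function(x) sum(bitwAnd(x, 2^(0:(m - 1))) > 0), 0L)
  for (mask in 0:(2^m - 1)) {
    i <- popcount[mask + 1]
    if (i >= n || !is.finite(f[mask + 1])) next
    for (j in 0:(m - 1)) {
      if (bitwAnd(mask, bitwShiftL(1L, j)) == 0) {
        nm <- bitwOr(mask, bitwShiftL(1L, j))
        cand <- f[mask + 1] + cost[i + 1, j + 1]
        if (cand < f[nm + 1]) f[nm + 1] <- cand
      }
    }
  }
  min(f[popcount == n])
}

# Exact hypergeometric upper tail P(X >= ov) by direct enumeration
enum_hyper_tail <- function(ov, n_univ, n_path, n_sel) {
  xs <- ov:min(n_path, n_sel)
  if (ov <= max(0, n_sel - (n_univ - n_path))) return(1)
  sum(choose(n_path, xs) * choose(n_univ - n_path, n_sel - xs)) /
    choose(n_univ, n_sel)
}

# BH step-up computed literally from the formula
bh_by_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  padj_sorted <- vapply(seq_len(m), function(i) {
    min(1, min(m * p[o][i:m] / (i:m)))
  }, numeric(1))
  out <- numeric(m)
  out[o] <- padj_sorted
  out
}

# minimal hand-built sample tibble for matching tests
make_people <- function(ids, group, age, sex = "male", bdg = "BDg1",
                        smoking = "current") {
  n <- length(ids)
  tibble::tibble(
    sample_id = ids, subject_id = ids, group = group, sex = rep_len(sex, n),
    age_at_donation = age, bdg = rep_len(bdg, n),
    smoking = rep_len(smoking, n),
    stage = ifelse(group == "case", "advanced", "not_applicable"),
    histology = ifelse(group == "case", "NSCLC", "not_applicable"),
    time_to_diagnosis = ifelse(group == "case", 60, NA_real_)
  )
}

# two-group NB count matrix with known log2 fold change on the first
# `n_true` RNAs (no covariates) — independent of the cohort generator
sim_two_group <- function(n_rnas, n_per_group, lfc = 0, n_true = 0,
                          alpha = 0.2, seed = 1) {
  withr::with_seed(seed, {
    mu0 <- exp(runif(n_rnas, log(30), log(1000)))
    fc <- rep(1, n_rnas)
    if (n_true > 0) fc[seq_len(n_true)] <- 2^rep_len(lfc, n_true)
    y_ctrl <- t(sapply(mu0, function(m) rnbinom(n_per_group, mu = m, size = 1 / alpha)))
    y_case <- t(sapply(mu0 * fc, function(m) rnbinom(n_per_group, mu = m, size = 1 / alpha)))
    m <- cbind(y_case, y_ctrl)
    rownames(m) <- sprintf("r%04d", seq_len(n_rnas))
    colnames(m) <- c(sprintf("case%03d", seq_len(n_per_group)),
                     sprintf("ctrl%03d", seq_len(n_per_group)))
    m
  })
}

two_group_design <- function(n_per_group) {
  x <- cbind(intercept = 1,
             group_case = rep(c(1, 0), each = n_per_group))
  x
}
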