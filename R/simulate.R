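#' Gaussian effect-trajectory profile for one RNA
#'
#' A prediagnostic case effect is modelled as a Gaussian bump in log2
#' fold-change over time to diagnosis: the effect peaks at `center_months`
#' before diagnosis, has width (sigma) `width_months` and signed peak height
#' `amplitude_log2`, and applies only to case samples whose stage and
#' histology fall in the given subsets.
#'
#' @param rna_id RNA feature identifier the effect is attached to.
#' @param center_months Peak time in months before diagnosis, within the span.
#' @param width_months Gaussian sigma in months; must be positive.
#' @param amplitude_log2 Signed peak log2 fold change (case vs control).
#' @param stages Stage subset the effect applies to (default: all case stages).
#' @param histologies Histology subset (default: all case histologies).
#' @return A one-row tibble; rows can be bound into a profile table.
#' @examples
#' effect_profile("rna0001", center_months = 84, width_months = 9,
#'                amplitude_log2 = 2)
#' @export
effect_profile <- function(rna_id, center_months, width_months, amplitude_log2,
                           stages = stage_levels()[1:4],
                           histologies = histology_levels()[1:4]) {
  if (width_months <= 0) abort("`width_months` must be > 0")
  assert_scalar_number(center_months, "center_months", min = 0)
  check_enum(stages, stage_levels()[1:4], "stages")
  check_enum(histologies, histology_levels()[1:4], "histologies")
  tibble::tibble(
    rna_id = as.character(rna_id),
    center_months = as.numeric(center_months),
    width_months = as.numeric(width_months),
    amplitude_log2 = as.numeric(amplitude_log2),
    stages = list(stages),
    histologies = list(histologies)
  )
}

#' Evaluate an effect profile at a time before diagnosis
#'
#' Returns `amplitude_log2 * exp(-(t - center)^2 / (2 * width^2))`: the
#' log2 fold change a case sample donated `t` months before diagnosis
#' experiences under the profile.
#'
#' @param profile A one-row profile tibble from [effect_profile()].
#' @param t Months before diagnosis (vectorised, must be >= 0).
#' @return Numeric log2 fold change(s).
#' @examples
#' p <- effect_profile("r", 84, 9, 2)
#' effect_at_time(p, 84)   # 2, the peak
#' effect_at_time(p, 93)   # 2 * exp(-1/2)
#' @export
effect_at_time <- function(profile, t) {
  if (any(t < 0)) abort("`t` must be >= 0")
  if (any(profile$width_months <= 0)) abort("`width_months` must be > 0")
  profile$amplitude_log2 *
    exp(-(t - profile$center_months)^2 / (2 * profile$width_months^2))
}

#' Construct and validate cohort margins
#'
#' Margins fix the exact sample composition the generator must reproduce:
#' case counts per histology x stage cell, sex counts per stage, never-smoker
#' case counts per stage, the control count, control sex counts and the
#' number of smoker controls. [janus_margins()] supplies the published
#' full-scale values; [toy_margins()] builds small feasible margins for
#' examples and tests.
#'
#' @param cases Integer matrix, histology (`NSCLC`, `SCLC`, `other`) x stage
#'   (`early`, `locally_advanced`, `advanced`, `unknown`).
#' @param n_controls Number of control samples.
#' @param case_sex Sex x stage matrix summing per stage to `colSums(cases)`;
#'   default splits ~70/30 male/female.
#' @param case_never_smokers Per-stage counts of non-smoker cases (default 0).
#' @param control_sex Named male/female counts summing to `n_controls`.
#' @param n_control_smokers Controls that are current/former smokers.
#' @param age Age means/SDs per group; defaults to the Janus values.
#' @return A validated margins list.
#' @export
cohort_margins <- function(cases, n_controls, case_sex = NULL,
                           case_never_smokers = NULL, control_sex = NULL,
                           n_control_smokers = n_controls,
                           age = janus_margins()$age) {
  stages <- stage_levels()[1:4]
  cases <- as.matrix(cases)
  if (!all(dim(cases) == c(3L, 4L))) abort("`cases` must be a 3 x 4 histology-by-stage matrix")
  rownames(cases) <- c("NSCLC", "SCLC", "other")
  colnames(cases) <- stages
  totals <- colSums(cases)
  if (is.null(case_sex)) {
    male <- round(totals * 0.7)
    case_sex <- rbind(male = male, female = totals - male)
  }
  case_sex <- as.matrix(case_sex)
  colnames(case_sex) <- stages
  if (!all(colSums(case_sex) == totals)) {
    abort("infeasible margins: case_sex columns must sum to the stage totals of `cases`")
  }
  if (is.null(case_never_smokers)) case_never_smokers <- setNames(rep(0L, 4), stages)
  if (any(case_never_smokers > totals)) {
    abort("infeasible margins: more never-smoker cases than cases in a stage")
  }
  if (is.null(control_sex)) {
    control_sex <- c(male = ceiling(n_controls * 0.67),
                     female = n_controls - ceiling(n_controls * 0.67))
  }
  if (sum(control_sex) != n_controls) {
    abort("infeasible margins: control_sex must sum to n_controls")
  }
  if (n_control_smokers > n_controls) {
    abort("infeasible margins: more smoker controls than controls")
  }
  if (any(cases < 0) || n_controls < 0) abort("margins must be non-negative")
  list(cases = cases, case_sex = case_sex,
       case_never_smokers = setNames(as.integer(case_never_smokers), stages),
       n_controls = as.integer(n_controls),
       control_sex = control_sex, n_control_smokers = as.integer(n_control_smokers),
       age = age)
}

#' @rdname cohort_margins
#' @param cases_per_cell Case samples per histology x stage cell.
#' @export
toy_margins <- function(cases_per_cell = 4L, n_controls = 60L) {
  cohort_margins(
    cases = matrix(cases_per_cell, nrow = 3, ncol = 4),
    n_controls = n_controls,
    n_control_smokers = n_controls
  )
}

#' Simulate a prediagnostic serum RNA cohort with known ground truth
#'
#' Generates (i) a sample table whose stage, histology, sex and smoking
#' composition matches `margins` exactly, with ages drawn per group from the
#' margin means/SDs and case times to diagnosis uniform on the follow-up
#' span; (ii) a negative-binomial count matrix in which RNA `i` in sample
#' `j` has mean `s_j * 2^(log2 baseline_i + covariate shifts + case
#' effect)`, with per-RNA dispersion; and (iii) a truth record of everything
#' injected. Case effects follow the Gaussian profiles in `profiles` and
#' apply only to case samples in the profile's stage/histology subsets.
#'
#' RNA features are named `rna0001`, `rna0002`, ... with classes drawn from
#' the ten circulating RNA classes; baseline log2 means are long-tailed so a
#' minority of RNAs dominates reads, as in serum sequencing; dispersions are
#' log-uniform on `dispersion_range`; library size factors are log-normal;
#' blood-donor-group (batch), sex, age and smoking shifts are small per-RNA
#' log2 effects so confounder adjustment is testable.
#'
#' @param n_rnas Number of RNA features (>= 10).
#' @param margins Cohort margins, see [cohort_margins()]; defaults to the
#'   published full-scale composition ([janus_margins()]).
#' @param profiles Effect-profile tibble ([effect_profile()] rows), or NULL
#'   for a null cohort with no case effect.
#' @param seed Integer seed; identical inputs and seed give identical output.
#' @param cfg A [study_config()]; supplies the follow-up span.
#' @param n_bdg Number of blood-donor-group batch levels.
#' @param dispersion_range Range of the log-uniform per-RNA NB dispersion.
#' @param library_size_sigma SD of log library size factors.
#' @param covariate_sd SD of per-RNA log2 shifts for age (per SD), sex and
#'   smoking; BDg shifts are uniform on [-0.5, 0.5].
#' @param uniform_times If TRUE (default) case times to diagnosis are uniform
#'   on the span so every window is occupied; if FALSE they are drawn from
#'   per-stage normal distributions matching the published means (~5.5-5.9
#'   years), truncated to the span.
#' @return A list with elements `samples` (tibble), `counts` (count tibble as
#'   in [read_count_matrix()]), and `truth` (list: `profiles`, `params`
#'   per-RNA tibble, `size_factors` per-sample tibble).
#' @examples
#' coh <- simulate_cohort(n_rnas = 20, margins = toy_margins(), seed = 1)
#' dim(coh$counts)
#' table(coh$samples$group)
#' @export
simulate_cohort <- function(n_rnas, margins = janus_margins(), profiles = NULL,
                            seed = 1L, cfg = study_config(), n_bdg = 4L,
                            dispersion_range = c(0.05, 1),
                            library_size_sigma = 0.3, covariate_sd = 0.15,
                            uniform_times = TRUE) {
  if (n_rnas < 10) abort("`n_rnas` must be >= 10")
  if (!is.null(profiles)) {
    ids <- sprintf("rna%04d", seq_len(n_rnas))
    missing <- setdiff(profiles$rna_id, ids)
    if (length(missing)) {
      abort(paste0("profile rna_id(s) not in the simulated feature set: ",
                   paste(head(missing, 5), collapse = ", ")))
    }
  }
  withr::with_seed(seed, {
    samples <- simulate_samples(margins, cfg, n_bdg, uniform_times)
    sim_counts(samples, n_rnas, profiles, cfg, dispersion_range,
               library_size_sigma, covariate_sd)
  })
}

simulate_samples <- function(margins, cfg, n_bdg, uniform_times) {
  stages <- stage_levels()[1:4]
  rows <- list()
  for (s in stages) {
    for (h in rownames(margins$cases)) {
      n <- margins$cases[h, s]
      if (n > 0) {
        rows[[paste(s, h)]] <- tibble::tibble(
          group = "case", stage = s, histology = h, n = seq_len(n)
        )
      }
    }
  }
  cases <- dplyr::bind_rows(rows)
  cases$n <- NULL
  # exact sex margin per stage, randomly spread over histologies
  cases <- dplyr::bind_rows(lapply(stages, function(s) {
    cs <- cases[cases$stage == s, , drop = FALSE]
    if (nrow(cs) == 0) return(cs)
    sex <- c(rep("male", margins$case_sex["male", s]),
             rep("female", margins$case_sex["female", s]))
    cs$sex <- sample(sex)
    nev <- margins$case_never_smokers[[s]]
    smk <- c(rep("never", nev),
             sample(c("current", "former"), nrow(cs) - nev, replace = TRUE))
    cs$smoking <- sample(smk)
    mu <- margins$age$case["mean", s]; sdev <- margins$age$case["sd", s]
    cs$age_at_donation <- round(pmin(pmax(rnorm(nrow(cs), mu, sdev), 20), 95), 1)
    if (uniform_times) {
      cs$time_to_diagnosis <- round(runif(nrow(cs), 0, cfg$span_months), 1)
    } else {
      tt <- rnorm(nrow(cs), 5.7 * 12, 2.7 * 12)
      cs$time_to_diagnosis <- round(pmin(pmax(tt, 0), cfg$span_months), 1)
    }
    cs
  }))
  n_ctrl <- margins$n_controls
  ctrl <- tibble::tibble(
    group = "control", stage = "not_applicable", histology = "not_applicable",
    sex = sample(c(rep("male", margins$control_sex[["male"]]),
                   rep("female", margins$control_sex[["female"]]))),
    smoking = sample(c(
      sample(c("current", "former"), margins$n_control_smokers, replace = TRUE),
      rep("never", n_ctrl - margins$n_control_smokers)
    )),
    age_at_donation = round(pmin(pmax(
      rnorm(n_ctrl, margins$age$control[["mean"]], margins$age$control[["sd"]]),
      20), 95), 1),
    time_to_diagnosis = NA_real_
  )
  cases$sample_id <- sprintf("case%04d", seq_len(nrow(cases)))
  ctrl$sample_id <- sprintf("ctrl%04d", seq_len(nrow(ctrl)))
  samples <- dplyr::bind_rows(cases, ctrl)
  samples$bdg <- sample(sprintf("BDg%d", seq_len(n_bdg)), nrow(samples),
                        replace = TRUE)
  samples$subject_id <- assign_subjects(samples)
  validate_samples(samples[sample_table_cols()], span_months = cfg$span_months)
}

# Assign samples to subjects within stage x histology x sex cells so repeated
# donors exist (roughly 0.72 subjects per case sample, near 1 for controls)
# while sample-level margins stay exact.
assign_subjects <- function(samples) {
  frac <- ifelse(samples$group == "case", 391 / 542, 518 / 519)
  cell <- paste(samples$group, samples$stage, samples$histology, samples$sex)
  out <- character(nrow(samples))
  offset <- 0L
  for (cl in unique(cell)) {
    idx <- which(cell == cl)
    n_subj <- max(1L, round(length(idx) * frac[idx[1]]))
    out[idx] <- sprintf("subj%04d", offset + 1L +
                          (seq_along(idx) - 1L) %% n_subj)
    offset <- offset + n_subj
  }
  out
}

sim_counts <- function(samples, n_rnas, profiles, cfg, dispersion_range,
                       library_size_sigma, covariate_sd) {
  n_s <- nrow(samples)
  ids <- sprintf("rna%04d", seq_len(n_rnas))
  classes <- sample(rna_classes(), n_rnas, replace = TRUE,
                    prob = c(0.14, 0.04, 0.12, 0.16, 0.12,
                             0.14, 0.06, 0.05, 0.06, 0.11))
  # long-tailed abundances (a few RNAs dominate reads), capped so extreme
  # draws cannot overflow integer counts
  log2_baseline <- 3 + pmin(stats::rexp(n_rnas, rate = 1 / 2.5), 13)
  dispersion <- exp(runif(n_rnas, log(dispersion_range[1]),
                          log(dispersion_range[2])))
  size_factor <- exp(rnorm(n_s, 0, library_size_sigma))
  beta_age <- rnorm(n_rnas, 0, covariate_sd)
  beta_sex_male <- rnorm(n_rnas, 0, covariate_sd)
  beta_smoking_current <- rnorm(n_rnas, 0, covariate_sd)
  beta_smoking_never <- rnorm(n_rnas, 0, covariate_sd)
  bdg_levels <- sort(unique(samples$bdg))
  beta_bdg <- matrix(runif(n_rnas * length(bdg_levels), -0.5, 0.5),
                     nrow = n_rnas)
  beta_bdg[, 1] <- 0  # first batch is the reference level
  colnames(beta_bdg) <- bdg_levels

  age_z <- as.numeric(scale(samples$age_at_donation))
  covar_shift <- outer(beta_age, age_z) +
    outer(beta_sex_male, as.numeric(samples$sex == "male")) +
    outer(beta_smoking_current, as.numeric(samples$smoking == "current")) +
    outer(beta_smoking_never, as.numeric(samples$smoking == "never")) +
    beta_bdg[, match(samples$bdg, bdg_levels), drop = FALSE]

  effect <- matrix(0, n_rnas, n_s)
  if (!is.null(profiles) && nrow(profiles) > 0) {
    for (k in seq_len(nrow(profiles))) {
      p <- profiles[k, ]
      i <- match(p$rna_id, ids)
      hit <- samples$group == "case" &
        samples$stage %in% p$stages[[1]] &
        samples$histology %in% p$histologies[[1]]
      if (any(hit)) {
        effect[i, hit] <- effect[i, hit] +
          effect_at_time(p, samples$time_to_diagnosis[hit])
      }
    }
  }

  log2_mu <- sweep(covar_shift + effect, 1, log2_baseline, "+")
  mu <- sweep(2^log2_mu, 2, size_factor, "*")
  counts <- matrix(
    rnbinom(n_rnas * n_s, mu = as.numeric(mu),
            size = rep(1 / dispersion, times = n_s)),
    nrow = n_rnas
  )
  count_tbl <- tibble::tibble(rna_id = ids, rna_class = classes)
  count_tbl[samples$sample_id] <- lapply(seq_len(n_s),
                                         function(j) as.integer(counts[, j]))
  params <- tibble::tibble(
    rna_id = ids, rna_class = classes, log2_baseline = log2_baseline,
    dispersion = dispersion, beta_age = beta_age,
    beta_sex_male = beta_sex_male,
    beta_smoking_current = beta_smoking_current,
    beta_smoking_never = beta_smoking_never
  )
  for (b in bdg_levels) params[[paste0("beta_", b)]] <- beta_bdg[, b]
  truth <- list(
    profiles = if (is.null(profiles)) empty_profiles() else profiles,
    params = params,
    size_factors = tibble::tibble(sample_id = samples$sample_id,
                                  size_factor = size_factor)
  )
  list(samples = samples, counts = count_tbl, truth = truth)
}

empty_profiles <- function() {
  tibble::tibble(rna_id = character(), center_months = numeric(),
                 width_months = numeric(), amplitude_log2 = numeric(),
                 stages = list(), histologies = list())
}

#' Write a simulated cohort to a directory
#'
#' Emits `samples.tsv` and `counts.tsv` in the formats of
#' [read_sample_table()] / [read_count_matrix()], plus `truth.tsv` holding
#' the injected effect profiles (header only for a null cohort); stage and
#' histology subsets are comma-joined.
#'
#' @param cohort A list as returned by [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("cannot create directory: ", dir))
  }
  paths <- c(samples = file.path(dir, "samples.tsv"),
             counts = file.path(dir, "counts.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_sample_table(cohort$samples, paths[["samples"]])
  write_count_matrix(cohort$counts, paths[["counts"]])
  pr <- cohort$truth$profiles
  flat <- tibble::tibble(
    rna_id = pr$rna_id,
    center_months = pr$center_months,
    width_months = pr$width_months,
    amplitude_log2 = pr$amplitude_log2,
    stages = vapply(pr$stages, paste, "", collapse = ","),
    histologies = vapply(pr$histologies, paste, "", collapse = ",")
  )
  readr::write_tsv(dplyr::arrange(flat, .data$rna_id), paths[["truth"]],
                   progress = FALSE)
  invisible(paths)
}
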