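test_that("effect profiles evaluate to the Gaussian closed form", {
  p <- effect_profile("rna0001", center_months = 84, width_months = 9,
                      amplitude_log2 = 2)
  expect_equal(effect_at_time(p, 84), 2)
  expect_equal(effect_at_time(p, 93), 2 * exp(-1 / 2), tolerance = 1e-12)
  expect_equal(effect_at_time(p, 75), effect_at_time(p, 93))  # symmetry
  expect_lt(abs(effect_at_time(p, 0)), 1e-9)
  expect_error(effect_profile("r", 84, 0, 2), "width")
  expect_error(effect_at_time(p, -1), ">= 0")
})

test_that("full-scale margins are reproduced exactly", {
  coh <- simulate_cohort(n_rnas = 10, margins = janus_margins(), seed = 5)
  s <- coh$samples
  expect_equal(sum(s$group == "case"), 542)
  expect_equal(sum(s$group == "control"), 519)
  cases <- s[s$group == "case", ]
  expect_equal(as.integer(table(cases$stage)[stage_levels()[1:4]]),
               c(103L, 141L, 279L, 19L))
  byhist <- table(cases$histology, cases$stage)[c("NSCLC", "SCLC", "other"),
                                                stage_levels()[1:4]]
  expect_equal(unclass(byhist), unclass(janus_margins()$cases),
               ignore_attr = TRUE)
  bysex <- table(cases$sex, cases$stage)[c("male", "female"),
                                         stage_levels()[1:4]]
  expect_equal(unclass(bysex), unclass(janus_margins()$case_sex),
               ignore_attr = TRUE)
  # smoking exclusion arithmetic: 11 non-smoker cases -> 531 smoker cases,
  # 189 smoker controls
  expect_equal(sum(cases$smoking %in% c("current", "former")), 531)
  expect_equal(sum(s$group == "control" &
                     s$smoking %in% c("current", "former")), 189)
  # control ages near the published mean
  ctrl_age <- s$age_at_donation[s$group == "control"]
  expect_equal(mean(ctrl_age), 49.9, tolerance = 0.05)
  expect_true(all(cases$time_to_diagnosis >= 0 &
                    cases$time_to_diagnosis <= 120))
})

test_that("margins are exact for arbitrary feasible requests and any seed", {
  m <- cohort_margins(cases = matrix(c(2, 0, 1), 3, 4), n_controls = 17,
                      n_control_smokers = 9)
  for (seed in c(1, 99)) {
    coh <- simulate_cohort(n_rnas = 10, margins = m, seed = seed)
    cases <- coh$samples[coh$samples$group == "case", ]
    got <- table(factor(cases$histology, c("NSCLC", "SCLC", "other")),
                 factor(cases$stage, stage_levels()[1:4]))
    expect_equal(unclass(got), unclass(m$cases), ignore_attr = TRUE)
    expect_equal(sum(coh$samples$group == "control"), 17)
  }
  expect_error(cohort_margins(matrix(2, 3, 4), 10,
                              case_sex = rbind(male = rep(9, 4),
                                               female = rep(0, 4))),
               "infeasible")
})

test_that("generation is seed-deterministic", {
  a <- simulate_cohort(n_rnas = 15, margins = toy_margins(2, 20), seed = 42)
  b <- simulate_cohort(n_rnas = 15, margins = toy_margins(2, 20), seed = 42)
  c <- simulate_cohort(n_rnas = 15, margins = toy_margins(2, 20), seed = 43)
  expect_identical(a$samples, b$samples)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth$params, b$truth$params)
  expect_false(identical(a$counts, c$counts))
})

test_that("a null cohort carries no effect profiles and zero-amplitude \
profiles leave the counts untouched", {
  null <- simulate_cohort(n_rnas = 20, margins = toy_margins(), seed = 8)
  expect_equal(nrow(null$truth$profiles), 0)

  # an amplitude-0 profile injects nothing and consumes no random draws, so
  # the counts are bit-identical to the null cohort at the same seed
  prof <- dplyr::bind_rows(lapply(sprintf("rna%04d", 1:6), function(id) {
    effect_profile(id, 60, 10, amplitude_log2 = 0)
  }))
  a <- simulate_cohort(n_rnas = 20, margins = toy_margins(), profiles = prof,
                       seed = 21)
  b <- simulate_cohort(n_rnas = 20, margins = toy_margins(), seed = 21)
  expect_identical(a$counts, b$counts)
  expect_identical(a$samples, b$samples)
  expect_equal(nrow(a$truth$profiles), 6)
})

test_that("per-RNA means converge to the injected baselines as dispersion \
vanishes", {
  m <- cohort_margins(cases = matrix(100, 3, 4), n_controls = 800,
                      n_control_smokers = 800)
  coh <- simulate_cohort(n_rnas = 10, margins = m, seed = 31, n_bdg = 1,
                         dispersion_range = c(1e-8, 1e-8), covariate_sd = 0)
  cnt <- serotraj:::count_mat(coh$counts, coh$samples$sample_id)
  sf <- coh$truth$size_factors$size_factor[
    match(colnames(cnt), coh$truth$size_factors$sample_id)]
  est <- rowMeans(sweep(cnt, 2, sf, "/"))
  rel_err <- abs(est - 2^coh$truth$params$log2_baseline) /
    2^coh$truth$params$log2_baseline
  expect_lt(max(rel_err), 0.05)
})

test_that("cohorts write to three files and read back identically", {
  coh <- simulate_cohort(n_rnas = 10, margins = toy_margins(2, 20), seed = 3)
  dir <- withr::local_tempdir()
  paths <- write_cohort(coh, dir)
  expect_length(paths, 3)
  expect_true(all(file.exists(paths)))
  counts_back <- read_count_matrix(paths[["counts"]])
  expect_equal(ncol(counts_back) - 2L, nrow(coh$samples))  # one col per sample
  expect_identical(counts_back, dplyr::arrange(coh$counts, rna_id))
  samples_back <- read_sample_table(paths[["samples"]])
  expect_identical(samples_back,
                   dplyr::arrange(coh$samples[names(samples_back)], sample_id))
  # null cohort -> header-only truth table
  truth <- readr::read_tsv(paths[["truth"]], show_col_types = FALSE)
  expect_equal(nrow(truth), 0)

  prof <- effect_profile("rna0001", 84, 9, 1.5)
  coh2 <- simulate_cohort(n_rnas = 10, margins = toy_margins(2, 20),
                          profiles = prof, seed = 3)
  write_cohort(coh2, dir)
  truth2 <- readr::read_tsv(file.path(dir, "truth.tsv"), show_col_types = FALSE)
  expect_equal(truth2$rna_id, "rna0001")
  expect_equal(truth2$center_months, 84)
})

test_that("profiles must reference simulated RNA features", {
  prof <- effect_profile("rna9999", 84, 9, 1.5)
  expect_error(
    simulate_cohort(n_rnas = 10, margins = toy_margins(2, 20),
                    profiles = prof, seed = 1),
    "not in the simulated feature set")
  expect_error(simulate_cohort(n_rnas = 5, margins = toy_margins(2, 20)),
               ">= 10")
})
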