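fake_summary <- function(label, center, de) {
  tibble::tibble(
    label = label, start_months = center - 8.5, end_months = center + 8.5,
    center_months = center, n_cases = 9L, n_controls = 45L,
    n_tested = 40L, n_de = nrow(de), skipped = FALSE, reason = NA_character_,
    de = list(de)
  )
}

de_rows <- function(ids, classes, lfc = 1) {
  tibble::tibble(rna_id = ids, rna_class = classes,
                 log2fc = rep_len(lfc, length(ids)),
                 padj = 0.01)
}

test_that("trajectories tabulate class counts that sum to the total", {
  s <- dplyr::bind_rows(
    fake_summary("w1", 10, de_rows(c("a", "b", "c"),
                                   c("piRNA", "piRNA", "tRF"))),
    fake_summary("w2", 30, de_rows(character(), character()))
  )
  traj <- build_trajectory(s)
  expect_equal(traj$total, c(3, 0))
  expect_equal(traj$piRNA, c(2, 0))
  expect_equal(traj$tRF, c(1, 0))
  expect_equal(rowSums(traj[rna_classes()]), traj$total)
  # order invariance
  traj2 <- build_trajectory(s[2:1, ])
  expect_identical(tibble::as_tibble(traj), tibble::as_tibble(traj2))
})

test_that("peak detection finds separated local maxima and nothing in flat \
series", {
  flat <- dplyr::bind_rows(lapply(seq(10, 110, by = 10), function(ct) {
    fake_summary(paste0("w", ct), ct, de_rows(character(), character()))
  }))
  expect_length(detect_peaks(build_trajectory(flat)), 0)

  heights <- c(0, 2, 8, 3, 0, 1, 9, 4, 1)
  centers <- seq(20, 100, by = 10)
  s <- dplyr::bind_rows(lapply(seq_along(centers), function(i) {
    n <- heights[i]
    fake_summary(paste0("w", i), centers[i],
                 de_rows(sprintf("r%d_%d", i, seq_len(n)),
                         rep("miRNA", n)))
  }))
  traj <- build_trajectory(s)
  pk <- detect_peaks(traj, min_height = 1, min_separation_months = 20)
  expect_equal(pk, c(80, 40))     # two bumps 40 months apart, tallest first
  expect_equal(detect_peaks(traj, min_height = 1,
                            min_separation_months = 60), 80)
  expect_error(detect_peaks(build_trajectory(s[1:2, ])), "at least 3")
})

test_that("recurrent RNAs are reported with windows and directions", {
  s <- dplyr::bind_rows(
    fake_summary("w1", 10, de_rows(c("a", "b"), c("tRF", "piRNA"), lfc = -2)),
    fake_summary("w2", 30, de_rows("c", "mRNA")),
    fake_summary("w4", 70, de_rows(c("a", "c"), c("tRF", "mRNA")))
  )
  rec <- recurrent_rnas(s, min_windows = 2)
  expect_equal(sort(rec$rna_id), c("a", "c"))
  a <- rec[rec$rna_id == "a", ]
  expect_equal(a$windows[[1]], c("w1", "w4"))
  expect_equal(a$signs[[1]], c(-1, 1))
  expect_equal(nrow(recurrent_rnas(s, min_windows = 1)), 3)
  expect_equal(nrow(recurrent_rnas(s, min_windows = 5)), 0)
})

test_that("phases produce the expected window counts and determinism", {
  coh <- cached_cohort("pipeline", function() {
    simulate_cohort(n_rnas = 12,
                    margins = cohort_margins(matrix(12, 3, 4), 90,
                                             n_control_smokers = 90),
                    seed = 77)
  })
  cfg <- study_config(sliding_step_months = 10)
  p1 <- run_phase(coh$samples, coh$counts, phase = 1, cfg = cfg, seed = 1)
  expect_equal(nrow(p1), 1)
  expect_equal(p1$n_cases, 144)   # phase 1 keeps non-smokers

  p2 <- run_phase(coh$samples, coh$counts, phase = 2, cfg = cfg,
                  n_cases = 5, ratio_k = 3, seed = 1)
  expect_equal(nrow(p2), 7)
  expect_true(all(p2$n_cases[!p2$skipped] == 5))
  expect_true(all(p2$n_controls[!p2$skipped] == 15))
  p2b <- run_phase(coh$samples, coh$counts, phase = 2, cfg = cfg,
                   n_cases = 5, ratio_k = 3, seed = 1)
  expect_identical(tibble::as_tibble(p2), tibble::as_tibble(p2b))

  p4 <- run_phase(coh$samples, coh$counts, phase = 4, cfg = cfg,
                  n_cases = 5, ratio_k = 3, seed = 1)
  expect_equal(nrow(p4), nrow(make_sliding_windows(17, 10, 120)))

  expect_error(run_phase(coh$samples, coh$counts, phase = 3, cfg = cfg),
               "stage_filter")
  expect_error(run_phase(coh$samples, coh$counts, phase = 7), "1, 2, 3 or 4")
})

test_that("the default sliding design yields 42 windows", {
  expect_equal(nrow(make_sliding_windows(
    study_config()$sliding_width_months,
    study_config()$sliding_step_months,
    study_config()$span_months)), 42)
})

test_that("windows that cannot fill their quota are skipped, not fatal", {
  coh <- cached_cohort("pipeline")
  # demand more cases than any window can hold
  p2 <- run_phase(coh$samples, coh$counts, phase = 2, n_cases = 100,
                  ratio_k = 2, seed = 1)
  expect_true(all(p2$skipped))
  expect_match(p2$reason[1], "eligible cases")
})

test_that("bootstrap summarises signal dispersion per window", {
  coh <- cached_cohort("boot", function() {
    simulate_cohort(n_rnas = 12,
                    margins = cohort_margins(matrix(30, 3, 4), 150,
                                             n_control_smokers = 150),
                    seed = 77)
  })
  cfg <- study_config(n_bootstrap = 2,
                      phase3_cases = c(early = 4, locally_advanced = 4,
                                       advanced = 4))
  b <- bootstrap_phase3(coh$samples, coh$counts, stage = "advanced",
                        cfg = cfg, seed = 5, ratio_k = 3)
  expect_equal(nrow(b), 7)
  expect_true(all(b$n_iter == 2))
  expect_true(all(b$min_n_de <= b$max_n_de))
  b1 <- bootstrap_phase3(coh$samples, coh$counts, stage = "advanced",
                         cfg = cfg, seed = 5, n_iter = 1, ratio_k = 3)
  expect_true(all(is.na(b1$sd_n_de)))
  expect_equal(b1$mean_n_de, as.numeric(b1$min_n_de))
})

test_that("a strong localized bump separates its window from all others \
across bootstrap iterations", {
  margins <- cohort_margins(matrix(35, 3, 4), 250, n_control_smokers = 250)
  prof <- dplyr::bind_rows(lapply(sprintf("rna%04d", 1:12), function(id) {
    effect_profile(id, center_months = 60, width_months = 6,
                   amplitude_log2 = 2)
  }))
  coh <- simulate_cohort(n_rnas = 40, margins = margins, profiles = prof,
                         seed = 303)
  cfg <- study_config(n_bootstrap = 3,
                      phase3_cases = c(early = 9, locally_advanced = 9,
                                       advanced = 9))
  b <- bootstrap_phase3(coh$samples, coh$counts, stage = "advanced",
                        cfg = cfg, seed = 11, ratio_k = 5)
  bump <- which(b$center_months > 51 & b$center_months < 69)
  expect_length(bump, 1)
  expect_gt(b$min_n_de[bump], max(b$max_n_de[-bump]))
})
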