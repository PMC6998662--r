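test_that("size factors follow the median-of-ratios closed form", {
  m <- rbind(c(2, 4), c(8, 16), c(5, 10))
  colnames(m) <- c("s1", "s2")
  expect_equal(unname(size_factors(m)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)
  m2 <- cbind(a = c(3, 9, 27), b = c(3, 9, 27), c = c(3, 9, 27))
  expect_equal(unname(size_factors(m2)), c(1, 1, 1))
  # permutation equivariance
  coh <- cached_cohort()
  cm <- serotraj:::count_mat(coh$counts)
  sf <- size_factors(cm)
  perm <- rev(seq_len(ncol(cm)))
  expect_equal(size_factors(cm[, perm]), sf[perm])
  # no RNA positive everywhere -> no reference
  bad <- rbind(c(0, 5), c(5, 0))
  colnames(bad) <- c("s1", "s2")
  expect_error(size_factors(bad), "reference")
})

test_that("dispersion estimation recovers known truth", {
  withr::with_seed(5, {
    n <- 100
    mu <- exp(runif(300, log(20), log(2000)))
    nb <- t(sapply(mu, function(m) rnbinom(n, mu = m, size = 1 / 0.5)))
    po <- t(sapply(mu, function(m) rpois(n, m)))
  })
  dimnames(nb) <- dimnames(po) <-
    list(sprintf("r%03d", 1:300), sprintf("s%03d", 1:100))
  d_nb <- estimate_dispersions(nb, rep(1, 100))
  d_po <- estimate_dispersions(po, rep(1, 100))
  expect_gt(median(d_nb), 0.3)
  expect_lt(median(d_nb), 0.8)
  expect_lte(median(d_po), 0.01)
  # constant counts sit at the floor
  const <- matrix(7, 3, 10, dimnames = list(paste0("r", 1:3), paste0("s", 1:10)))
  expect_equal(unname(estimate_dispersions(const, rep(1, 10))), rep(1e-8, 3))
})

test_that("the Wald estimator is consistent for an injected fold change", {
  # effects are sign-balanced on a minority of RNAs so the median-of-ratios
  # reference stays anchored to the unchanged majority
  n <- 150
  m <- sim_two_group(100, n, lfc = c(1, -1), n_true = 20, alpha = 0.2,
                     seed = 9)
  design <- two_group_design(n)
  sf <- size_factors(m)
  disp <- estimate_dispersions(m, sf)
  res <- wald_test(m, design, sf, disp)
  expect_true(all(res$converged))
  up <- seq(1, 19, by = 2)
  expect_equal(mean(res$log2fc[up]), 1, tolerance = 0.1)
  expect_equal(mean(res$log2fc[up + 1]), -1, tolerance = 0.1)
  expect_equal(mean(res$log2fc[21:100]), 0, tolerance = 0.05)
  expect_true(all(res$padj >= res$pvalue, na.rm = TRUE))
})

test_that("p-values are uniform under a permutation null", {
  n <- 60
  m <- sim_two_group(200, n, seed = 13)
  # shuffle group labels so case/control have identical distributions
  perm <- withr::with_seed(14, sample(2 * n))
  design <- two_group_design(n)
  m <- m[, perm]
  sf <- size_factors(m)
  res <- wald_test(m, design, sf, estimate_dispersions(m, sf))
  expect_gt(stats::ks.test(res$pvalue, "punif")$p.value, 0.01)
})

test_that("all-zero RNAs are flagged, never fatal", {
  n <- 20
  m <- sim_two_group(10, n, seed = 3)
  m[1, ] <- 0
  design <- two_group_design(n)
  sf <- size_factors(m)
  res <- wald_test(m, design, sf, estimate_dispersions(m, sf))
  expect_false(res$converged[1])
  expect_true(is.na(res$pvalue[1]))
  expect_true(all(res$converged[-1]))
})

test_that("BH adjustment matches the step-up formula", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  expect_equal(adjust_bh(0.37), 0.37)
  expect_equal(adjust_bh(rep(1, 4)), rep(1, 4))
  withr::with_seed(21, {
    for (i in 1:10) {
      p <- runif(sample(3:40, 1))^sample(1:3, 1)
      expect_equal(adjust_bh(p), bh_by_hand(p), tolerance = 1e-12)
    }
  })
  # monotone: sorting by p sorts padj non-decreasingly
  p <- withr::with_seed(3, runif(50))
  padj <- adjust_bh(p)
  expect_true(!is.unsorted(padj[order(p)]))
  # NaN excluded with m reduced
  expect_warning(got <- adjust_bh(c(0.01, NaN, 0.03)), "NaN")
  expect_equal(got, c(0.02, NA, 0.03))
  expect_error(adjust_bh(c(0.5, 2)), "\\[0, 1\\]")
})

test_that("Wald ranking agrees with a profile-likelihood-ratio ranking", {
  n <- 20  # 50 RNAs x 40 samples
  m <- sim_two_group(50, n, lfc = 0.8, n_true = 15, alpha = 0.3, seed = 17)
  design <- two_group_design(n)
  sf <- size_factors(m)
  disp <- estimate_dispersions(m, sf)
  res <- wald_test(m, design, sf, disp)
  # oracle: deviance difference between full and group-free NB fits
  lrt <- vapply(seq_len(nrow(m)), function(i) {
    fam <- MASS::negative.binomial(theta = 1 / max(disp[i], 1e-8))
    full <- stats::glm.fit(design, m[i, ], offset = log(sf), family = fam)
    red <- stats::glm.fit(design[, 1, drop = FALSE], m[i, ],
                          offset = log(sf), family = fam)
    red$deviance - full$deviance
  }, numeric(1))
  expect_gt(stats::cor(abs(res$wald), lrt, method = "spearman"), 0.95)
})

test_that("log2 fold changes are stable under rescaling one sample's depth", {
  coh <- cached_cohort()
  m <- serotraj:::count_mat(coh$counts)
  design <- design_matrix(coh$samples)
  sf1 <- size_factors(m)
  disp <- estimate_dispersions(m, sf1, design)
  r1 <- wald_test(m, design, sf1, disp)
  m2 <- m
  m2[, 5] <- m2[, 5] * 2
  r2 <- wald_test(m2, design, size_factors(m2), disp)
  expect_lt(max(abs(r1$log2fc - r2$log2fc), na.rm = TRUE), 0.02)
})

test_that("injected signals at window sample sizes are detected with \
sensitivity above one half", {
  margins <- cohort_margins(cases = matrix(3, 3, 4), n_controls = 140,
                            n_control_smokers = 140)
  sens <- vapply(1:3, function(s) {
    prof <- dplyr::bind_rows(lapply(sprintf("rna%04d", 1:15), function(id) {
      effect_profile(id, center_months = 60, width_months = 1e6,
                     amplitude_log2 = 1.5)
    }))
    coh <- simulate_cohort(n_rnas = 150, margins = margins, profiles = prof,
                           seed = s)
    sub <- dplyr::bind_rows(
      dplyr::filter(coh$samples, group == "case")[1:27, ],
      dplyr::filter(coh$samples, group == "control")[1:135, ])
    de <- run_de(coh$counts, sub)
    mean(de$padj[de$rna_id %in% sprintf("rna%04d", 1:15)] < 0.05, na.rm = TRUE)
  }, numeric(1))
  expect_gte(median(sens), 0.5)
})

test_that("the design matrix encodes covariates and drops constants", {
  coh <- cached_cohort()
  x <- design_matrix(coh$samples)
  expect_true(all(c("intercept", "group_case", "age_z", "sex_male") %in%
                    colnames(x)))
  expect_equal(qr(x)$rank, ncol(x))
  one_group <- dplyr::filter(coh$samples, group == "case")
  expect_error(design_matrix(one_group), "cases and controls")
  tiny <- coh$samples[c(1, 2, nrow(coh$samples)), ]
  expect_error(design_matrix(tiny), "degrees of freedom")
})

test_that("size factors agree with the reference bioinformatics implementation", {
  skip_if_not_installed("DESeq2")
  coh <- cached_cohort()
  m <- serotraj:::count_mat(coh$counts)
  ours <- size_factors(m)
  theirs <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-8)
})
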