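#' Design matrix for covariate-adjusted differential expression
#'
#' Builds the regression design: intercept, case indicator (`group_case`),
#' standardized age, male indicator, smoking indicators (reference: former
#' smoker) and blood-donor-group indicators (reference: first BDg label
#' alphabetically). Covariates that do not vary among the supplied samples
#' are dropped so the matrix stays full column rank.
#'
#' @param samples Sample tibble for the analysed samples.
#' @return Numeric matrix, one row per sample (named by `sample_id`).
#' @export
design_matrix <- function(samples) {
  n <- nrow(samples)
  if (length(unique(samples$group)) < 2) {
    abort("design requires both cases and controls")
  }
  age_z <- as.numeric(scale(samples$age_at_donation))
  if (anyNA(age_z)) age_z <- rep(0, n)  # constant age
  cols <- list(
    intercept = rep(1, n),
    group_case = as.numeric(samples$group == "case"),
    age_z = age_z,
    sex_male = as.numeric(samples$sex == "male")
  )
  for (lev in c("current", "never", "unknown")) {
    cols[[paste0("smoking_", lev)]] <- as.numeric(samples$smoking == lev)
  }
  bdg_levels <- sort(unique(samples$bdg))
  for (lev in bdg_levels[-1]) {
    cols[[paste0("bdg_", lev)]] <- as.numeric(samples$bdg == lev)
  }
  x <- do.call(cbind, cols)
  rownames(x) <- samples$sample_id
  keep <- c(TRUE, vapply(seq_len(ncol(x))[-1],
                         function(j) var(x[, j]) > 0, logical(1)))
  x <- x[, keep, drop = FALSE]
  if (nrow(x) - ncol(x) < 2) abort("fewer than 2 residual degrees of freedom")
  if (qr(x)$rank < ncol(x)) {
    abort("design matrix is rank deficient (aliased covariates)")
  }
  x
}

#' Median-of-ratios size factors
#'
#' The per-sample normalisation constant `s_j` is the median over RNAs
#' (restricted to RNAs with a positive geometric mean across samples) of
#' `count_ij / geomean_i`. No rescaling is applied afterwards.
#'
#' @param counts Count tibble ([read_count_matrix()] layout) or numeric
#'   matrix (RNA x sample).
#' @return Named positive numeric vector, one entry per sample.
#' @examples
#' m <- rbind(c(2, 4), c(8, 16), c(1, 2))
#' colnames(m) <- c("a", "b")
#' size_factors(m)  # (1/sqrt(2), sqrt(2))
#' @export
size_factors <- function(counts) {
  m <- if (is.matrix(counts)) counts else count_mat(counts)
  log_geo <- rowMeans(log(m))
  use <- is.finite(log_geo)
  if (!any(use)) abort("no RNA has positive counts in every sample; cannot form the reference")
  sf <- apply(m[use, , drop = FALSE], 2, function(col) {
    r <- log(col) - log_geo[use]
    r <- r[is.finite(r)]
    if (!length(r)) abort("a sample shares no positive RNA with the reference")
    exp(median(r))
  })
  sf
}

#' Method-of-moments dispersion estimates with trend shrinkage
#'
#' For each RNA the raw negative-binomial dispersion is estimated from
#' normalized counts as `max(floor, (s^2 - mean) / mean^2)`; estimates above
#' the floor are then shrunk 50/50 in log space toward a fitted
#' mean-dispersion trend `a0/mean + a1`. Estimates at the floor (e.g.
#' constant or underdispersed counts) stay at the floor (`1e-8`).
#'
#' @inheritParams size_factors
#' @param sf Size factors from [size_factors()].
#' @param design Design matrix (used for the residual-df precondition).
#' @return Named per-RNA dispersion vector (> 0).
#' @export
estimate_dispersions <- function(counts, sf, design = NULL) {
  m <- if (is.matrix(counts)) counts else count_mat(counts)
  if (!is.null(design) && nrow(design) - ncol(design) < 2) {
    abort("fewer than 2 residual degrees of freedom")
  }
  floor_a <- 1e-8
  norm <- sweep(m, 2, sf, "/")
  mu <- rowMeans(norm)
  v <- apply(norm, 1, var)
  raw <- (v - mu) / mu^2
  raw[!is.finite(raw) | raw < floor_a] <- floor_a
  est <- raw
  fit_idx <- which(raw > floor_a & mu > 0)
  if (length(fit_idx) >= 5) {
    co <- coef(lm(raw[fit_idx] ~ I(1 / mu[fit_idx])))
    a1 <- max(co[1], 0); a0 <- max(co[2], 0)
    if (a0 > 0 || a1 > 0) {
      trend <- pmax(a0 / mu + a1, floor_a)
      est[fit_idx] <- exp((log(raw[fit_idx]) + log(trend[fit_idx])) / 2)
    }
  }
  setNames(pmax(est, floor_a), rownames(m))
}

# single-RNA NB log-link fit with fixed dispersion and log size-factor offset
nb_fit_one <- function(y, design, sf, alpha) {
  theta <- 1 / max(alpha, 1e-8)
  fit <- suppressWarnings(tryCatch(
    stats::glm.fit(x = design, y = y, offset = log(sf),
                   family = MASS::negative.binomial(theta = theta),
                   control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    error = function(e) NULL))
  if (is.null(fit) || !isTRUE(fit$converged) || anyNA(fit$coefficients)) {
    return(NULL)
  }
  r_mat <- qr.R(fit$qr)
  piv <- fit$qr$pivot
  cov <- matrix(NA_real_, ncol(design), ncol(design))
  cov[piv, piv] <- tryCatch(chol2inv(r_mat), error = function(e) NA_real_)
  se <- sqrt(diag(cov))
  if (anyNA(se)) return(NULL)
  list(coef = fit$coefficients, se = se, deviance = fit$deviance)
}

#' Per-RNA negative-binomial Wald test
#'
#' Fits, for each RNA, a negative-binomial log-link regression of counts on
#' the design with the RNA's dispersion held fixed and `log(s_j)` offsets
#' (iteratively reweighted least squares to relative tolerance 1e-8, at most
#' 100 iterations). The case-vs-control coefficient is reported in log2
#' units with its standard error from the unscaled information matrix; the
#' Wald p-value uses the standard normal reference, and Benjamini-Hochberg
#' adjustment is applied across the RNAs with a defined p-value.
#' Non-converging or all-zero RNAs are flagged (`converged = FALSE`,
#' missing p) rather than failing the run.
#'
#' @inheritParams estimate_dispersions
#' @param design Design matrix from [design_matrix()]; columns must include
#'   `group_case`.
#' @param dispersions Per-RNA dispersions from [estimate_dispersions()].
#' @return A tibble (class `de_results`): `rna_id`, `rna_class`,
#'   `base_mean`, `log2fc`, `se`, `wald`, `pvalue`, `padj`, `converged`.
#' @export
wald_test <- function(counts, design, sf, dispersions) {
  m <- if (is.matrix(counts)) counts else count_mat(counts)
  classes <- if (is.matrix(counts)) rep(NA_character_, nrow(m)) else counts$rna_class
  if (!"group_case" %in% colnames(design)) {
    abort("design must contain a `group_case` column")
  }
  g <- which(colnames(design) == "group_case")
  norm <- sweep(m, 2, sf, "/")
  ln2 <- log(2)
  res <- lapply(seq_len(nrow(m)), function(i) {
    y <- m[i, ]
    if (all(y == 0)) return(list(NA_real_, NA_real_, NA_real_, FALSE))
    fit <- nb_fit_one(y, design, sf, dispersions[i])
    if (is.null(fit)) return(list(NA_real_, NA_real_, NA_real_, FALSE))
    list(fit$coef[g] / ln2, fit$se[g] / ln2, fit$coef[g] / fit$se[g], TRUE)
  })
  out <- tibble::tibble(
    rna_id = rownames(m),
    rna_class = classes,
    base_mean = rowMeans(norm),
    log2fc = vapply(res, `[[`, 0, 1),
    se = vapply(res, `[[`, 0, 2),
    wald = vapply(res, `[[`, 0, 3),
    converged = vapply(res, `[[`, TRUE, 4)
  )
  out$pvalue <- 2 * pnorm(-abs(out$wald))
  out$padj <- adjust_bh(out$pvalue)
  class(out) <- c("de_results", class(out))
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment. Missing or NaN p-values are excluded (with a
#' warning for NaN) and the number of tests `m` is reduced accordingly;
#' their adjusted value is returned as `NA`.
#'
#' @param p Numeric p-values in `[0, 1]` (NA/NaN allowed).
#' @return Adjusted p-values, same length and order as `p`.
#' @examples
#' adjust_bh(c(0.01, 0.02, 0.03, 0.04, 0.05))  # all 0.05
#' @export
adjust_bh <- function(p) {
  if (any(is.nan(p))) {
    warn("NaN p-value(s) excluded from BH adjustment")
    p[is.nan(p)] <- NA_real_
  }
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) abort("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' Differential expression for one set of samples
#'
#' Convenience wrapper chaining the engine: subset the count matrix to the
#' given samples, estimate size factors and dispersions, build the
#' covariate-adjusted design and run the Wald test.
#'
#' @param counts Count tibble covering at least the given samples.
#' @param samples Sample tibble of the analysed cases and controls.
#' @return A `de_results` tibble.
#' @export
run_de <- function(counts, samples) {
  m <- count_mat(counts, samples$sample_id)
  keep <- rowSums(m) > 0
  m <- m[keep, , drop = FALSE]
  classes <- counts$rna_class[keep]
  design <- design_matrix(samples)
  sf <- size_factors(m)
  disp <- estimate_dispersions(m, sf, design)
  sub <- counts[keep, c("rna_id", "rna_class"), drop = FALSE]
  res <- wald_test(m, design, sf, disp)
  res$rna_class <- classes
  res
}

#' @export
glance.de_results <- function(x, alpha = 0.05, ...) {
  tibble::tibble(
    n_tested = sum(!is.na(x$pvalue)),
    n_significant = sum(x$padj < alpha, na.rm = TRUE),
    max_abs_log2fc = ifelse(any(x$padj < alpha, na.rm = TRUE),
                            max(abs(x$log2fc[!is.na(x$padj) & x$padj < alpha])),
                            NA_real_),
    n_flagged = sum(!x$converged)
  )
}

#' @export
tidy.de_results <- function(x, ...) {
  tibble::as_tibble(x)
}
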