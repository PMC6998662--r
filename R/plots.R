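#' Plot an RNA-class signal trajectory
#'
#' Stacked per-class counts of significant RNAs against window center time
#' (months before diagnosis, diagnosis at the left). Set `smooth_bandwidth`
#' to a positive number of months for a kernel-smoothed rendering of the
#' stacked densities; smoothing affects plotting only, never peak
#' detection.
#'
#' @param object A trajectory from [build_trajectory()].
#' @param smooth_bandwidth Optional Gaussian kernel bandwidth (months).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.serotraj_trajectory <- function(object, smooth_bandwidth = NULL, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("center_months", rna_classes())],
    cols = -"center_months", names_to = "rna_class", values_to = "n_de")
  long <- long[long$n_de > 0 | TRUE, ]
  if (!is.null(smooth_bandwidth)) {
    long <- long |>
      dplyr::group_by(.data$rna_class) |>
      dplyr::mutate(n_de = kernel_smooth(.data$center_months, .data$n_de,
                                         smooth_bandwidth)) |>
      dplyr::ungroup()
  }
  ggplot2::ggplot(long, ggplot2::aes(x = .data$center_months / 12,
                                     y = .data$n_de,
                                     fill = .data$rna_class)) +
    ggplot2::geom_area(position = "stack") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "Years before diagnosis",
                  y = "Differentially expressed RNAs",
                  fill = "RNA class") +
    ggplot2::theme_minimal()
}

kernel_smooth <- function(x, y, bw) {
  vapply(x, function(x0) {
    w <- exp(-(x - x0)^2 / (2 * bw^2))
    sum(w * y) / sum(w)
  }, numeric(1))
}

#' @rdname autoplot.serotraj_trajectory
#' @param x A trajectory.
#' @export
plot.serotraj_trajectory <- function(x, ...) print(autoplot(x, ...))

#' Volcano plot of one window's differential expression results
#'
#' @param de A `de_results` tibble from [wald_test()] or [run_de()].
#' @param alpha Adjusted-p significance cutoff drawn as a horizontal line.
#' @return A ggplot object.
#' @export
plot_volcano <- function(de, alpha = 0.05) {
  d <- de[!is.na(de$padj), ]
  d$status <- dplyr::case_when(
    d$padj < alpha & d$log2fc > 0 ~ "up",
    d$padj < alpha & d$log2fc < 0 ~ "down",
    TRUE ~ "ns"
  )
  thr <- suppressWarnings(max(d$pvalue[d$padj < alpha], na.rm = TRUE))
  gg <- ggplot2::ggplot(d, ggplot2::aes(x = .data$log2fc,
                                        y = -log10(.data$pvalue),
                                        colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(up = "#2e7d32", down = "#c62828",
                                            ns = "grey60")) +
    ggplot2::labs(x = "log2 fold change (case vs control)",
                  y = "-log10 p-value", colour = NULL) +
    ggplot2::theme_minimal()
  if (is.finite(thr)) {
    gg <- gg + ggplot2::geom_hline(yintercept = -log10(thr),
                                   linetype = "dashed", colour = "grey40")
  }
  gg
}
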