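# ggplot2 figures for the main result types.

#' Plot diagnostic status composition
#'
#' @param object An `ird_diagnosis` from [classify_cohort()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ird_diagnosis <- function(object, ...) {
  dat <- object$statuses |>
    dplyr::count(status = factor(.data$status, levels = rev(ird_statuses)))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$status, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "index patients",
                  title = sprintf("Diagnostic yield %g%%",
                                  object$yield$yield_percent)) +
    ggplot2::theme_minimal()
}

#' Plot per-gene prevalence among diagnosed patients
#'
#' @param prevalence Output of [gene_prevalence()].
#' @return A ggplot (bar chart, genes ordered by patient count).
#' @export
plot_gene_prevalence <- function(prevalence) {
  dat <- prevalence |>
    dplyr::mutate(gene = stats::reorder(.data$gene, .data$n_patients))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$gene,
                                    y = .data$percent_of_diagnosed)) +
    ggplot2::geom_col(fill = "darkseagreen4") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "% of diagnosed index cases") +
    ggplot2::theme_minimal()
}

#' Plot the allele recurrence spectrum
#'
#' @param spectrum Output of [recurrence_spectrum()].
#' @return A ggplot.
#' @export
plot_recurrence_spectrum <- function(spectrum) {
  dat <- spectrum |>
    dplyr::mutate(bin = factor(.data$bin,
                               levels = c("once", "twice", "three_plus"),
                               labels = c("once", "twice", "3+ times")))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$bin, y = .data$fraction)) +
    ggplot2::geom_col(fill = "indianred3") +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = "times detected", y = "fraction") +
    ggplot2::theme_minimal()
}

#' Plot per-genome autozygosity by genotype class
#'
#' @param statuses Diagnosis tibble or `ird_diagnosis`.
#' @param totals Per-patient totals from [autozygosity_totals()].
#' @return A ggplot (boxplots of total autozygosity per genotype class).
#' @export
plot_autozygosity_by_class <- function(statuses, totals) {
  if (inherits(statuses, "ird_diagnosis")) statuses <- statuses$statuses
  dat <- statuses |>
    dplyr::mutate(class = dplyr::if_else(
      .data$status %in% c("solved", "likely_solved") &
        !is.na(.data$zygosity_class),
      .data$zygosity_class, "unsolved")) |>
    dplyr::inner_join(totals, by = "patient_id")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$class, y = .data$total_mb)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(x = NULL, y = "total autozygosity (Mb)") +
    ggplot2::theme_minimal()
}

#' Plot normalized exon depth ratios along a gene
#'
#' @param ratios Output of [normalize_depth()], one gene.
#' @param highlight Optional sample id drawn in color on top.
#' @return A ggplot of per-exon ratios with the copy-state bands of
#'   [cnv_params()] shaded.
#' @export
plot_depth_ratio <- function(ratios, highlight = NULL) {
  samples <- coverage_samples(ratios)
  long <- tidyr::pivot_longer(ratios, dplyr::all_of(samples),
                              names_to = "sample", values_to = "ratio")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$exon, y = .data$ratio,
                                          group = .data$sample)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf, ymin = 0, ymax = 0.15,
                      alpha = 0.15, fill = "red") +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf, ymin = 0.35,
                      ymax = 0.65, alpha = 0.15, fill = "orange") +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::labs(x = "exon", y = "depth ratio") +
    ggplot2::theme_minimal()
  if (!is.null(highlight)) {
    p <- p + ggplot2::geom_line(
      data = long[long$sample == highlight, ],
      color = "red", linewidth = 1)
  }
  p
}

#' Plot birth-cohort trends
#'
#' @param trend Output of [birth_cohort_trend()].
#' @return A ggplot of median autozygosity and percent homozygous
#'   diagnoses per decade of birth.
#' @export
plot_birth_cohort_trend <- function(trend) {
  long <- trend |>
    dplyr::select("decade", autozygosity_mb = "median_autozygosity_mb",
                  percent_hom = "percent_hom") |>
    tidyr::pivot_longer(-"decade", names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$decade, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "decade of birth", y = NULL) +
    ggplot2::theme_minimal()
}
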