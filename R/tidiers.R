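# broom-style accessors for the pipeline's result objects.

#' Tidy a cohort diagnosis
#'
#' @param x An `ird_diagnosis` from [classify_cohort()].
#' @param ... Unused.
#' @return One row per index patient: `patient_id`, `status`, `gene`,
#'   `variant_id`, `variant_id_2`, `zygosity_class`, `xl_female_het`.
#' @export
tidy.ird_diagnosis <- function(x, ...) x$statuses

#' One-row diagnosis summary
#'
#' @param x An `ird_diagnosis`.
#' @param ... Unused.
#' @return A one-row tibble with per-status counts, `yield` and
#'   `yield_percent`.
#' @export
glance.ird_diagnosis <- function(x, ...) x$yield

#' @export
print.ird_diagnosis <- function(x, ...) {
  y <- x$yield
  cat(sprintf(
    "<ird_diagnosis> %d patients: %d solved, %d likely solved, %d uncertain, %d unsolved (yield %g%%)\n",
    y$n, y$solved, y$likely_solved, y$uncertain, y$unsolved,
    y$yield_percent))
  invisible(x)
}

#' Tidy a cohort landscape summary
#'
#' @param x An `ird_cohort_summary` from [cohort_summary()].
#' @param ... Unused.
#' @return The per-gene prevalence table.
#' @export
tidy.ird_cohort_summary <- function(x, ...) x$per_gene

#' One-row landscape summary
#'
#' @param x An `ird_cohort_summary`.
#' @param ... Unused.
#' @return A one-row tibble: cohort size, yield, distinct variants, allele
#'   occurrences, and the three recurrence fractions (variant denominator).
#' @export
glance.ird_cohort_summary <- function(x, ...) {
  rec <- x$recurrence_by_variant
  tibble::tibble(
    n = x$yield$n,
    n_diagnosed = x$yield$solved + x$yield$likely_solved,
    yield = x$yield$yield,
    yield_percent = x$yield$yield_percent,
    n_distinct_variants = nrow(x$occurrences),
    n_allele_occurrences = sum(x$occurrences$occurrences),
    frac_once = rec$fraction[rec$bin == "once"],
    frac_twice = rec$fraction[rec$bin == "twice"],
    frac_three_plus = rec$fraction[rec$bin == "three_plus"])
}
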