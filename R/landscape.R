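# Cohort-level landscape statistics: allele occurrences, recurrence
# spectrum, per-gene prevalence, zygosity breakdown, birth-cohort trends,
# and a cohort summary object.

#' Allele occurrences of causative variants
#'
#' Counts allele copies over diagnosed index patients: a homozygote
#' contributes 2, a heterozygote or hemizygote 1. Only calls of diagnosed
#' (solved or likely solved) index patients are counted; affected relatives
#' are outside the denominator by construction of the cohort tables.
#'
#' @param genotypes Genotype-call tibble of *causative* calls.
#' @param diagnosed_ids Character vector of diagnosed index patient ids;
#'   calls of other patients are ignored.
#' @return A tibble: `variant_id`, `n_index` (distinct carriers),
#'   `occurrences` (allele copies).
#' @examples
#' g <- tibble::tibble(
#'   patient_id = sprintf("P%d", 1:9), variant_id = "v1",
#'   zygosity = rep(c("hom", "het"), c(8, 1)),
#'   phase_partner = NA_character_, phase = "not_applicable")
#' allele_occurrences(g, g$patient_id)  # 8 hom + 1 het -> 17
#' @export
allele_occurrences <- function(genotypes, diagnosed_ids) {
  g <- genotypes[genotypes$patient_id %in% diagnosed_ids, ]
  g |>
    dplyr::group_by(.data$variant_id) |>
    dplyr::summarise(
      n_index = dplyr::n_distinct(.data$patient_id),
      occurrences = sum(ifelse(.data$zygosity == "hom", 2L, 1L)),
      .groups = "drop")
}

#' Recurrence spectrum of causative alleles
#'
#' Bins per-variant occurrence counts into once / twice / three-or-more
#' and reports the fraction per bin. Two denominators are supported:
#' `distinct_variants` (fraction of distinct causative variants per bin)
#' and `alleles` (fraction of total allele occurrences per bin).
#'
#' @param occurrences Tibble from [allele_occurrences()] (needs
#'   `variant_id`, `occurrences`); empty input is an error.
#' @param denominator `"distinct_variants"` or `"alleles"`.
#' @return A tibble: `bin` (once/twice/three_plus), `n_variants`,
#'   `n_alleles`, `fraction`.
#' @export
recurrence_spectrum <- function(occurrences,
                                denominator = c("distinct_variants",
                                                "alleles")) {
  denominator <- match.arg(denominator)
  if (nrow(occurrences) == 0) {
    abort("cannot compute a recurrence spectrum from no variants")
  }
  binned <- occurrences |>
    dplyr::mutate(bin = dplyr::case_when(
      .data$occurrences == 1 ~ "once",
      .data$occurrences == 2 ~ "twice",
      TRUE ~ "three_plus")) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(n_variants = dplyr::n(),
                     n_alleles = sum(.data$occurrences), .groups = "drop")
  out <- tibble::tibble(bin = c("once", "twice", "three_plus")) |>
    dplyr::left_join(binned, by = "bin") |>
    dplyr::mutate(dplyr::across(c("n_variants", "n_alleles"),
                                ~ dplyr::coalesce(.x, 0L)))
  out$fraction <- if (denominator == "distinct_variants") {
    out$n_variants / sum(out$n_variants)
  } else {
    out$n_alleles / sum(out$n_alleles)
  }
  out
}

#' Per-gene prevalence among diagnosed patients
#'
#' Counts diagnosed index cases per causal gene; percentages are computed
#' over the diagnosed (solved + likely solved) patients, with an optional
#' secondary percentage over all index cases.
#'
#' @param statuses Diagnosis tibble (`patient_id`, `status`, `gene`), e.g.
#'   from [classify_cohort()].
#' @param n_total Optional total number of index cases for the
#'   `percent_of_all` column.
#' @param other_max Genes with at most this many patients are grouped as
#'   "other" (`NULL` to disable; default 2).
#' @return A tibble: `gene`, `n_patients`, `percent_of_diagnosed` (and
#'   `percent_of_all` when `n_total` is given), sorted by count.
#' @export
gene_prevalence <- function(statuses, n_total = NULL, other_max = 2) {
  if (inherits(statuses, "ird_diagnosis")) statuses <- statuses$statuses
  diag <- statuses[statuses$status %in% c("solved", "likely_solved"), ]
  if (nrow(diag) == 0) {
    return(tibble::tibble(gene = character(), n_patients = integer(),
                          percent_of_diagnosed = double()))
  }
  out <- diag |>
    dplyr::count(gene = .data$gene, name = "n_patients")
  if (!is.null(other_max)) {
    out <- out |>
      dplyr::mutate(gene = ifelse(.data$n_patients <= other_max,
                                  "other", .data$gene)) |>
      dplyr::group_by(.data$gene) |>
      dplyr::summarise(n_patients = sum(.data$n_patients), .groups = "drop")
  }
  out$percent_of_diagnosed <- 100 * out$n_patients / nrow(diag)
  if (!is.null(n_total)) {
    out$percent_of_all <- 100 * out$n_patients / n_total
  }
  dplyr::arrange(out, .data$gene == "other", dplyr::desc(.data$n_patients))
}

#' Zygosity breakdown of diagnosed patients
#'
#' Assigns each diagnosed patient exactly one of AR_hom, AR_comp_het,
#' AD_het, XL_hemi or XL_het_female and returns the fractions over the
#' diagnosed set. A diagnosed patient without a genotype class is an error
#' (listing the patients).
#'
#' @param statuses Diagnosis tibble with `status` and `zygosity_class`.
#' @return A tibble: `zygosity_class`, `n`, `fraction`.
#' @export
zygosity_breakdown <- function(statuses) {
  if (inherits(statuses, "ird_diagnosis")) statuses <- statuses$statuses
  diag <- statuses[statuses$status %in% c("solved", "likely_solved"), ]
  bad <- is.na(diag$zygosity_class)
  if (any(bad)) {
    abort(sprintf("diagnosed patient(s) without a genotype class: %s",
                  paste(diag$patient_id[bad], collapse = ", ")))
  }
  diag |>
    dplyr::count(zygosity_class = .data$zygosity_class, name = "n") |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::arrange(dplyr::desc(.data$n))
}

#' Birth-cohort trends of autozygosity and homozygous diagnoses
#'
#' Bins patients by decade of birth and reports the median per-genome
#' autozygosity and the percentage of homozygous genotypes among diagnosed
#' patients per decade. Patients with missing birth years are excluded
#' (their count is reported in the `n_missing_year` attribute and a
#' message).
#'
#' @param patients Patient tibble with `birth_year`.
#' @param statuses Diagnosis tibble (`patient_id`, `status`,
#'   `zygosity_class`).
#' @param totals Per-patient autozygosity totals ([autozygosity_totals()]);
#'   optional (medians are `NA` without it).
#' @return A tibble: `decade`, `n`, `median_autozygosity_mb`,
#'   `n_diagnosed`, `percent_hom`.
#' @export
birth_cohort_trend <- function(patients, statuses, totals = NULL) {
  if (inherits(statuses, "ird_diagnosis")) statuses <- statuses$statuses
  assert_cols(patients, c("patient_id", "birth_year"))
  n_missing <- sum(is.na(patients$birth_year))
  dat <- patients[!is.na(patients$birth_year), ] |>
    dplyr::left_join(statuses[, c("patient_id", "status", "zygosity_class")],
                     by = "patient_id")
  if (!is.null(totals)) {
    dat <- dplyr::left_join(dat, totals, by = "patient_id")
  } else {
    dat$total_mb <- NA_real_
  }
  if (n_missing > 0) {
    message(sprintf("excluding %d patient(s) with missing birth year",
                    n_missing))
  }
  if (nrow(dat) == 0) {
    warn("no patients with a birth year")
    out <- tibble::tibble(decade = integer(), n = integer(),
                          median_autozygosity_mb = double(),
                          n_diagnosed = integer(), percent_hom = double())
    attr(out, "n_missing_year") <- n_missing
    return(out)
  }
  out <- dat |>
    dplyr::mutate(decade = 10L * (.data$birth_year %/% 10L),
                  diagnosed = .data$status %in% c("solved", "likely_solved")) |>
    dplyr::group_by(.data$decade) |>
    dplyr::summarise(
      n = dplyr::n(),
      median_autozygosity_mb = median(.data$total_mb),
      n_diagnosed = sum(.data$diagnosed),
      percent_hom = ifelse(.data$n_diagnosed > 0,
                           100 * sum(.data$diagnosed &
                                       .data$zygosity_class %in% "AR_hom") /
                             .data$n_diagnosed, NA_real_),
      .groups = "drop") |>
    dplyr::arrange(.data$decade)
  attr(out, "n_missing_year") <- n_missing
  out
}

#' Distinct-variant and occurrence counts by variant kind
#'
#' @param variants Variant tibble.
#' @param occurrences Tibble from [allele_occurrences()].
#' @return A tibble: `kind`, `distinct`, `occurrences`. Sums over kinds
#'   conserve the totals.
#' @export
variant_class_counts <- function(variants, occurrences) {
  occurrences |>
    dplyr::inner_join(variants[, c("variant_id", "kind")],
                      by = "variant_id") |>
    dplyr::group_by(kind = .data$kind) |>
    dplyr::summarise(distinct = dplyr::n(),
                     occurrences = sum(.data$occurrences),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$distinct))
}

#' Assemble the cohort landscape summary
#'
#' Bundles diagnostic yield, per-gene prevalence, the recurrence spectrum
#' under both denominators, the zygosity breakdown and per-kind variant
#' counts into one object with [tidy()]/[glance()] methods.
#'
#' @param diagnosis An `ird_diagnosis` from [classify_cohort()].
#' @param variants Variant tibble.
#' @param genotypes Genotype-call tibble of causative calls (defaults to
#'   the calls of diagnosed patients' assigned variants).
#' @return An object of class `ird_cohort_summary`.
#' @export
cohort_summary <- function(diagnosis, variants, genotypes) {
  stopifnot(inherits(diagnosis, "ird_diagnosis"))
  statuses <- diagnosis$statuses
  diagnosed <- statuses$patient_id[statuses$status %in%
                                     c("solved", "likely_solved")]
  causal_ids <- unique(stats::na.omit(c(statuses$variant_id,
                                        statuses$variant_id_2)))
  causal_calls <- genotypes[genotypes$variant_id %in% causal_ids, ]
  occ <- allele_occurrences(causal_calls, diagnosed)
  out <- list(
    yield = diagnosis$yield,
    per_gene = gene_prevalence(statuses, n_total = nrow(statuses)),
    occurrences = occ,
    recurrence_by_variant = recurrence_spectrum(occ, "distinct_variants"),
    recurrence_by_allele = recurrence_spectrum(occ, "alleles"),
    zygosity = zygosity_breakdown(statuses),
    variant_classes = variant_class_counts(variants, occ))
  class(out) <- "ird_cohort_summary"
  out
}

#' @export
print.ird_cohort_summary <- function(x, ...) {
  y <- x$yield
  cat(sprintf("<ird_cohort_summary> %d index cases, yield %d/%d = %g%%\n",
              y$n, y$solved + y$likely_solved, y$n, y$yield_percent))
  cat(sprintf("  top genes: %s\n",
              paste(utils::head(x$per_gene$gene, 5), collapse = ", ")))
  rec <- x$recurrence_by_variant
  cat(sprintf("  recurrence (variants): once %.0f%%, twice %.0f%%, >=3x %.0f%%\n",
              100 * rec$fraction[1], 100 * rec$fraction[2],
              100 * rec$fraction[3]))
  invisible(x)
}
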