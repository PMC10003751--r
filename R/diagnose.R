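# Patient-level decision procedure: maps a genotype assortment (the P/LP/VUS
# calls retained in the top candidate gene) to one of four diagnostic
# statuses. Statuses are ordered unsolved < uncertain < likely_solved <
# solved, and promoting any VUS to LP never lowers the status.

#' Classify one genotype assortment
#'
#' Applies the diagnostic decision rules to the (at most two) variants
#' retained in a patient's top candidate gene.
#'
#' Rules, in order, for a recessive or isolated condition: two PLP in trans
#' or one homozygous PLP is solved; a PLP plus a VUS in trans, or two PLP
#' with unresolved phase, is likely solved; two VUS in trans, a PLP plus a
#' VUS with unresolved phase, two VUS with unresolved phase, or one
#' homozygous VUS is uncertain. For a dominant condition one heterozygous
#' PLP is solved and one heterozygous VUS is uncertain. For an X-linked
#' condition in a male, one hemizygous PLP is solved and one hemizygous VUS
#' is uncertain. Anything else - notably a single heterozygous PLP in a
#' recessive context, or any pair in cis - is unsolved.
#'
#' Unknown inheritance is handled under the recessive rules (like isolated
#' cases). A heterozygous X-linked female (the manifesting-carrier
#' situation) is governed by `xl_female_het_policy`: under `"solved"` a het
#' PLP is solved (flagged downstream) and a het VUS is uncertain; under
#' `"unsolved"` both are unsolved.
#'
#' @param inheritance One of isolated/AR/AD/XL/unknown.
#' @param sex Patient sex ("male"/"female").
#' @param classes Character vector (length 1-2) of clinical classes among
#'   P/LP/VUS.
#' @param zygosities Matching vector of zygosities (het/hom/hemi).
#' @param phases Matching vector of phases; hom/hemi entries must be
#'   `not_applicable`.
#' @param xl_female_het_policy `"solved"` (default) or `"unsolved"`.
#' @return A single status string.
#' @examples
#' classify_patient("AD", "female", "LP", "het", "unknown")      # solved
#' classify_patient("AR", "male", c("P", "VUS"), c("het", "het"),
#'                  c("in_trans", "in_trans"))                   # likely_solved
#' classify_patient("AR", "male", "VUS", "hom", "not_applicable") # uncertain
#' classify_patient("AR", "male", "P", "het", "unknown")          # unsolved
#' @export
classify_patient <- function(inheritance, sex, classes, zygosities, phases,
                             xl_female_het_policy = c("solved", "unsolved")) {
  xl_female_het_policy <- match.arg(xl_female_het_policy)
  n <- length(classes)
  if (n > 2) abort("an assortment may hold at most 2 distinct variants")
  if (length(zygosities) != n || length(phases) != n) {
    abort("classes, zygosities and phases must have equal length")
  }
  assert_values(inheritance, ird_inheritances, "inheritance")
  assert_values(sex, ird_sexes, "sex")
  assert_values(classes, c("P", "LP", "VUS"), "clinical class")
  assert_values(zygosities, ird_zygosities, "zygosity")
  assert_values(phases, ird_phases, "phase")
  if (any(zygosities == "hemi" & sex == "female")) {
    abort("hemizygous call in a female patient")
  }
  if (any(zygosities %in% c("hom", "hemi") & phases != "not_applicable")) {
    abort("hom/hemi calls must carry phase = not_applicable")
  }
  if (n == 0) return("unsolved")

  # A homozygous (or hemizygous) variant is already biallelic; if paired
  # with a het partner, the single-variant rule for it decides alone.
  if (n == 2 && any(zygosities != "het")) {
    i <- which(zygosities != "het")[1]
    return(classify_patient(inheritance, sex, classes[i], zygosities[i],
                            phases[i], xl_female_het_policy))
  }

  plp <- is_plp(classes)
  recessive_rules <- function() {
    if (n == 1) {
      z <- zygosities[1]
      if (z %in% c("hom", "hemi")) {
        if (plp[1]) "solved" else "uncertain"
      } else {
        "unsolved"  # a single heterozygous variant in a recessive context
      }
    } else {
      phase <- phases[1]
      if (phase == "in_cis") return("unsolved")
      if (phase == "in_trans") {
        if (all(plp)) "solved"
        else if (any(plp)) "likely_solved"
        else "uncertain"
      } else {  # phase could not be ascertained
        if (all(plp)) "likely_solved" else "uncertain"
      }
    }
  }
  dominant_rules <- function() {
    if (any(plp)) "solved" else "uncertain"
  }

  switch(inheritance,
    AR = ,
    isolated = ,
    unknown = recessive_rules(),
    AD = dominant_rules(),
    XL = {
      if (sex == "male") {
        # only a hemizygous (or X-homozygous, equivalently single-copy)
        # call is a valid X-linked male genotype; anything else is unsolved
        if (n == 1 && zygosities[1] %in% c("hemi", "hom")) {
          dominant_rules()
        } else {
          "unsolved"
        }
      } else if (n == 1 && zygosities[1] == "het") {
        if (xl_female_het_policy == "solved") {
          if (plp[1]) "solved" else "uncertain"
        } else {
          "unsolved"
        }
      } else {
        # biallelic situations in a female follow the recessive rules
        recessive_rules()
      }
    })
}

#' Classify every patient in a cohort
#'
#' Builds inheritance-compatible candidates from the genotype calls (see
#' [inheritance_candidates()]), evaluates the decision rules on each, and
#' assigns each patient the best achievable status; ties are broken by gene
#' tier. Patients with no candidate are unsolved.
#'
#' @param patients Patient tibble.
#' @param genotypes Genotype-call tibble.
#' @param variants Variant tibble (clinical classes are read from here).
#' @param config A [prioritization_config()] (gene tiers).
#' @param xl_female_het_policy See [classify_patient()].
#' @return An object of class `ird_diagnosis`: list with `statuses` (tibble:
#'   `patient_id`, `status`, `gene`, `variant_id`, `variant_id_2`,
#'   `zygosity_class`, `xl_female_het` flag) and `yield` (see
#'   [diagnostic_yield()]). Supports [tidy()], [glance()] and `autoplot()`.
#' @export
classify_cohort <- function(patients, genotypes, variants,
                            config = prioritization_config(),
                            xl_female_het_policy = c("solved", "unsolved")) {
  xl_female_het_policy <- match.arg(xl_female_het_policy)
  assert_cols(patients, c("patient_id", "sex", "inheritance"))
  cand <- inheritance_candidates(patients, genotypes, variants, config)
  vclass <- setNames(variants$clinical_class, variants$variant_id)

  eval_one <- function(patient_id, gene, variant_id, variant_id_2,
                       zygosity, zygosity_2, phase, ...) {
    p <- patients[patients$patient_id == patient_id, ]
    ids <- c(variant_id, variant_id_2)
    ids <- ids[!is.na(ids)]
    classes <- unname(vclass[ids])
    if (any(classes %in% c("B", "LB"))) return("unsolved")
    zyg <- c(zygosity, zygosity_2)[seq_along(ids)]
    ph <- if (length(ids) == 2) rep(phase, 2) else phase
    classify_patient(p$inheritance, p$sex, classes, zyg, ph,
                     xl_female_het_policy)
  }

  if (nrow(cand) > 0) {
    cand$status <- purrr::pmap_chr(cand, eval_one)
    best <- cand |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::arrange(dplyr::desc(status_rank(.data$status)), .data$tier,
                     .by_group = TRUE) |>
      dplyr::slice(1) |>
      dplyr::ungroup()
  } else {
    best <- tibble::tibble(patient_id = character(), gene = character(),
                           variant_id = character(),
                           variant_id_2 = character(),
                           zygosity = character(), zygosity_2 = character(),
                           phase = character(), tier = integer(),
                           status = character())
  }

  statuses <- patients |>
    dplyr::select("patient_id", "sex", "inheritance") |>
    dplyr::left_join(best |>
                       dplyr::select("patient_id", "status", "gene",
                                     "variant_id", "variant_id_2",
                                     "zygosity", "phase"),
                     by = "patient_id") |>
    dplyr::mutate(
      status = dplyr::coalesce(.data$status, "unsolved"),
      zygosity_class = dplyr::case_when(
        .data$status %in% c("unsolved", "uncertain") ~ NA_character_,
        !is.na(.data$variant_id_2) ~ "AR_comp_het",
        .data$zygosity == "hom" ~ "AR_hom",
        .data$zygosity == "hemi" ~ "XL_hemi",
        .data$inheritance == "XL" & .data$sex == "female" &
          .data$zygosity == "het" ~ "XL_het_female",
        .data$zygosity == "het" ~ "AD_het",
        TRUE ~ NA_character_
      ),
      xl_female_het = .data$inheritance == "XL" & .data$sex == "female" &
        !is.na(.data$zygosity) & .data$zygosity == "het" &
        .data$status == "solved"
    ) |>
    dplyr::select("patient_id", "status", "gene", "variant_id",
                  "variant_id_2", "zygosity_class", "xl_female_het")

  out <- list(statuses = statuses,
              yield = diagnostic_yield(statuses),
              xl_female_het_policy = xl_female_het_policy)
  class(out) <- "ird_diagnosis"
  out
}

#' Diagnostic yield of a classified cohort
#'
#' Yield is the fraction of index patients in the solved or likely-solved
#' classes. The reported percentage rounds half-up to an integer.
#'
#' @param statuses A tibble with a `status` column (one row per index
#'   patient), or an `ird_diagnosis`.
#' @param by Optional column name to stratify by (e.g. a phenotype class).
#' @return A one-row tibble (`n`, per-status counts, `yield`,
#'   `yield_percent`), or one row per stratum when `by` is given.
#' @examples
#' statuses <- tibble::tibble(
#'   status = rep(c("solved", "likely_solved", "unsolved"), c(150, 24, 56)))
#' diagnostic_yield(statuses)  # 174 of 230 -> 75.65% -> 76%
#' @export
diagnostic_yield <- function(statuses, by = NULL) {
  if (inherits(statuses, "ird_diagnosis")) statuses <- statuses$statuses
  assert_cols(statuses, "status")
  if (nrow(statuses) == 0) abort("cannot compute yield of an empty cohort")
  assert_values(statuses$status, ird_statuses, "status")
  group_cols <- if (is.null(by)) character() else by
  statuses |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::summarise(
      n = dplyr::n(),
      solved = sum(.data$status == "solved"),
      likely_solved = sum(.data$status == "likely_solved"),
      uncertain = sum(.data$status == "uncertain"),
      unsolved = sum(.data$status == "unsolved"),
      yield = (.data$solved + .data$likely_solved) / .data$n,
      yield_percent = round_half_up(100 * .data$yield),
      .groups = "drop")
}
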