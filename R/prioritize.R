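# Variant prioritization cascade: molecular profile, population frequency,
# the VUS retention gate, gene tiers, and inheritance-compatible candidate
# genotype configurations.

#' Prioritization configuration
#'
#' @param maf_causal_max Population-frequency ceiling for causal
#'   candidates (strict `<`, default 0.01, i.e. MAF below 1%).
#' @param maf_vus_max Frequency ceiling for retaining a VUS (default 0.01).
#' @param gerp_min Conservation floor for the VUS gate (default 4; a
#'   missing GERP fails this arm).
#' @param splice_score_min Minimum splice-prediction score (dbscSNV-ADA
#'   scale, default 0.6) to rescue synonymous/intronic variants and to
#'   satisfy the VUS splice arm.
#' @param retained_profiles Molecular profiles kept by the profile filter.
#' @param tier1_genes,tier2_genes Gene sets for tier assignment (defaults:
#'   the synthetic retinal-panel and wider Mendelian sets).
#' @param min_quality Optional minimum call quality; applied by
#'   [prioritize_variants()] only when the variant table has a `qual`
#'   column.
#' @return A validated list of class `prioritization_config`.
#' @export
prioritization_config <- function(maf_causal_max = 0.01,
                                  maf_vus_max = 0.01,
                                  gerp_min = 4,
                                  splice_score_min = 0.6,
                                  retained_profiles = c(
                                    "nonsense", "frameshift", "missense",
                                    "splice_region", "start_loss",
                                    "structural", "inframe_indel"),
                                  tier1_genes = ird_tier1_genes(),
                                  tier2_genes = ird_tier2_genes(),
                                  min_quality = NULL) {
  if (maf_causal_max < 0 || maf_causal_max > 1 ||
      maf_vus_max < 0 || maf_vus_max > 1) {
    abort("MAF thresholds must lie in [0, 1]")
  }
  if (splice_score_min < 0 || splice_score_min > 1) {
    abort("splice_score_min must lie in [0, 1]")
  }
  assert_values(retained_profiles, ird_profiles, "retained profile")
  structure(list(maf_causal_max = maf_causal_max, maf_vus_max = maf_vus_max,
                 gerp_min = gerp_min, splice_score_min = splice_score_min,
                 retained_profiles = retained_profiles,
                 tier1_genes = tier1_genes, tier2_genes = tier2_genes,
                 min_quality = min_quality),
            class = "prioritization_config")
}

#' Molecular-profile filter
#'
#' Keeps variants whose profile is in the retained set (nonsense,
#' frameshift, missense, splice, start-loss, structural, in-frame indel by
#' default). A synonymous variant is kept only when its splice-prediction
#' score reaches `splice_score_min` (the splicing-synonymous rescue); a
#' synonymous variant with no splice score is dropped.
#'
#' @param variants Variant tibble.
#' @param config A [prioritization_config()].
#' @return The input with logical `keep` and character `reason` columns.
#' @export
profile_filter <- function(variants, config = prioritization_config()) {
  assert_cols(variants, "profile")
  splice <- if ("splice_score" %in% names(variants)) variants$splice_score
            else rep(NA_real_, nrow(variants))
  splice_ok <- !is.na(splice) & splice >= config$splice_score_min
  keep <- variants$profile %in% config$retained_profiles |
    (variants$profile == "synonymous" & splice_ok)
  reason <- dplyr::case_when(
    variants$profile %in% config$retained_profiles ~ "retained profile",
    variants$profile == "synonymous" & splice_ok ~
      "synonymous rescued by splice prediction",
    variants$profile == "synonymous" ~
      "synonymous without qualifying splice prediction",
    TRUE ~ "profile not retained")
  dplyr::mutate(variants, keep = keep, reason = reason)
}

#' Population-frequency filter
#'
#' Keeps variants with missing MAF (absence from population databases is
#' not evidence of frequency) or MAF strictly below `maf_causal_max`.
#'
#' @inheritParams profile_filter
#' @return The input with logical `keep` and character `reason` columns.
#' @export
frequency_filter <- function(variants, config = prioritization_config()) {
  assert_cols(variants, "maf")
  keep <- is.na(variants$maf) | variants$maf < config$maf_causal_max
  reason <- dplyr::case_when(
    is.na(variants$maf) ~ "no population record",
    keep ~ sprintf("MAF below %g", config$maf_causal_max),
    TRUE ~ sprintf("MAF %g at or above %g", variants$maf,
                   config$maf_causal_max))
  dplyr::mutate(variants, keep = keep, reason = reason)
}

#' VUS retention gate
#'
#' A variant of unknown significance is retained only when it resembles a
#' typical causative allele: frequency under `maf_vus_max` (missing MAF
#' passes), an impact at the protein level (any non-synonymous,
#' non-splice-only profile) or a qualifying splice prediction, and either
#' strong conservation (GERP above `gerp_min`; missing GERP fails this arm)
#' or a qualifying splice prediction.
#'
#' @param variants Variant tibble; every row must have
#'   `clinical_class == "VUS"` (anything else is an error).
#' @param config A [prioritization_config()].
#' @return The input with logical `keep` and character `reason` columns.
#' @export
vus_retention <- function(variants, config = prioritization_config()) {
  assert_cols(variants, c("clinical_class", "maf", "gerp", "profile"))
  if (any(variants$clinical_class != "VUS")) {
    abort("vus_retention applies only to VUS-class variants")
  }
  splice <- if ("splice_score" %in% names(variants)) variants$splice_score
            else rep(NA_real_, nrow(variants))
  splice_ok <- !is.na(splice) & splice >= config$splice_score_min
  freq_ok <- is.na(variants$maf) | variants$maf < config$maf_vus_max
  protein_ok <- variants$profile %in% c("missense", "nonsense", "frameshift",
                                        "inframe_indel", "start_loss",
                                        "structural") | splice_ok
  cons_ok <- (!is.na(variants$gerp) & variants$gerp > config$gerp_min) |
    splice_ok
  keep <- freq_ok & protein_ok & cons_ok
  reason <- dplyr::case_when(
    !freq_ok ~ "frequency too high for a VUS",
    !protein_ok ~ "no protein-level or splice-predicted impact",
    !cons_ok ~ "not conserved and no splice prediction",
    TRUE ~ "VUS with mutation-like characteristics")
  dplyr::mutate(variants, keep = keep, reason = reason)
}

#' Gene tier lookup
#'
#' Tier 1: the retinal-disease gene panel; tier 2: the wider
#' Mendelian-disease set; tier 3: everything else. Candidates are reported
#' sorted by tier.
#'
#' @param gene Character vector of gene symbols.
#' @param config A [prioritization_config()].
#' @return Integer vector of tiers (1, 2 or 3).
#' @export
gene_tier <- function(gene, config = prioritization_config()) {
  dplyr::case_when(gene %in% config$tier1_genes ~ 1L,
                   gene %in% config$tier2_genes ~ 2L,
                   TRUE ~ 3L)
}

#' Run the full prioritization cascade
#'
#' Applies, in order: the optional call-quality floor, the frequency
#' filter, the profile filter, and (for VUS-class variants) the retention
#' gate. The filters are conjunctive, so the kept set equals the
#' intersection of the single-filter kept sets.
#'
#' @param variants Variant tibble.
#' @param config A [prioritization_config()].
#' @return The input variants with `keep` (logical), `drop_reason`
#'   (character, `NA` when kept) and `tier` columns, sorted by tier.
#' @export
prioritize_variants <- function(variants, config = prioritization_config()) {
  out <- variants
  qual_ok <- if (!is.null(config$min_quality) && "qual" %in% names(out)) {
    !is.na(out$qual) & out$qual >= config$min_quality
  } else {
    rep(TRUE, nrow(out))
  }
  freq <- frequency_filter(out, config)
  prof <- profile_filter(out, config)
  vus_keep <- rep(TRUE, nrow(out))
  vus_reason <- rep(NA_character_, nrow(out))
  is_vus <- out$clinical_class == "VUS"
  if (any(is_vus)) {
    gate <- vus_retention(out[is_vus, , drop = FALSE], config)
    vus_keep[is_vus] <- gate$keep
    vus_reason[is_vus] <- gate$reason
  }
  benign <- out$clinical_class %in% c("B", "LB")
  out$keep <- qual_ok & freq$keep & prof$keep & vus_keep & !benign
  out$drop_reason <- dplyr::case_when(
    out$keep ~ NA_character_,
    !qual_ok ~ "below call-quality floor",
    benign ~ "benign/likely benign",
    !freq$keep ~ freq$reason,
    !prof$keep ~ prof$reason,
    TRUE ~ vus_reason)
  out$tier <- gene_tier(out$gene, config)
  dplyr::arrange(out, .data$tier, chrom_order(.data$chrom), .data$start)
}

#' Inheritance-compatible candidate genotype configurations
#'
#' For each patient, enumerates the genotype configurations compatible with
#' the reported inheritance: recessive/isolated conditions admit homozygous
#' (or hemizygous) singletons and heterozygous pairs within one gene;
#' dominant conditions admit single variants; X-linked conditions admit
#' hemizygous calls in males and X-chromosome variants in females. Unknown
#' inheritance takes the union of all patterns. A single heterozygous call
#' in a recessive context is *not* a candidate.
#'
#' @param patients Patient tibble (`patient_id`, `sex`, `inheritance`).
#' @param genotypes Genotype-call tibble.
#' @param variants Variant tibble (for gene and chromosome lookup).
#' @param config A [prioritization_config()] (tier assignment).
#' @return A tibble with one row per candidate: `patient_id`, `gene`,
#'   `variant_id`, `variant_id_2` (`NA` for singletons), `zygosity`,
#'   `zygosity_2`, `phase` (pair phase; `not_applicable` for singletons),
#'   `tier`, `pattern`; sorted by patient and tier.
#' @export
inheritance_candidates <- function(patients, genotypes, variants,
                                   config = prioritization_config()) {
  assert_cols(patients, c("patient_id", "sex", "inheritance"))
  empty <- tibble::tibble(patient_id = character(), gene = character(),
                          variant_id = character(),
                          variant_id_2 = character(),
                          zygosity = character(), zygosity_2 = character(),
                          phase = character(), tier = integer(),
                          pattern = character())
  if (nrow(genotypes) == 0) return(empty)
  calls <- genotypes |>
    dplyr::inner_join(variants |>
                        dplyr::select("variant_id", "gene", "chrom"),
                      by = "variant_id")

  one_patient <- function(patient_id, sex, inheritance, ...) {
    g <- calls[calls$patient_id == patient_id, ]
    if (nrow(g) == 0) return(NULL)
    singleton <- function(rows, pattern) {
      if (nrow(rows) == 0) return(NULL)
      tibble::tibble(patient_id = patient_id, gene = rows$gene,
                     variant_id = rows$variant_id,
                     variant_id_2 = NA_character_,
                     zygosity = rows$zygosity, zygosity_2 = NA_character_,
                     phase = "not_applicable", pattern = pattern)
    }
    recessive_cands <- function() {
      res <- list(singleton(g[g$zygosity %in% c("hom", "hemi"), ],
                            "recessive_biallelic"))
      hets <- g[g$zygosity == "het", ]
      for (gene in unique(hets$gene)) {
        h <- hets[hets$gene == gene, ]
        if (nrow(h) < 2) next
        pairs <- utils::combn(seq_len(nrow(h)), 2)
        res <- c(res, list(tibble::tibble(
          patient_id = patient_id, gene = gene,
          variant_id = h$variant_id[pairs[1, ]],
          variant_id_2 = h$variant_id[pairs[2, ]],
          zygosity = "het", zygosity_2 = "het",
          phase = purrr::map2_chr(pairs[1, ], pairs[2, ], function(i, j) {
            if (!is.na(h$phase_partner[i]) &&
                h$phase_partner[i] == h$variant_id[j] &&
                !is.na(h$phase[i])) h$phase[i] else "unknown"
          }),
          pattern = "recessive_pair")))
      }
      res
    }
    dominant_cands <- function() {
      list(singleton(g, "dominant_het"))
    }
    xl_cands <- function() {
      on_x <- g[g$chrom == "X", ]
      if (sex == "male") {
        list(singleton(on_x[on_x$zygosity %in% c("hemi", "hom"), ],
                       "xl_hemi"))
      } else {
        list(singleton(on_x, "xl_female"))
      }
    }
    res <- switch(inheritance,
      AR = ,
      isolated = recessive_cands(),
      AD = dominant_cands(),
      XL = xl_cands(),
      unknown = c(recessive_cands(), dominant_cands(), xl_cands()))
    out <- dplyr::bind_rows(res)
    if (nrow(out) == 0) return(NULL)
    dplyr::distinct(out, .data$variant_id, .data$variant_id_2,
                    .data$pattern, .keep_all = TRUE)
  }

  out <- purrr::pmap(patients, one_patient) |> dplyr::bind_rows()
  if (nrow(out) == 0) return(empty)
  out$tier <- gene_tier(out$gene, config)
  dplyr::arrange(out, .data$patient_id, .data$tier, .data$gene)
}
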