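# Small in-code fixtures shared across test files.

a_variant <- function(variant_id = "v1", gene = "EYS", chrom = "6",
                      start = 1000L, end = start, ref = "A", alt = "T",
                      kind = "snv", profile = "missense", maf = NA_real_,
                      gerp = NA_real_, splice_score = NA_real_,
                      clinical_class = "P", novel = FALSE) {
  tibble::tibble(variant_id = variant_id, gene = gene, chrom = chrom,
                 start = as.integer(start), end = as.integer(end),
                 ref = ref, alt = alt, kind = kind, profile = profile,
                 maf = maf, gerp = gerp, splice_score = splice_score,
                 clinical_class = clinical_class, novel = novel)
}

a_call <- function(patient_id = "P1", variant_id = "v1", zygosity = "het",
                   phase = "unknown", phase_partner = NA_character_) {
  if (zygosity %in% c("hom", "hemi")) phase <- "not_applicable"
  tibble::tibble(patient_id = patient_id, variant_id = variant_id,
                 zygosity = zygosity, phase_partner = phase_partner,
                 phase = phase)
}

a_patient <- function(patient_id = "P1", sex = "male", inheritance = "AR",
                      phenotype_class = "RP", birth_year = 1970L) {
  tibble::tibble(patient_id = patient_id, sex = sex,
                 inheritance = inheritance,
                 phenotype_class = phenotype_class,
                 birth_year = as.integer(birth_year))
}

# ROH segment row in the caller's output shape
a_segment <- function(patient_id = "P1", chrom = "1", start = 1L,
                      end = 1000000L, n_markers = 300L, n_het = 0L) {
  tibble::tibble(patient_id = patient_id, chrom = chrom,
                 start = as.integer(start), end = as.integer(end),
                 n_markers = as.integer(n_markers),
                 n_het = as.integer(n_het),
                 length_bp = as.integer(end) - as.integer(start) + 1L)
}

arrange_cohort <- function(x) {
  list(patients = dplyr::arrange(x$patients, patient_id),
       variants = dplyr::arrange(x$variants, variant_id),
       genotypes = dplyr::arrange(x$genotypes, patient_id, variant_id))
}
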