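# Readers/writers for the pipeline's tabular formats. All genomic intervals
# are 1-based inclusive internally; BED output converts to 0-based half-open
# at the boundary only. Missing values are encoded as "." in every TSV.
# Chromosome names are stored without a "chr" prefix; readers strip it.

ird_na <- "."

read_tsv_checked <- function(path, col_types) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  out <- suppressWarnings(readr::read_tsv(path, col_types = col_types,
                                          na = ird_na, progress = FALSE))
  probs <- readr::problems(out)
  if (nrow(probs) > 0) {
    abort(sprintf("malformed line in %s: row %d, column %s (%s)",
                  path, probs$row[1], as.character(probs$col[1]),
                  probs$expected[1]))
  }
  out
}

#' Read and write patient metadata
#'
#' `patients.tsv` columns: `patient_id`, `sex`, `inheritance`, `phenotype`,
#' `birth_year`, and optionally `status`. Internally the phenotype column is
#' named `phenotype_class`.
#'
#' @param path File path.
#' @return `read_patients()` returns a tibble; `write_patients()` returns
#'   `path` invisibly.
#' @export
read_patients <- function(path) {
  out <- read_tsv_checked(path, readr::cols(
    patient_id = readr::col_character(),
    sex = readr::col_character(),
    inheritance = readr::col_character(),
    phenotype = readr::col_character(),
    birth_year = readr::col_integer(),
    .default = readr::col_character()
  ))
  out <- dplyr::rename(out, phenotype_class = "phenotype")
  if (anyDuplicated(out$patient_id)) {
    abort(sprintf("duplicate patient_id in %s: %s", path,
                  out$patient_id[duplicated(out$patient_id)][1]))
  }
  assert_values(out$sex, ird_sexes, "sex")
  assert_values(out$inheritance, ird_inheritances, "inheritance")
  if ("status" %in% names(out)) assert_values(out$status, ird_statuses, "status")
  out
}

#' @rdname read_patients
#' @param patients Tibble as returned by [read_patients()] or
#'   [simulate_cohort()].
#' @export
write_patients <- function(patients, path) {
  assert_cols(patients, c("patient_id", "sex", "inheritance",
                          "phenotype_class", "birth_year"))
  out <- dplyr::rename(patients, phenotype = "phenotype_class")
  readr::write_tsv(out, path, na = ird_na)
  invisible(path)
}

#' Read and write genotype calls
#'
#' `genotypes.tsv` columns: `patient_id`, `variant_id`, `zygosity`
#' (het/hom/hemi), `phase_partner` (variant_id or "."), `phase`
#' (in_trans/in_cis/unknown/not_applicable).
#'
#' @param path File path.
#' @return A tibble of genotype calls.
#' @export
read_genotypes <- function(path) {
  out <- read_tsv_checked(path, readr::cols(
    patient_id = readr::col_character(),
    variant_id = readr::col_character(),
    zygosity = readr::col_character(),
    phase_partner = readr::col_character(),
    phase = readr::col_character()
  ))
  assert_values(out$zygosity, ird_zygosities, "zygosity")
  assert_values(out$phase, ird_phases, "phase")
  validate_genotypes(out)
  out
}

#' @rdname read_genotypes
#' @param genotypes Tibble of genotype calls.
#' @export
write_genotypes <- function(genotypes, path) {
  assert_cols(genotypes, c("patient_id", "variant_id", "zygosity",
                           "phase_partner", "phase"))
  readr::write_tsv(genotypes, path, na = ird_na)
  invisible(path)
}

# hom/hemi calls carry no phase; phase must be symmetric between partners.
validate_genotypes <- function(genotypes) {
  bad <- genotypes$zygosity %in% c("hom", "hemi") &
    genotypes$phase != "not_applicable"
  if (any(bad)) {
    abort(sprintf("hom/hemi genotype with phase != not_applicable: %s/%s",
                  genotypes$patient_id[bad][1], genotypes$variant_id[bad][1]))
  }
  invisible(genotypes)
}

#' Read and write variant tables (TSV form)
#'
#' `variants.tsv` columns: `variant_id`, `gene`, `chrom`, `start`, `end`,
#' `ref`, `alt`, `kind`, `profile`, `maf`, `gerp`, `splice_score`,
#' `clinical_class`, `novel`. For CNV/MEI records `ref`/`alt` are empty
#' (written as ".").
#'
#' @param path File path.
#' @return A tibble of variant records.
#' @export
read_variants <- function(path) {
  out <- read_tsv_checked(path, readr::cols(
    variant_id = readr::col_character(),
    gene = readr::col_character(),
    chrom = readr::col_character(),
    start = readr::col_integer(),
    end = readr::col_integer(),
    ref = readr::col_character(),
    alt = readr::col_character(),
    kind = readr::col_character(),
    profile = readr::col_character(),
    maf = readr::col_double(),
    gerp = readr::col_double(),
    splice_score = readr::col_double(),
    clinical_class = readr::col_character(),
    novel = readr::col_logical()
  ))
  out$chrom <- strip_chr_prefix(out$chrom)
  out$ref[is.na(out$ref)] <- ""
  out$alt[is.na(out$alt)] <- ""
  validate_variants(out)
  out
}

#' @rdname read_variants
#' @param variants Tibble of variant records.
#' @export
write_variants <- function(variants, path) {
  out <- variants
  out$ref[out$ref == ""] <- NA_character_
  out$alt[out$alt == ""] <- NA_character_
  readr::write_tsv(out, path, na = ird_na)
  invisible(path)
}

validate_variants <- function(variants) {
  assert_cols(variants, c("variant_id", "gene", "chrom", "start", "end",
                          "kind", "profile", "clinical_class"))
  assert_values(variants$kind, ird_variant_kinds, "kind")
  assert_values(variants$profile, ird_profiles, "profile")
  assert_values(variants$clinical_class, ird_clinical_classes, "clinical_class")
  if (any(variants$start > variants$end, na.rm = TRUE)) {
    bad <- variants$variant_id[which(variants$start > variants$end)][1]
    abort(sprintf("variant %s has start > end", bad))
  }
  bad_maf <- !is.na(variants$maf) & (variants$maf < 0 | variants$maf > 1)
  if (any(bad_maf)) {
    abort(sprintf("variant %s has maf outside [0, 1]",
                  variants$variant_id[bad_maf][1]))
  }
  is_cnv <- variants$kind %in% c("cnv_del", "cnv_dup")
  if (any(is_cnv & variants$profile != "structural")) {
    abort("cnv_del/cnv_dup variants must have profile = structural")
  }
  invisible(variants)
}

#' Read and write biallelic marker tracks
#'
#' `markers.tsv` columns: `patient_id`, `chrom`, `pos` (1-based), `gt`
#' (AA/AB/BB/missing). Positions must be strictly increasing within each
#' patient x chromosome track.
#'
#' @param path File path.
#' @return A tibble of marker genotypes.
#' @export
read_markers <- function(path) {
  out <- read_tsv_checked(path, readr::cols(
    patient_id = readr::col_character(),
    chrom = readr::col_character(),
    pos = readr::col_integer(),
    gt = readr::col_character()
  ))
  out$chrom <- strip_chr_prefix(out$chrom)
  assert_values(out$gt, ird_marker_genotypes, "marker genotype")
  out
}

#' @rdname read_markers
#' @param markers Tibble of marker genotypes.
#' @export
write_markers <- function(markers, path) {
  assert_cols(markers, c("patient_id", "chrom", "pos", "gt"))
  readr::write_tsv(markers, path, na = ird_na)
  invisible(path)
}

#' Read and write per-exon coverage matrices
#'
#' `coverage.tsv` is wide: index columns `gene`, `exon`, `chrom`, `start`,
#' `end` followed by one depth column per sample.
#'
#' @param path File path.
#' @return A wide tibble (one row per exon, one column per sample).
#' @export
read_coverage <- function(path) {
  out <- read_tsv_checked(path, readr::cols(
    gene = readr::col_character(),
    exon = readr::col_integer(),
    chrom = readr::col_character(),
    start = readr::col_integer(),
    end = readr::col_integer(),
    .default = readr::col_double()
  ))
  out$chrom <- strip_chr_prefix(out$chrom)
  samples <- coverage_samples(out)
  if (any(as.matrix(out[samples]) < 0, na.rm = TRUE)) {
    abort(sprintf("negative depth in %s", path))
  }
  out
}

#' @rdname read_coverage
#' @param coverage Wide coverage tibble.
#' @export
write_coverage <- function(coverage, path) {
  assert_cols(coverage, c("gene", "exon", "chrom", "start", "end"))
  readr::write_tsv(coverage, path, na = ird_na)
  invisible(path)
}

coverage_samples <- function(coverage) {
  setdiff(names(coverage), c("gene", "exon", "chrom", "start", "end"))
}

#' Read and write ROH segments as BED
#'
#' Internally ROH segments are 1-based inclusive; on disk they are BED
#' (0-based half-open). Columns written: chrom, start, end, patient_id,
#' n_markers, n_het. The conversion is lossless in both directions.
#'
#' @param path File path.
#' @return `read_roh_bed()` returns a segment tibble with `length_bp`.
#' @export
read_roh_bed <- function(path) {
  out <- read_tsv_checked(path, readr::cols(
    chrom = readr::col_character(),
    start = readr::col_integer(),
    end = readr::col_integer(),
    patient_id = readr::col_character(),
    n_markers = readr::col_integer(),
    n_het = readr::col_integer()
  ))
  tibble::tibble(
    patient_id = out$patient_id,
    chrom = strip_chr_prefix(out$chrom),
    start = out$start + 1L,  # BED 0-based -> 1-based inclusive
    end = out$end,
    n_markers = out$n_markers,
    n_het = out$n_het,
    length_bp = out$end - out$start
  )
}

#' @rdname read_roh_bed
#' @param segments ROH segment tibble (see [call_roh()]).
#' @export
write_roh_bed <- function(segments, path) {
  assert_cols(segments, c("patient_id", "chrom", "start", "end",
                          "n_markers", "n_het"))
  out <- tibble::tibble(
    chrom = segments$chrom,
    start = segments$start - 1L,  # 1-based inclusive -> BED half-open
    end = segments$end,
    patient_id = segments$patient_id,
    n_markers = segments$n_markers,
    n_het = segments$n_het
  )
  readr::write_tsv(out, path, na = ird_na)
  invisible(path)
}

#' Read a cohort from disk with cross-referencing checks
#'
#' @param paths Named list or vector with entries `patients`, `genotypes`,
#'   and either `variants` (TSV) or `vcf` (VCF v4.2 subset; see
#'   [write_vcf()]). `genotypes` may be omitted when a VCF with sample
#'   columns is given.
#' @return A list with tibbles `patients`, `variants`, `genotypes`, fully
#'   cross-referenced. A genotype call naming an unknown `variant_id` or
#'   `patient_id` is an error.
#' @export
read_cohort <- function(paths) {
  paths <- as.list(paths)
  if (is.null(paths$patients)) abort("paths$patients is required")
  patients <- read_patients(paths$patients)
  if (!is.null(paths$vcf)) {
    vcf <- read_vcf(paths$vcf)
    variants <- vcf$variants
    genotypes <- if (!is.null(paths$genotypes)) {
      read_genotypes(paths$genotypes)
    } else {
      vcf$genotypes
    }
  } else if (!is.null(paths$variants)) {
    variants <- read_variants(paths$variants)
    genotypes <- if (is.null(paths$genotypes)) {
      tibble::tibble(patient_id = character(), variant_id = character(),
                     zygosity = character(), phase_partner = character(),
                     phase = character())
    } else {
      read_genotypes(paths$genotypes)
    }
  } else {
    abort("paths must include either 'variants' or 'vcf'")
  }
  unknown_var <- setdiff(genotypes$variant_id, variants$variant_id)
  if (length(unknown_var) > 0) {
    abort(sprintf("genotype references unknown variant_id: %s",
                  unknown_var[1]))
  }
  unknown_pat <- setdiff(genotypes$patient_id, patients$patient_id)
  if (length(unknown_pat) > 0) {
    abort(sprintf("genotype references unknown patient_id: %s",
                  unknown_pat[1]))
  }
  list(patients = patients, variants = variants, genotypes = genotypes)
}

#' Write a cohort to a directory
#'
#' Writes `patients.tsv`, `genotypes.tsv`, `variants.tsv` and
#' `variants.vcf`; the inverse of [read_cohort()].
#'
#' @param cohort A list with `patients`, `variants`, `genotypes` (as
#'   returned by [simulate_cohort()] or [read_cohort()]).
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_patients(cohort$patients, file.path(dir, "patients.tsv"))
  write_genotypes(cohort$genotypes, file.path(dir, "genotypes.tsv"))
  write_variants(cohort$variants, file.path(dir, "variants.tsv"))
  if (nrow(cohort$variants) > 0) {
    write_vcf(cohort$variants, cohort$genotypes,
              file.path(dir, "variants.vcf"))
  }
  if (!is.null(cohort$truth)) {
    readr::write_tsv(cohort$truth, file.path(dir, "truth.tsv"), na = ird_na)
  }
  invisible(dir)
}
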