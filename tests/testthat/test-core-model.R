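# Readers/writers, cross-referencing, and round-trip contracts.

test_that("read_cohort handles an empty genotype table", {
  dir <- withr::local_tempdir()
  write_patients(dplyr::bind_rows(a_patient("P1"), a_patient("P2", "female")),
                 file.path(dir, "patients.tsv"))
  write_variants(a_variant()[0, ], file.path(dir, "variants.tsv"))
  write_genotypes(a_call()[0, ], file.path(dir, "genotypes.tsv"))
  co <- read_cohort(list(patients = file.path(dir, "patients.tsv"),
                         variants = file.path(dir, "variants.tsv"),
                         genotypes = file.path(dir, "genotypes.tsv")))
  expect_equal(nrow(co$patients), 2)
  expect_equal(nrow(co$variants), 0)
  expect_equal(nrow(co$genotypes), 0)
})

test_that("a synthetic cohort round-trips through the TSV formats", {
  co <- simulate_cohort(sim_config(n_index = 40, seed = 42))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(list(patients = file.path(dir, "patients.tsv"),
                           variants = file.path(dir, "variants.tsv"),
                           genotypes = file.path(dir, "genotypes.tsv")))
  expect_equal(arrange_cohort(back)$patients, arrange_cohort(co)$patients)
  expect_equal(arrange_cohort(back)$variants, arrange_cohort(co)$variants)
  expect_equal(arrange_cohort(back)$genotypes, arrange_cohort(co)$genotypes)
})

test_that("referential integrity is enforced on read", {
  dir <- withr::local_tempdir()
  write_patients(a_patient("P1"), file.path(dir, "patients.tsv"))
  write_variants(a_variant("v1"), file.path(dir, "variants.tsv"))
  write_genotypes(a_call("P1", "v_missing"), file.path(dir, "genotypes.tsv"))
  expect_error(
    read_cohort(list(patients = file.path(dir, "patients.tsv"),
                     variants = file.path(dir, "variants.tsv"),
                     genotypes = file.path(dir, "genotypes.tsv"))),
    "unknown variant_id")
  write_genotypes(a_call("P_missing", "v1"), file.path(dir, "genotypes.tsv"))
  expect_error(
    read_cohort(list(patients = file.path(dir, "patients.tsv"),
                     variants = file.path(dir, "variants.tsv"),
                     genotypes = file.path(dir, "genotypes.tsv"))),
    "unknown patient_id")
})

test_that("duplicate patient ids and malformed rows are errors naming the file", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "patients.tsv")
  write_patients(dplyr::bind_rows(a_patient("P1"), a_patient("P1")), p)
  expect_error(read_patients(p), "duplicate patient_id")
  bad <- file.path(dir, "bad.tsv")
  writeLines(c("patient_id\tchrom\tpos\tgt", "P1\t1\tnot_a_number\tAA"), bad)
  expect_error(read_markers(bad), "bad.tsv")
})

test_that("hom calls with a phase label are rejected", {
  dir <- withr::local_tempdir()
  g <- file.path(dir, "genotypes.tsv")
  readr::write_tsv(tibble::tibble(patient_id = "P1", variant_id = "v1",
                                  zygosity = "hom",
                                  phase_partner = NA_character_,
                                  phase = "in_trans"), g, na = ".")
  expect_error(read_genotypes(g), "not_applicable")
})

test_that("write_vcf encodes zygosity and symbolic CNV alleles", {
  variants <- dplyr::bind_rows(
    a_variant("v1", gene = "RHO", chrom = "3", start = 500L),
    a_variant("v2", gene = "EYS", chrom = "6", start = 65665873L,
              end = 65773340L, ref = "", alt = "", kind = "cnv_del",
              profile = "structural"))
  genotypes <- dplyr::bind_rows(a_call("P1", "v1", "hom"),
                                a_call("P1", "v2", "het"))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(variants, genotypes, path)
  lines <- readLines(path)
  data <- lines[!startsWith(lines, "#")]
  expect_length(data, 2)
  snv <- data[grepl("\tv1\t", data)]
  expect_match(snv, "1/1")
  cnv <- data[grepl("\tv2\t", data)]
  expect_match(cnv, "<DEL>")
  expect_match(cnv, "END=65773340")
  expect_match(cnv, "0/1")
})

test_that("VCF output round-trips via read_vcf on a random cohort", {
  co <- simulate_cohort(sim_config(n_index = 30, seed = 9))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(co$variants, co$genotypes, path)
  back <- read_vcf(path)
  expect_equal(dplyr::arrange(back$variants, variant_id),
               dplyr::arrange(co$variants, variant_id))
  expect_equal(dplyr::arrange(back$genotypes, patient_id, variant_id),
               dplyr::arrange(co$genotypes, patient_id, variant_id))
})

test_that("the VCF dialect is parseable by an independent VCF reader", {
  skip_if_not_installed("vcfR")
  co <- simulate_cohort(sim_config(n_index = 20, seed = 5))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(co$variants, co$genotypes, path)
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  expect_equal(nrow(v@fix), nrow(co$variants))
  ours <- dplyr::arrange(co$variants, chrom_order(chrom), start, variant_id)
  expect_equal(unname(v@fix[, "ID"]), ours$variant_id)
  expect_equal(as.integer(v@fix[, "POS"]), ours$start)
  # spot-check genotypes: every hom call reads back as 1/1
  gt <- vcfR::extract.gt(v)
  hom <- co$genotypes[co$genotypes$zygosity == "hom", ]
  for (i in seq_len(nrow(hom))) {
    expect_equal(unname(gt[hom$variant_id[i], hom$patient_id[i]]), "1/1")
  }
})

test_that("ROH segments convert to BED half-open and back losslessly", {
  segs <- dplyr::bind_rows(
    a_segment("P1", "1", 1L, 1000000L),
    a_segment("P2", "6", 30000001L, 39500000L, n_markers = 3000L,
              n_het = 5L))
  path <- withr::local_tempfile(fileext = ".bed")
  write_roh_bed(segs, path)
  bed <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(bed$start, segs$start - 1L)  # 0-based
  expect_equal(bed$end, segs$end)           # half-open end == inclusive end
  back <- read_roh_bed(path)
  expect_equal(back, segs)
})

test_that("unsortable variant records are rejected by write_vcf", {
  v <- a_variant("v1")
  v$start <- NA_integer_
  v$end <- NA_integer_
  expect_error(write_vcf(v, a_call()[0, ], withr::local_tempfile()),
               "sort")
})
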