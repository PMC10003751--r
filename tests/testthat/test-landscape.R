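# Allele counting, recurrence spectra, prevalence, zygosity, birth-cohort
# trends, and conservation invariants.

test_that("allele occurrences count hom carriers twice", {
  g <- dplyr::bind_rows(
    purrr::map(sprintf("P%d", 1:8), ~ a_call(.x, "v1", "hom")),
    list(a_call("P9", "v1", "het")))
  occ <- allele_occurrences(g, sprintf("P%d", 1:9))
  expect_equal(occ$occurrences, 17L)
  expect_equal(occ$n_index, 9L)
  # a single het carrier counts once
  occ1 <- allele_occurrences(a_call("P1", "v2"), "P1")
  expect_equal(occ1$occurrences, 1L)
  # carriers outside the diagnosed set do not count
  expect_equal(nrow(allele_occurrences(a_call("P1", "v2"), "P99")), 0)
})

test_that("recurrence spectrum supports both denominators", {
  occ <- tibble::tibble(variant_id = c("a", "b", "c"),
                        occurrences = c(1L, 1L, 2L))
  by_var <- recurrence_spectrum(occ, "distinct_variants")
  expect_equal(by_var$fraction, c(2 / 3, 1 / 3, 0))
  by_allele <- recurrence_spectrum(occ, "alleles")
  expect_equal(by_allele$fraction, c(2 / 4, 2 / 4, 0))
  expect_error(recurrence_spectrum(occ[0, ]), "no variants")
  # denominators agree when every variant occurs equally often
  eq <- tibble::tibble(variant_id = c("a", "b"), occurrences = c(2L, 2L))
  expect_equal(recurrence_spectrum(eq, "distinct_variants")$fraction,
               recurrence_spectrum(eq, "alleles")$fraction)
})

test_that("gene prevalence is computed over diagnosed patients", {
  statuses <- tibble::tibble(
    patient_id = sprintf("P%03d", 1:120),
    status = rep(c("solved", "unsolved"), c(100, 20)),
    gene = c(rep("EYS", 10), rep("ABCA4", 6), rep("USH2A", 4),
             sprintf("G%02d", 1:80), rep(NA_character_, 20)))
  out <- gene_prevalence(statuses, n_total = 120)
  expect_equal(out$percent_of_diagnosed[out$gene == "EYS"], 10)
  expect_equal(out$n_patients[out$gene == "USH2A"], 4)  # above the lump bound
  expect_equal(out$n_patients[out$gene == "other"], 80)
  expect_equal(sum(out$n_patients), 100)
  # empty diagnosed set yields an empty table
  none <- tibble::tibble(patient_id = "P1", status = "unsolved",
                         gene = NA_character_)
  expect_equal(nrow(gene_prevalence(none)), 0)
})

test_that("zygosity breakdown partitions the diagnosed set", {
  statuses <- tibble::tibble(
    patient_id = sprintf("P%d", 1:4),
    status = "solved",
    zygosity_class = c("AR_hom", "AR_comp_het", "AD_het", "XL_hemi"))
  out <- zygosity_breakdown(statuses)
  expect_equal(sort(out$fraction), rep(0.25, 4))
  all_hom <- tibble::tibble(patient_id = "P1", status = "solved",
                            zygosity_class = "AR_hom")
  expect_equal(zygosity_breakdown(all_hom)$fraction, 1)
  bad <- tibble::tibble(patient_id = "Px", status = "solved",
                        zygosity_class = NA_character_)
  expect_error(zygosity_breakdown(bad), "Px")
})

test_that("birth cohort trend bins decades and handles missing years", {
  statuses <- tibble::tibble(patient_id = sprintf("P%d", 1:6),
                             status = "solved",
                             zygosity_class = rep(c("AR_hom",
                                                    "AR_comp_het"), 3))
  pats <- dplyr::bind_rows(purrr::map(1:6, function(i)
    a_patient(sprintf("P%d", i),
              birth_year = c(1951L, 1958L, 1961L, 1968L, 1971L, 1979L)[i])))
  totals <- tibble::tibble(patient_id = sprintf("P%d", 1:6),
                           total_mb = c(40, 36, 25, 22, 10, 8))
  out <- birth_cohort_trend(pats, statuses, totals)
  expect_equal(out$decade, c(1950L, 1960L, 1970L))
  # planted decreasing autozygosity is recovered as monotone medians
  expect_true(all(diff(out$median_autozygosity_mb) < 0))
  # constant homozygous share across decades
  expect_equal(out$percent_hom, rep(50, 3))
  # single decade collapses to one row
  one <- birth_cohort_trend(pats[1:2, ], statuses[1:2, ], totals[1:2, ])
  expect_equal(nrow(one), 1)
  # all-missing years: empty table, count reported
  pats_na <- dplyr::mutate(pats, birth_year = NA_integer_)
  expect_warning(
    expect_message(none <- birth_cohort_trend(pats_na, statuses, totals),
                   "excluding 6"),
    "no patients")
  expect_equal(nrow(none), 0)
  expect_equal(attr(none, "n_missing_year"), 6)
})

test_that("per-kind counts conserve totals on a simulated cohort", {
  co <- simulate_cohort(sim_config(n_index = 120, seed = 88))
  d <- classify_cohort(co$patients, co$genotypes, co$variants)
  summ <- cohort_summary(d, co$variants, co$genotypes)
  expect_equal(sum(summ$variant_classes$distinct), nrow(summ$occurrences))
  expect_equal(sum(summ$variant_classes$occurrences),
               sum(summ$occurrences$occurrences))
  # spectrum fractions sum to one under both denominators
  expect_equal(sum(summ$recurrence_by_variant$fraction), 1)
  expect_equal(sum(summ$recurrence_by_allele$fraction), 1)
  g <- glance(summ)
  expect_equal(g$n, 120)
  expect_s3_class(tidy(summ), "tbl_df")
})

test_that("planted zygosity and recurrence fractions are recovered at cohort scale", {
  # founder plan sized so that alleles seen three or more times are
  # expected to carry ~42% of all causative allele copies
  founders <- tibble::tibble(
    gene = rep(c("EYS", "ABCA4", "USH2A", "CRB1", "RPE65", "CNGB3",
                 "MYO7A", "CDH23", "PCDH15", "CERKL", "MERTK", "SAG",
                 "TULP1", "RDH12", "LCA5"), each = 1),
    target_occurrences = rep(20L, 15),
    kind = "snv")
  three_plus <- hom_share <- numeric(3)
  for (s in 1:3) {
    cfg <- sim_config(n_index = 1000, seed = 99 + s,
                      founder_alleles = founders, private_allele_rate = 1)
    co <- simulate_cohort(cfg)
    d <- classify_cohort(co$patients, co$genotypes, co$variants)
    summ <- cohort_summary(d, co$variants, co$genotypes)
    rec <- summ$recurrence_by_allele
    three_plus[s] <- rec$fraction[rec$bin == "three_plus"]
    # planted homozygous share: hom_fraction governs solved recessive
    # cases (likely-solved genotypes are compound het by construction)
    st <- tidy(d)
    solved_rec <- st[st$status == "solved" &
                       st$zygosity_class %in% c("AR_hom", "AR_comp_het"), ]
    hom_share[s] <- mean(solved_rec$zygosity_class == "AR_hom")
  }
  # predicted allele denominator from the configuration alone: recessive
  # diagnoses carry 2 causative alleles, dominant/X-linked 1
  cfg <- sim_config(n_index = 1000, founder_alleles = founders)
  p_rec <- sum(cfg$inheritance_mix[c("isolated", "AR")]) +
    (1 - sum(cfg$inheritance_mix))
  p_diag <- cfg$status_mix[["solved"]] + cfg$status_mix[["likely_solved"]]
  expected_alleles <- 1000 * p_diag * (2 * p_rec + (1 - p_rec))
  expected_three_plus <- sum(founders$target_occurrences) / expected_alleles
  expect_lt(abs(mean(three_plus) - expected_three_plus), 0.03)
  expect_lt(abs(mean(hom_share) - cfg$hom_fraction), 0.03)
})
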