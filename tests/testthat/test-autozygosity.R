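# ROH caller vs brute-force oracle, totals, shared regions, containment.

test_that("call_roh equals the brute-force window-scan oracle on random tracks", {
  params <- roh_params(window_markers = 10, max_het_per_window = 1,
                       min_length_bp = 30000, min_markers = 5,
                       stitch_gap_bp = 15000)
  set.seed(4242)
  for (rep in 1:40) {
    n <- sample(50:500, 1)
    dens <- runif(1, 0.05, 0.5)
    planted <- if (runif(1) < 0.6) {
      a <- sample(seq_len(n - 20), 1)
      list(c(a, min(n, a + sample(10:80, 1))))
    } else {
      NULL
    }
    tr <- random_track(n, dens, planted)
    got <- call_roh(tr, params)
    want <- oracle_call_roh(tr$pos, tr$gt, params)
    if (is.null(want) || nrow(want) == 0) {
      expect_equal(nrow(got), 0, info = paste("rep", rep))
    } else {
      expect_equal(got$start, want$start, info = paste("rep", rep))
      expect_equal(got$end, want$end, info = paste("rep", rep))
      expect_equal(got$n_markers, want$n_markers, info = paste("rep", rep))
      expect_equal(got$n_het, want$n_het, info = paste("rep", rep))
    }
  }
})

test_that("degenerate tracks are handled", {
  all_het <- tibble::tibble(patient_id = "P1", chrom = "1",
                            pos = as.integer(seq(1000, 100000, 1000)),
                            gt = "AB")
  expect_equal(nrow(call_roh(all_het)), 0)
  unsorted <- tibble::tibble(patient_id = "P1", chrom = "1",
                             pos = c(5L, 1L), gt = c("AA", "AA"))
  expect_error(call_roh(unsorted), "strictly increasing")
})

test_that("a planted multi-Mb interval is recovered within 5%", {
  cfg <- sim_config()
  iv <- tibble::tibble(start = 20000001L, end = 24500000L)
  lens <- vapply(1:5, function(s) {
    set.seed(s)
    tr <- simulate_marker_track("P1", "1", iv, cfg)
    segs <- call_roh(tr)
    sum(segs$length_bp)
  }, numeric(1))
  expect_true(all(abs(lens / 4.5e6 - 1) < 0.05))
})

test_that("total autozygosity sums segments in Mb", {
  expect_equal(total_autozygosity(a_segment()[0, ]), 0)
  expect_equal(total_autozygosity(
    a_segment("P1", "1", 1L, 4500000L)), 4.5)
  expect_equal(total_autozygosity(dplyr::bind_rows(
    a_segment("P1", "1", 1L, 1000000L),
    a_segment("P1", "2", 5000001L, 6000000L))), 2.0)
  expect_error(total_autozygosity(dplyr::bind_rows(
    a_segment("P1", "1", 1L, 1000000L),
    a_segment("P1", "1", 500000L, 1500000L))), "overlap")
})

test_that("per-patient totals exclude male X segments", {
  segs <- dplyr::bind_rows(
    a_segment("P1", "X", 1L, 2000000L),
    a_segment("P1", "1", 1L, 1000000L),
    a_segment("P2", "X", 1L, 2000000L))
  pats <- dplyr::bind_rows(a_patient("P1", sex = "male"),
                           a_patient("P2", sex = "female"),
                           a_patient("P3", sex = "male"))
  tot <- autozygosity_totals(segs, pats)
  expect_equal(tot$total_mb[tot$patient_id == "P1"], 1)
  expect_equal(tot$total_mb[tot$patient_id == "P2"], 2)
  expect_equal(tot$total_mb[tot$patient_id == "P3"], 0)
})

test_that("shared_roh returns the intersection of nested segments", {
  segs <- dplyr::bind_rows(
    a_segment("P1", "6", 1L, 100L),
    a_segment("P2", "6", 10L, 90L),
    a_segment("P3", "6", 20L, 80L))
  sh <- shared_roh(segs, min_patients = 3)
  expect_equal(nrow(sh), 1)
  expect_equal(c(sh$start, sh$end), c(20L, 80L))
  expect_equal(c(sh$mcr_start, sh$mcr_end), c(20L, 80L))
  expect_equal(sh$patients[[1]], c("P1", "P2", "P3"))
  # disjoint segments share nothing
  disj <- dplyr::bind_rows(a_segment("P1", "6", 1L, 100L),
                           a_segment("P2", "6", 200L, 300L))
  expect_equal(nrow(shared_roh(disj, 2)), 0)
  expect_error(shared_roh(segs, 1), "at least 2")
  expect_error(shared_roh(a_segment("P1"), 2), "at least 2 patients")
})

test_that("shared intervals are supported by at least min_patients", {
  set.seed(7)
  segs <- purrr::map(1:12, function(i) {
    k <- sample(1:3, 1)
    starts <- sort(sample(seq(1, 5e7, 1e6), k))
    dplyr::bind_rows(purrr::map(starts, function(s)
      a_segment(sprintf("P%02d", i), "3", as.integer(s),
                as.integer(s + sample(1e6:8e6, 1)))))
  }) |> dplyr::bind_rows()
  for (k in c(2, 4, 6)) {
    sh <- shared_roh(segs, k)
    if (nrow(sh) == 0) next
    expect_true(all(sh$n_patients >= k))
    # non-overlapping output intervals
    sh <- dplyr::arrange(sh, chrom, start)
    expect_true(all(sh$start[-1] > sh$end[-nrow(sh)] | nrow(sh) == 1))
    # every reported patient's union really covers part of the interval
    for (i in seq_len(nrow(sh))) {
      for (p in sh$patients[[i]]) {
        own <- segs[segs$patient_id == p & segs$chrom == sh$chrom[i], ]
        expect_true(any(own$start <= sh$end[i] & own$end >= sh$start[i]))
      }
    }
  }
})

test_that("variant containment is exact at segment boundaries", {
  segs <- a_segment("P1", "6", 1000L, 2000L)
  v_in <- tibble::tibble(chrom = "6", start = 1500L, end = 1500L)
  v_edge <- tibble::tibble(chrom = "6", start = 2000L, end = 2000L)
  v_out <- tibble::tibble(chrom = "6", start = 2001L, end = 2001L)
  v_span <- tibble::tibble(chrom = "6", start = 1999L, end = 2001L)
  expect_true(variant_in_roh(v_in, segs))
  expect_true(variant_in_roh(v_edge, segs))
  expect_false(variant_in_roh(v_out, segs))
  expect_false(variant_in_roh(v_span, segs))
})

test_that("the cohort scan flags exactly the planted outlier homozygote", {
  cfg <- sim_config(n_index = 60, seed = 33, roh_exception_patients = 1)
  co <- simulate_cohort(cfg)
  hom <- co$truth[co$truth$zygosity_class %in% "AR_hom", ]
  # tracks only for hom patients on their causal chromosomes
  v <- co$variants[match(hom$variant_id, co$variants$variant_id), ]
  set.seed(34)
  tracks <- purrr::map2(hom$patient_id, v$chrom, function(pid, chrom) {
    iv <- co$roh_plan[co$roh_plan$patient_id == pid &
                        co$roh_plan$chrom == chrom, ]
    simulate_marker_track(pid, chrom, iv, cfg)
  }) |> dplyr::bind_rows()
  segs <- call_roh(tracks)
  causal_calls <- co$genotypes[
    paste(co$genotypes$patient_id, co$genotypes$variant_id) %in%
      paste(hom$patient_id, hom$variant_id), ]
  scan <- roh_containment_scan(causal_calls, co$variants, segs)
  outlier <- hom$patient_id[!hom$in_roh]
  expect_equal(scan$patient_id[!scan$in_roh], outlier)
})

test_that("autozygosity by genotype class uses the lower median and omits empty classes", {
  statuses <- tibble::tibble(
    patient_id = c("A", "B", "C", "D"),
    status = c("solved", "solved", "solved", "unsolved"),
    zygosity_class = c("AR_hom", "AR_comp_het", "AD_het", NA))
  totals <- tibble::tibble(patient_id = c("A", "B", "C", "D"),
                           total_mb = c(30, 12, 8, 5))
  expect_warning(out <- autozygosity_by_genotype_class(statuses, totals),
                 "XL_hemi")
  expect_equal(out$median_mb[out$class == "AR_hom"], 30)
  expect_equal(out$median_mb[out$class == "unsolved"], 5)
  # permuting patient order leaves the summary unchanged
  perm <- sample(nrow(statuses))
  expect_warning(out2 <- autozygosity_by_genotype_class(statuses[perm, ],
                                                        totals), "XL_hemi")
  expect_equal(out, out2)
  # lower-median convention on an even-sized class
  st2 <- tibble::tibble(patient_id = c("A", "B"), status = "solved",
                        zygosity_class = "AR_hom")
  tt2 <- tibble::tibble(patient_id = c("A", "B"), total_mb = c(10, 20))
  expect_warning(out3 <- autozygosity_by_genotype_class(st2, tt2))
  expect_equal(out3$median_mb, 10)
})

test_that("homozygous diagnoses carry more planted autozygosity than compound hets", {
  co <- simulate_cohort(sim_config(n_index = 400, seed = 55))
  plan_segs <- co$roh_plan |>
    dplyr::mutate(n_markers = 1000L, n_het = 0L,
                  length_bp = .data$end - .data$start + 1L)
  totals <- autozygosity_totals(plan_segs, co$patients)
  statuses <- co$truth |>
    dplyr::transmute(patient_id, status = true_status, zygosity_class)
  out <- suppressWarnings(autozygosity_by_genotype_class(statuses, totals))
  expect_gt(out$median_mb[out$class == "AR_hom"],
            out$median_mb[out$class == "AR_comp_het"])
})
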