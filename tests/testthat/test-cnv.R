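# Depth normalization, CNV calling, deletion/junction arithmetic, and
# breakpoint refinement.

ratio_fixture <- function(values, gene = "CNGB3", samples = NULL) {
  # build a ratio tibble directly: values is exon x sample matrix
  ex <- ird_exon_model(gene)[seq_len(nrow(values)), ]
  samples <- samples %||% sprintf("S%02d", seq_len(ncol(values)))
  colnames(values) <- samples
  dplyr::bind_cols(ex, tibble::as_tibble(values))
}

test_that("identical samples normalize to ratios of one", {
  ex <- ird_exon_model("CNGB3")
  depth <- matrix(100, nrow(ex), 10,
                  dimnames = list(NULL, sprintf("S%02d", 1:10)))
  cov <- dplyr::bind_cols(ex, tibble::as_tibble(depth))
  r <- normalize_depth(cov)
  expect_true(all(abs(as.matrix(r[coverage_samples(r)]) - 1) < 1e-12))
})

test_that("a genome-wide half-depth sample normalizes back to one", {
  ex <- ird_exon_model("CNGB3")
  depth <- matrix(100, nrow(ex), 10,
                  dimnames = list(NULL, sprintf("S%02d", 1:10)))
  depth[, 1] <- 50
  cov <- dplyr::bind_cols(ex, tibble::as_tibble(depth))
  r <- normalize_depth(cov)
  expect_true(all(abs(as.matrix(r[coverage_samples(r)]) - 1) < 1e-12))
})

test_that("all-zero exons are masked with a warning and cohort floor enforced", {
  ex <- ird_exon_model("CNGB3")
  depth <- matrix(100, nrow(ex), 10,
                  dimnames = list(NULL, sprintf("S%02d", 1:10)))
  depth[3, ] <- 0
  cov <- dplyr::bind_cols(ex, tibble::as_tibble(depth))
  expect_warning(r <- normalize_depth(cov), "masking")
  expect_false(3 %in% r$exon)
  expect_error(normalize_depth(cov[, 1:9]), "at least 8")
})

test_that("call_cnv reports maximal runs in each copy-state band", {
  vals <- matrix(1, 18, 10)
  expect_equal(nrow(call_cnv(ratio_fixture(vals))), 0)
  # hom del spanning exons 13-14
  vals2 <- vals
  vals2[13:14, 1] <- 0.02
  calls <- call_cnv(ratio_fixture(vals2))
  expect_equal(nrow(calls), 1)
  expect_equal(calls$copy_state, "hom_del")
  expect_equal(c(calls$first_exon, calls$last_exon), c(13L, 14L))
  expect_equal(calls$patient_id, "S01")
  # a single-exon heterozygous deletion is callable
  vals3 <- vals
  vals3[7, 4] <- 0.5
  calls3 <- call_cnv(ratio_fixture(vals3))
  expect_equal(calls3$copy_state, "het_del")
  expect_equal(c(calls3$first_exon, calls3$last_exon), c(7L, 7L))
  # duplications and in-between ("dead zone") ratios
  vals4 <- vals
  vals4[2:5, 2] <- 1.6
  vals4[9, 2] <- 0.25  # between hom and het bands: not callable
  calls4 <- call_cnv(ratio_fixture(vals4))
  expect_equal(calls4$copy_state, "dup")
  expect_equal(c(calls4$first_exon, calls4$last_exon), c(2L, 5L))
})

test_that("calls are invariant to sample column order", {
  set.seed(8)
  cfg <- sim_config()
  ex <- ird_exon_model("CNGB3")
  samples <- sprintf("S%02d", 1:12)
  carriers <- tibble::tibble(patient_id = "S05", first_exon = 10L,
                             last_exon = 12L, copy_state = "hom_del")
  cov <- simulate_coverage(ex, samples, carriers, cfg)
  shuffled <- cov[, c("gene", "exon", "chrom", "start", "end",
                      sample(samples))]
  a <- call_cnv(normalize_depth(cov))
  b <- call_cnv(normalize_depth(shuffled))
  expect_equal(dplyr::arrange(a, patient_id, gene, first_exon),
               dplyr::arrange(b, patient_id, gene, first_exon))
})

test_that("planted deletions are recovered with high sensitivity and few false calls", {
  cfg <- sim_config()
  ex <- ird_exon_model("CNGB3")
  samples <- sprintf("S%02d", 1:12)
  # events shaped like the cohort's recurrent founder deletion: two exons,
  # one homozygous and one heterozygous carrier
  carriers <- dplyr::bind_rows(
    tibble::tibble(patient_id = "S01", first_exon = 13L, last_exon = 14L,
                   copy_state = "hom_del"),
    tibble::tibble(patient_id = "S02", first_exon = 5L, last_exon = 6L,
                   copy_state = "het_del"))
  hits_hom <- hits_het <- fp <- 0L
  n_seed <- 30
  for (s in seq_len(n_seed)) {
    set.seed(1000 + s)
    calls <- call_cnv(normalize_depth(
      simulate_coverage(ex, samples, carriers, cfg)))
    hom_ok <- any(calls$patient_id == "S01" & calls$copy_state == "hom_del" &
                    calls$first_exon <= 13 & calls$last_exon >= 14)
    het_ok <- any(calls$patient_id == "S02" & calls$copy_state == "het_del" &
                    calls$first_exon <= 6 & calls$last_exon >= 5)
    hits_hom <- hits_hom + hom_ok
    hits_het <- hits_het + het_ok
    fp <- fp + sum(calls$copy_state == "hom_del" & calls$patient_id != "S01")
  }
  expect_gte(hits_hom / n_seed, 0.95)
  expect_gte(hits_het / n_seed, 0.95)
  expect_lt(fp / (n_seed * (length(samples) - 1)), 0.01)
})

test_that("deletion length matches the printed founder-deletion arithmetic", {
  dl <- deletion_length(65665873, 65773340)
  expect_equal(dl$bp, 107468)
  expect_equal(dl$kb, 107.5)
  expect_equal(deletion_length(10, 10)$bp, 1)
  expect_equal(deletion_length(1, 1000)$kb, 1.0)
  expect_error(deletion_length(100, 10), "inverted")
})

test_that("deletion length agrees with a position-enumeration oracle", {
  set.seed(123)
  for (i in 1:10000) {
    a <- sample.int(1e6, 1)
    b <- a + sample.int(3000, 1) - 1L
    expect_equal(deletion_length(a, b)$bp, length(seq.int(a, b)))
  }
})

test_that("junction product size is template minus deletion", {
  # the founder-deletion assay: 107,720 bp template across a 107,468 bp
  # deletion leaves a 252 bp junction product
  expect_equal(junction_product_size(65665853, 65773572, 65665873, 65773340),
               252)
  # zero-length deletion: product equals the template span
  expect_equal(junction_product_size(100, 400, 200, 199), 301)
  # primers adjacent to both breakpoints: product is the summed primer span
  expect_equal(junction_product_size(180, 320, 200, 300), 20 + 20)
  expect_error(junction_product_size(250, 400, 200, 300), "flank")
})

test_that("breakpoints refine to width-one intervals on step-function depth", {
  ex <- ird_exon_model("CNGB3")
  del_start <- ex$end[12] + 5000L   # inside intron 12
  del_end <- ex$start[15] - 4000L   # inside intron 14
  pos <- seq(ex$start[10] - 2000L, ex$end[17] + 2000L)
  depth <- ifelse(pos >= del_start & pos <= del_end, 0, 100)
  call <- tibble::tibble(gene = "CNGB3", first_exon = 13L, last_exon = 14L,
                         copy_state = "hom_del")
  bp <- refine_breakpoints(tibble::tibble(pos = pos, depth = depth), call, ex)
  expect_equal(c(bp$breakpoint_left_lo, bp$breakpoint_left_hi),
               c(del_start, del_start))
  expect_equal(c(bp$breakpoint_right_lo, bp$breakpoint_right_hi),
               c(del_end, del_end))
})

test_that("noisy breakpoint refinement brackets the planted breakpoints", {
  ex <- ird_exon_model("CNGB3")
  del_start <- ex$end[12] + 5000L
  del_end <- ex$start[15] - 4000L
  pos <- seq(ex$start[11], ex$end[16])
  inside <- pos >= del_start & pos <= del_end
  n_hit <- 0L
  n_seed <- 40
  for (s in seq_len(n_seed)) {
    set.seed(2000 + s)
    depth <- rnbinom(length(pos), size = 20, mu = ifelse(inside, 0, 150))
    call <- tibble::tibble(gene = "CNGB3", first_exon = 13L,
                           last_exon = 14L, copy_state = "hom_del")
    bp <- refine_breakpoints(tibble::tibble(pos = pos, depth = depth),
                             call, ex)
    ok <- bp$breakpoint_left_lo <= del_start &
      del_start <= bp$breakpoint_left_hi &
      bp$breakpoint_right_lo <= del_end & del_end <= bp$breakpoint_right_hi
    n_hit <- n_hit + ok
  }
  expect_gte(n_hit / n_seed, 0.95)
})

test_that("duplication breakpoints bracket the gain region", {
  ex <- ird_exon_model("CNGB3")
  gain_start <- ex$end[6] + 1000L
  gain_end <- ex$start[9] - 1000L
  pos <- seq(ex$start[4], ex$end[11])
  depth <- ifelse(pos >= gain_start & pos <= gain_end, 150, 100)
  call <- tibble::tibble(gene = "CNGB3", first_exon = 7L, last_exon = 8L,
                         copy_state = "dup")
  bp <- refine_breakpoints(tibble::tibble(pos = pos, depth = depth), call, ex)
  expect_true(bp$breakpoint_left_lo <= gain_start &
                gain_start <= bp$breakpoint_left_hi)
  expect_true(bp$breakpoint_right_lo <= gain_end &
                gain_end <= bp$breakpoint_right_hi)
})
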