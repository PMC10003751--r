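# Exon-resolution CNV calling from depth ratios, breakpoint-interval
# refinement from per-base depth, and deletion/junction arithmetic.

#' CNV-calling parameters
#'
#' Ratio bands for copy-state assignment (relative to the leave-one-out
#' cohort median after library-size normalization): homozygous deletion at
#' or below 0.15, heterozygous deletion within 0.35-0.65, duplication at or
#' above 1.35. Events have a minimal size of one exon and no maximal size.
#'
#' @param hom_del_ratio_max Upper ratio bound for homozygous deletions.
#' @param het_del_band Two-element ratio band for heterozygous deletions.
#' @param dup_ratio_min Lower ratio bound for duplications.
#' @param min_exons Minimum exons per call (default 1).
#' @param min_reference_samples Minimum cohort size for normalization.
#' @return A validated list of class `cnv_params`.
#' @export
cnv_params <- function(hom_del_ratio_max = 0.15,
                       het_del_band = c(0.35, 0.65),
                       dup_ratio_min = 1.35,
                       min_exons = 1,
                       min_reference_samples = 8) {
  if (length(het_del_band) != 2 || het_del_band[1] >= het_del_band[2]) {
    abort("het_del_band must be an ordered pair")
  }
  if (hom_del_ratio_max >= het_del_band[1] ||
      het_del_band[2] >= dup_ratio_min) {
    abort("ratio bands must be ordered and non-overlapping")
  }
  structure(list(hom_del_ratio_max = hom_del_ratio_max,
                 het_del_band = het_del_band,
                 dup_ratio_min = dup_ratio_min,
                 min_exons = as.integer(min_exons),
                 min_reference_samples = as.integer(min_reference_samples)),
            class = "cnv_params")
}

#' Normalize an exon coverage matrix to depth ratios
#'
#' Depths are first library-size normalized (each sample scaled so its
#' total matches the cohort median total); each (exon, sample) entry is
#' then divided by the median of the *other* samples at that exon
#' (leave-one-out cohort reference). Exons with zero depth across the whole
#' cohort are masked with a warning.
#'
#' @param coverage Wide coverage tibble (see [read_coverage()]).
#' @param params A [cnv_params()] (minimum cohort size).
#' @return The coverage tibble with depths replaced by ratios (masked exons
#'   removed).
#' @export
normalize_depth <- function(coverage, params = cnv_params()) {
  samples <- coverage_samples(coverage)
  if (length(samples) < params$min_reference_samples) {
    abort(sprintf("normalization needs at least %d samples (got %d)",
                  params$min_reference_samples, length(samples)))
  }
  depth <- as.matrix(coverage[samples])
  dead <- rowSums(depth) == 0
  if (any(dead)) {
    warn(sprintf("masking %d exon(s) with zero depth across the cohort",
                 sum(dead)))
    coverage <- coverage[!dead, , drop = FALSE]
    depth <- depth[!dead, , drop = FALSE]
  }
  # library-size factors by two-pass median-of-ratios: a totals-based
  # factor would be deflated by a carried deletion, and even the plain
  # median rank-shifts when an event spans a sizeable share of the panel,
  # so exons that look copy-altered after the first pass are masked and
  # the factor re-estimated on the remainder
  ref_row <- apply(depth, 1, median)
  usable <- ref_row > 0
  size_of <- function(d, keep) {
    s <- median(d[keep] / ref_row[keep])
    if (!is.finite(s) || s == 0) 1 else s
  }
  size <- vapply(seq_len(ncol(depth)), function(j) {
    d <- depth[, j]
    s0 <- size_of(d, usable)
    clean <- usable & d / (ref_row * s0) > 0.75 & d / (ref_row * s0) < 1.25
    if (sum(clean) >= 3) size_of(d, clean) else s0
  }, numeric(1))
  depth <- sweep(depth, 2, size, `/`)
  n_s <- ncol(depth)
  ratios <- depth
  for (j in seq_len(n_s)) {
    ref <- apply(depth[, -j, drop = FALSE], 1, median)
    ratios[, j] <- ifelse(ref > 0, depth[, j] / ref, NA_real_)
  }
  dplyr::bind_cols(coverage[, c("gene", "exon", "chrom", "start", "end")],
                   tibble::as_tibble(ratios))
}

#' Call copy-number events from depth ratios
#'
#' Assigns each (exon, sample) ratio to a copy-state band and reports
#' maximal runs of consecutive exons in the same non-diploid state;
#' single-exon events are allowed and there is no maximum span.
#'
#' @param ratios Normalized ratio tibble from [normalize_depth()].
#' @param params A [cnv_params()].
#' @return A tibble of calls: `patient_id`, `gene`, `chrom`, `first_exon`,
#'   `last_exon`, `n_exons`, `copy_state` (hom_del/het_del/dup), `start`,
#'   `end` (bp of the outermost affected exons), `mean_ratio`.
#' @export
call_cnv <- function(ratios, params = cnv_params()) {
  samples <- coverage_samples(ratios)
  long <- ratios |>
    tidyr::pivot_longer(dplyr::all_of(samples), names_to = "patient_id",
                        values_to = "ratio") |>
    dplyr::mutate(state = dplyr::case_when(
      is.na(.data$ratio) ~ "normal",
      .data$ratio <= params$hom_del_ratio_max ~ "hom_del",
      .data$ratio >= params$het_del_band[1] &
        .data$ratio <= params$het_del_band[2] ~ "het_del",
      .data$ratio >= params$dup_ratio_min ~ "dup",
      TRUE ~ "normal"))
  runs <- long |>
    dplyr::group_by(.data$patient_id, .data$gene) |>
    dplyr::arrange(.data$exon, .by_group = TRUE) |>
    dplyr::mutate(run = cumsum(.data$state !=
                                 dplyr::lag(.data$state,
                                            default = "__none__"))) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$state != "normal")
  if (nrow(runs) == 0) {
    return(tibble::tibble(patient_id = character(), gene = character(),
                          chrom = character(), first_exon = integer(),
                          last_exon = integer(), n_exons = integer(),
                          copy_state = character(), start = integer(),
                          end = integer(), mean_ratio = double()))
  }
  calls <- runs |>
    dplyr::group_by(.data$patient_id, .data$gene, .data$chrom, .data$run,
                    .data$state) |>
    dplyr::summarise(first_exon = min(.data$exon),
                     last_exon = max(.data$exon),
                     n_exons = dplyr::n(),
                     start = min(.data$start), end = max(.data$end),
                     mean_ratio = mean(.data$ratio), .groups = "drop") |>
    dplyr::filter(.data$n_exons >= params$min_exons) |>
    dplyr::select("patient_id", "gene", "chrom", "first_exon", "last_exon",
                  "n_exons", copy_state = "state", "start", "end",
                  "mean_ratio")
  dplyr::arrange(calls, .data$patient_id, .data$gene, .data$first_exon)
}

#' Genomic deletion length from breakpoint coordinates
#'
#' Both coordinates are 1-based inclusive, so the length is
#' `g_end - g_start + 1`; the kb value rounds half-up to one decimal.
#'
#' @param g_start,g_end Deletion start/end in genomic coordinates.
#' @return A tibble with `bp` and `kb` columns (vectorized).
#' @examples
#' deletion_length(65665873, 65773340)  # 107468 bp = 107.5 kb
#' @export
deletion_length <- function(g_start, g_end) {
  if (any(g_start > g_end)) abort("inverted interval: g_start > g_end")
  bp <- g_end - g_start + 1
  tibble::tibble(bp = bp, kb = round_half_up(bp / 1000, 1))
}

#' Junction-PCR product size across a deletion
#'
#' The amplicon from primers flanking a deletion equals the undeleted
#' template span minus the deleted length: with the left primer's 5' start
#' and the right primer's 3' end on the reference, the template is
#' `right_primer_end - left_primer_start + 1` bp.
#'
#' @param left_primer_start 5'-most genomic coordinate of the left primer.
#' @param right_primer_end 3'-most genomic coordinate of the right primer.
#' @param del_start,del_end Deletion interval (1-based inclusive). Use
#'   `del_end = del_start - 1` for a zero-length deletion.
#' @return Product size in bp. Primers inside the deletion, or a
#'   non-positive product, are errors.
#' @export
junction_product_size <- function(left_primer_start, right_primer_end,
                                  del_start, del_end) {
  if (del_end < del_start - 1) abort("inverted deletion interval")
  if (left_primer_start >= del_start || right_primer_end <= del_end) {
    abort("primers must flank the deletion entirely")
  }
  template <- right_primer_end - left_primer_start + 1
  product <- template - (del_end - del_start + 1)
  if (product <= 0) abort("non-positive product size")
  product
}

# thresholds (as fractions of the flanking median) delimiting the
# outside/inside depth states of each copy state
breakpoint_thresholds <- function(copy_state) {
  switch(copy_state,
         hom_del = list(outer = function(x, m) x >= 0.5 * m,
                        inner = function(x, m) x < 0.15 * m),
         het_del = list(outer = function(x, m) x >= 0.85 * m,
                        inner = function(x, m) x <= 0.65 * m),
         dup = list(outer = function(x, m) x <= 1.1 * m,
                    inner = function(x, m) x >= 1.35 * m),
         abort(sprintf("unknown copy state: %s", copy_state)))
}

running_median <- function(x, k) {
  if (k <= 1 || length(x) < k) return(x)
  stats::runmed(x, k, endrule = "keep")
}

#' Refine CNV breakpoints from per-base depth
#'
#' For each side of a called event, locates the depth transition inside the
#' flanking intron: the breakpoint uncertainty interval runs from just
#' after the last position still at the flanking copy state (depth at or
#' above 50% of the flanking median, for a homozygous deletion) to the
#' first position clearly inside the event (below 15%). Depth is smoothed
#' with a running median before thresholding. If no transition is found the
#' whole intron is returned as the uncertainty interval.
#'
#' @param per_base_depth Tibble with `pos`, `depth` covering the gene.
#' @param call One row of [call_cnv()] output (uses `first_exon`,
#'   `last_exon`, `copy_state`).
#' @param gene_model Exon tibble for the gene ([ird_exon_model()]).
#' @param smooth_k Running-median window (odd; default 101).
#' @return A one-row tibble: `breakpoint_left_lo`, `breakpoint_left_hi`,
#'   `breakpoint_right_lo`, `breakpoint_right_hi` (uncertainty bounds, bp).
#' @export
refine_breakpoints <- function(per_base_depth, call, gene_model,
                               smooth_k = 101) {
  ex <- dplyr::arrange(gene_model[gene_model$gene == call$gene, ], .data$exon)
  if (nrow(ex) == 0) abort(sprintf("gene %s not in gene model", call$gene))
  # flanking introns (fall back to the gene edge for terminal exons)
  left_lo <- if (call$first_exon > 1) ex$end[call$first_exon - 1] + 1L
             else min(per_base_depth$pos)
  left_hi <- ex$start[call$first_exon] - 1L
  right_lo <- ex$end[call$last_exon] + 1L
  right_hi <- if (call$last_exon < nrow(ex)) ex$start[call$last_exon + 1] - 1L
              else max(per_base_depth$pos)

  pbd <- dplyr::arrange(per_base_depth, .data$pos)
  sm <- running_median(pbd$depth, smooth_k)
  outside <- pbd$pos < left_lo | pbd$pos > right_hi
  m <- median(pbd$depth[outside])
  if (!is.finite(m) || m <= 0) m <- median(pbd$depth)
  th <- breakpoint_thresholds(call$copy_state)

  side <- function(lo, hi, from_left) {
    idx <- which(pbd$pos >= lo & pbd$pos <= hi)
    if (length(idx) == 0) return(c(lo, hi))
    outer_ok <- th$outer(sm[idx], m)
    inner_ok <- th$inner(sm[idx], m)
    if (from_left) {
      l <- if (any(outer_ok)) max(which(outer_ok)) else NA
      r <- if (!is.na(l)) {
        after <- which(inner_ok & seq_along(idx) > l)
        if (length(after)) after[1] else NA
      } else NA
      if (is.na(l) || is.na(r)) return(c(lo, hi))
      c(pbd$pos[idx[l]] + 1L, pbd$pos[idx[r]])
    } else {
      # mirror: scanning right-to-left, outer state lies right of the event
      r <- if (any(outer_ok)) min(which(outer_ok)) else NA
      l <- if (!is.na(r)) {
        before <- which(inner_ok & seq_along(idx) < r)
        if (length(before)) before[length(before)] else NA
      } else NA
      if (is.na(l) || is.na(r)) return(c(lo, hi))
      c(pbd$pos[idx[l]], pbd$pos[idx[r]] - 1L)
    }
  }
  bl <- side(left_lo, left_hi, from_left = TRUE)
  br <- side(right_lo, right_hi, from_left = FALSE)
  tibble::tibble(breakpoint_left_lo = bl[1], breakpoint_left_hi = bl[2],
                 breakpoint_right_lo = br[1], breakpoint_right_hi = br[2])
}
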