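# Runs-of-homozygosity calling from biallelic marker tracks, per-genome
# autozygosity totals, cross-patient shared-ROH detection with a minimal
# critical region, and ROH-containment checks for homozygous variants.

#' ROH-calling parameters
#'
#' Defaults are tuned to recover Mb-scale autozygous segments from tracks at
#' ~3 kb marker spacing with ~0.2% genotyping error: windows of 50 markers
#' tolerating 1 heterozygous call, segments of at least 1 Mb and 25 markers,
#' and stitching of segments separated by less than 500 kb (so isolated
#' genotyping errors do not fragment a long run).
#'
#' @param window_markers Sliding-window width, in markers.
#' @param max_het_per_window Maximum heterozygous calls tolerated in any
#'   window.
#' @param min_length_bp Minimum reported segment length (bp).
#' @param min_markers Minimum markers per reported segment.
#' @param stitch_gap_bp Segments separated by less than this many bp merge.
#' @return A validated list of class `roh_params`.
#' @export
roh_params <- function(window_markers = 50, max_het_per_window = 1,
                       min_length_bp = 1e6, min_markers = 25,
                       stitch_gap_bp = 5e5) {
  vals <- c(window_markers, max_het_per_window, min_length_bp, min_markers,
            stitch_gap_bp)
  if (any(vals <= 0)) abort("all ROH parameters must be positive")
  structure(list(window_markers = as.integer(window_markers),
                 max_het_per_window = as.integer(max_het_per_window),
                 min_length_bp = min_length_bp,
                 min_markers = as.integer(min_markers),
                 stitch_gap_bp = stitch_gap_bp),
            class = "roh_params")
}

# Maximal marker-index runs in which every window of W consecutive markers
# (clipped to the run) holds at most H heterozygous calls. Equivalent
# characterization used here: a run is valid iff it contains no H+1 het
# markers whose index span is below W; each violating het group (p, q)
# forces a break, and because the p are strictly increasing every violation
# fires in the greedy left-to-right emission, so the runs vectorize.
roh_candidate_runs <- function(is_het, W, H) {
  n <- length(is_het)
  if (n == 0) return(matrix(integer(), ncol = 2))
  hets <- which(is_het)
  k <- length(hets)
  if (k > H) {
    p <- hets[seq_len(k - H)]
    q <- hets[(H + 1L):k]
    viol <- which(q - p < W)
    cbind(c(1L, p[viol] + 1L), c(q[viol] - 1L, n))
  } else {
    cbind(1L, n)
  }
}

call_roh_one_track <- function(pos, gt, params) {
  if (is.unsorted(pos, strictly = TRUE)) {
    abort("marker positions must be strictly increasing within a track")
  }
  is_het <- gt == "AB"
  is_hom <- gt %in% c("AA", "BB")
  runs <- roh_candidate_runs(is_het, params$window_markers,
                             params$max_het_per_window)
  # trim boundaries to the outermost homozygous markers
  het_cum <- cumsum(is_het)
  homs <- which(is_hom)
  if (length(homs) == 0) return(NULL)
  a2 <- homs[findInterval(runs[, 1] - 1L, homs) + 1L]
  b2 <- homs[pmax(findInterval(runs[, 2], homs), 1L)]
  ok <- !is.na(a2) & !is.na(b2) & a2 <= runs[, 2] & b2 >= runs[, 1] &
    a2 <= b2
  # only runs individually supported by min_markers enter the stitching
  # stage; this keeps short background runs from chaining across stitch
  # gaps while split pieces of a genuine long segment still merge
  ok <- ok & (b2 - a2 + 1L >= params$min_markers)
  if (!any(ok)) return(NULL)
  segs <- cbind(a2[ok], b2[ok])
  # stitch runs separated by small genomic gaps (isolated het clusters)
  merged <- list()
  cur <- segs[1, ]
  for (r in seq_len(nrow(segs))[-1]) {
    gap <- pos[segs[r, 1]] - pos[cur[2]]
    if (gap < params$stitch_gap_bp) {
      cur[2] <- segs[r, 2]
    } else {
      merged[[length(merged) + 1L]] <- cur
      cur <- segs[r, ]
    }
  }
  merged[[length(merged) + 1L]] <- cur
  merged <- do.call(rbind, merged)
  het_cum0 <- c(0L, het_cum)  # 1-padded so a segment starting at marker 1 indexes cleanly
  out <- tibble::tibble(
    start = pos[merged[, 1]],
    end = pos[merged[, 2]],
    n_markers = merged[, 2] - merged[, 1] + 1L,
    n_het = het_cum0[merged[, 2] + 1L] - het_cum0[merged[, 1]],
    length_bp = pos[merged[, 2]] - pos[merged[, 1]] + 1L
  )
  out[out$length_bp >= params$min_length_bp &
        out$n_markers >= params$min_markers, ]
}

#' Call runs of homozygosity from a marker track
#'
#' Segments are maximal marker runs in which every sliding window of
#' `window_markers` markers holds at most `max_het_per_window` heterozygous
#' calls; boundaries are reported at the outermost homozygous markers,
#' adjacent runs closer than `stitch_gap_bp` are merged, and the result is
#' filtered by `min_length_bp` and `min_markers`.
#'
#' @param track Marker-track tibble (`patient_id`, `chrom`, `pos`, `gt`);
#'   may hold several patients/chromosomes. Unsorted positions within a
#'   track are an error.
#' @param params A [roh_params()].
#' @return A segment tibble: `patient_id`, `chrom`, `start`, `end`,
#'   `n_markers`, `n_het`, `length_bp`, sorted by coordinate.
#' @export
call_roh <- function(track, params = roh_params()) {
  assert_cols(track, c("patient_id", "chrom", "pos", "gt"))
  assert_values(track$gt, ird_marker_genotypes, "marker genotype")
  out <- track |>
    dplyr::group_by(.data$patient_id, .data$chrom) |>
    dplyr::group_map(function(g, key) {
      segs <- call_roh_one_track(g$pos, g$gt, params)
      if (is.null(segs) || nrow(segs) == 0) return(NULL)
      dplyr::bind_cols(key[rep(1, nrow(segs)), ], segs)
    }) |>
    dplyr::bind_rows()
  if (nrow(out) == 0) {
    return(tibble::tibble(patient_id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          n_markers = integer(), n_het = integer(),
                          length_bp = integer()))
  }
  dplyr::arrange(out, .data$patient_id, chrom_order(.data$chrom), .data$start)
}

#' Total autozygosity of a set of segments
#'
#' @param segments Segment tibble; segments must be non-overlapping within
#'   each patient x chromosome (overlap is an error).
#' @return Total length in Mb (a single number).
#' @examples
#' total_autozygosity(tibble::tibble(
#'   patient_id = "P1", chrom = "1", start = 1L, end = 4500000L))
#' @export
total_autozygosity <- function(segments) {
  if (nrow(segments) == 0) return(0)
  check_no_overlap(segments)
  sum(segments$end - segments$start + 1) / 1e6
}

check_no_overlap <- function(segments) {
  segments |>
    dplyr::group_by(.data$patient_id, .data$chrom) |>
    dplyr::group_walk(function(g, key) {
      g <- dplyr::arrange(g, .data$start)
      if (nrow(g) > 1 && any(g$start[-1] <= g$end[-nrow(g)])) {
        abort(sprintf("overlapping segments for patient %s chrom %s",
                      key$patient_id, key$chrom))
      }
    })
  invisible(segments)
}

#' Per-patient autozygosity totals
#'
#' Sums segment lengths per genome. The X chromosome is excluded for male
#' patients when `patients` (with a `sex` column) is supplied: hemizygosity
#' is not autozygosity.
#'
#' @param segments Segment tibble.
#' @param patients Optional patient tibble; patients without segments get a
#'   zero total, and male X segments are excluded.
#' @return A tibble: `patient_id`, `total_mb`.
#' @export
autozygosity_totals <- function(segments, patients = NULL) {
  segs <- segments
  if (!is.null(patients) && "sex" %in% names(patients)) {
    males <- patients$patient_id[patients$sex == "male"]
    segs <- segs[!(segs$patient_id %in% males & segs$chrom == "X"), ]
  }
  check_no_overlap(segs)
  totals <- segs |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(total_mb = sum(.data$end - .data$start + 1) / 1e6,
                     .groups = "drop")
  if (!is.null(patients)) {
    totals <- patients |>
      dplyr::select("patient_id") |>
      dplyr::left_join(totals, by = "patient_id") |>
      dplyr::mutate(total_mb = dplyr::coalesce(.data$total_mb, 0))
  }
  totals
}

#' Shared ROH regions across patients and the minimal critical region
#'
#' Sweep-line over per-patient segment unions: returns the maximal
#' intervals covered by the ROHs of at least `min_patients` patients. For
#' each interval, the minimal critical region is the intersection of the
#' supporting patients' covering segments - the interval that localizes a
#' shared founder haplotype.
#'
#' @param segments Segment tibble for two or more patients.
#' @param min_patients Minimum supporting patients (at least 2).
#' @return A tibble: `chrom`, `start`, `end`, `length_bp`, `n_patients`,
#'   `patients` (list column), `mcr_start`, `mcr_end`, `mcr_length_bp`.
#' @export
shared_roh <- function(segments, min_patients) {
  if (min_patients < 2) abort("min_patients must be at least 2")
  if (length(unique(segments$patient_id)) < 2) {
    abort("shared_roh requires segments from at least 2 patients")
  }
  empty <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), length_bp = integer(),
                          n_patients = integer(), patients = list(),
                          mcr_start = integer(), mcr_end = integer(),
                          mcr_length_bp = integer())
  # union segments per patient x chromosome first so one patient never
  # contributes coverage twice
  un <- segments |>
    dplyr::group_by(.data$patient_id, .data$chrom) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(run = cumsum(.data$start >
                                 dplyr::lag(cummax(.data$end + 1L),
                                            default = 0L))) |>
    dplyr::group_by(.data$patient_id, .data$chrom, .data$run) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     .groups = "drop")

  out <- un |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_map(function(g, key) {
      events <- rbind(cbind(g$start, 1L), cbind(g$end + 1L, -1L))
      events <- events[order(events[, 1]), , drop = FALSE]
      pos <- unique(events[, 1])
      cov <- cumsum(vapply(split(events[, 2], match(events[, 1], pos)),
                           sum, numeric(1))[as.character(seq_along(pos))])
      hit <- which(cov >= min_patients)
      if (length(hit) == 0) return(NULL)
      # maximal covered intervals: consecutive qualifying spans concatenate
      brk <- c(0, which(diff(hit) != 1), length(hit))
      purrr::map(seq_len(length(brk) - 1), function(i) {
        idx <- hit[(brk[i] + 1):brk[i + 1]]
        start <- pos[idx[1]]
        end <- pos[idx[length(idx)] + 1] - 1L
        sup <- g[g$start <= end & g$end >= start, ]
        sup_best <- sup |>
          dplyr::mutate(ov = pmin(.data$end, .env$end) -
                          pmax(.data$start, .env$start)) |>
          dplyr::group_by(.data$patient_id) |>
          dplyr::slice_max(.data$ov, n = 1, with_ties = FALSE) |>
          dplyr::ungroup()
        tibble::tibble(
          chrom = key$chrom, start = as.integer(start), end = as.integer(end),
          length_bp = as.integer(end - start + 1),
          n_patients = nrow(sup_best),
          patients = list(sort(sup_best$patient_id)),
          mcr_start = as.integer(max(sup_best$start)),
          mcr_end = as.integer(min(sup_best$end)),
          mcr_length_bp = as.integer(min(sup_best$end) -
                                       max(sup_best$start) + 1))
      }) |> dplyr::bind_rows()
    }) |>
    dplyr::bind_rows()
  if (nrow(out) == 0) return(empty)
  dplyr::arrange(out, chrom_order(.data$chrom), .data$start)
}

#' Is a variant contained in a run of homozygosity?
#'
#' @param variants Tibble with `chrom`, `start`, `end` (one or more rows).
#' @param segments Segment tibble for the *same patient*.
#' @return Logical vector: `TRUE` where the variant interval is fully
#'   contained in some segment.
#' @export
variant_in_roh <- function(variants, segments) {
  vapply(seq_len(nrow(variants)), function(i) {
    s <- segments[segments$chrom == variants$chrom[i], ]
    any(s$start <= variants$start[i] & variants$end[i] <= s$end)
  }, logical(1))
}

#' Flag homozygous causal calls outside ROHs across a cohort
#'
#' @param genotypes Genotype-call tibble (hom calls are checked).
#' @param variants Variant tibble.
#' @param segments Cohort segment tibble (all patients).
#' @return A tibble `patient_id`, `variant_id`, `in_roh` with one row per
#'   homozygous call.
#' @export
roh_containment_scan <- function(genotypes, variants, segments) {
  hom <- genotypes[genotypes$zygosity == "hom", ]
  if (nrow(hom) == 0) {
    return(tibble::tibble(patient_id = character(), variant_id = character(),
                          in_roh = logical()))
  }
  hom <- dplyr::inner_join(hom, variants[, c("variant_id", "chrom",
                                             "start", "end")],
                           by = "variant_id")
  hom$in_roh <- vapply(seq_len(nrow(hom)), function(i) {
    segs <- segments[segments$patient_id == hom$patient_id[i], ]
    variant_in_roh(hom[i, ], segs)
  }, logical(1))
  hom[, c("patient_id", "variant_id", "in_roh")]
}

#' Autozygosity by genotype class
#'
#' Summarizes per-genome autozygosity totals by the diagnosed genotype
#' class (AR_hom, AR_comp_het, AD_het, XL_hemi, and "unsolved" for
#' undiagnosed patients). Medians use the lower-median convention.
#'
#' @param statuses Diagnosis tibble (`patient_id`, `status`,
#'   `zygosity_class`), e.g. from [classify_cohort()].
#' @param totals Per-patient autozygosity totals ([autozygosity_totals()]).
#' @return A tibble: `class`, `n`, `q1`, `median_mb`, `q3`. Classes with no
#'   patients are omitted with a warning.
#' @export
autozygosity_by_genotype_class <- function(statuses, totals) {
  if (inherits(statuses, "ird_diagnosis")) statuses <- statuses$statuses
  assert_cols(statuses, c("patient_id", "status", "zygosity_class"))
  dat <- statuses |>
    dplyr::mutate(class = dplyr::if_else(
      .data$status %in% c("solved", "likely_solved") &
        !is.na(.data$zygosity_class),
      .data$zygosity_class, "unsolved")) |>
    dplyr::inner_join(totals, by = "patient_id")
  out <- dat |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(n = dplyr::n(),
                     q1 = unname(quantile(.data$total_mb, 0.25)),
                     median_mb = lower_median(.data$total_mb),
                     q3 = unname(quantile(.data$total_mb, 0.75)),
                     .groups = "drop")
  expected <- c("AR_hom", "AR_comp_het", "AD_het", "XL_hemi", "unsolved")
  absent <- setdiff(expected, out$class)
  if (length(absent) > 0) {
    warn(sprintf("no patients in genotype class(es): %s",
                 paste(absent, collapse = ", ")))
  }
  dplyr::arrange(out, match(.data$class, c(expected, "XL_het_female")))
}
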