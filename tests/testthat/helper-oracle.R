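# Independent brute-force oracle for ROH calling: literal sliding-window
# validity checks and a naive greedy scan, followed by plainly-written
# trim / support-filter / stitch / final-filter stages. Kept free of the
# het-index arithmetic the package implementation uses.

oracle_valid <- function(is_het, a, b, W, H) {
  len <- b - a + 1
  if (len <= W) return(sum(is_het[a:b]) <= H)
  for (i in a:(b - W + 1)) {
    if (sum(is_het[i:(i + W - 1)]) > H) return(FALSE)
  }
  TRUE
}

oracle_runs <- function(is_het, W, H) {
  n <- length(is_het)
  runs <- list()
  a <- 1
  while (a <= n) {
    if (!oracle_valid(is_het, a, a, W, H)) {
      a <- a + 1
      next
    }
    b <- a
    while (b < n && oracle_valid(is_het, a, b + 1, W, H)) b <- b + 1
    runs[[length(runs) + 1]] <- c(a, b)
    if (b == n) break
    a2 <- a + 1
    while (a2 <= b + 1 && !oracle_valid(is_het, a2, b + 1, W, H)) {
      a2 <- a2 + 1
    }
    a <- a2
  }
  runs
}

oracle_call_roh <- function(pos, gt, params) {
  is_het <- gt == "AB"
  is_hom <- gt %in% c("AA", "BB")
  runs <- oracle_runs(is_het, params$window_markers,
                      params$max_het_per_window)
  # trim to outermost homozygous markers; drop unsupported runs
  segs <- list()
  for (r in runs) {
    inside <- r[1]:r[2]
    hom_at <- inside[is_hom[inside]]
    if (length(hom_at) == 0) next
    a <- min(hom_at)
    b <- max(hom_at)
    if (b - a + 1 < params$min_markers) next
    segs[[length(segs) + 1]] <- c(a, b)
  }
  if (length(segs) == 0) return(NULL)
  # stitch across small genomic gaps
  merged <- list(segs[[1]])
  for (s in segs[-1]) {
    last <- merged[[length(merged)]]
    if (pos[s[1]] - pos[last[2]] < params$stitch_gap_bp) {
      merged[[length(merged)]] <- c(last[1], s[2])
    } else {
      merged[[length(merged) + 1]] <- s
    }
  }
  out <- do.call(rbind, lapply(merged, function(s) {
    data.frame(start = pos[s[1]], end = pos[s[2]],
               n_markers = s[2] - s[1] + 1,
               n_het = sum(is_het[s[1]:s[2]]),
               length_bp = pos[s[2]] - pos[s[1]] + 1)
  }))
  out[out$length_bp >= params$min_length_bp &
        out$n_markers >= params$min_markers, , drop = FALSE]
}

random_track <- function(n, het_density, planted = NULL, spacing = 1000) {
  pos <- seq.int(spacing, n * spacing, by = spacing)
  het <- runif(n) < het_density
  if (!is.null(planted)) {
    for (p in planted) het[p[1]:p[2]] <- runif(p[2] - p[1] + 1) < 0.01
  }
  gt <- ifelse(het, "AB", ifelse(runif(n) < 0.5, "AA", "BB"))
  gt[runif(n) < 0.02] <- "missing"
  tibble::tibble(patient_id = "T", chrom = "1", pos = as.integer(pos),
                 gt = gt)
}
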