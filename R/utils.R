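# Shared vocabularies. Every factor-like column in the pipeline is plain
# character validated against one of these sets.
ird_variant_kinds <- c("snv", "indel", "cnv_del", "cnv_dup", "mei")
ird_profiles <- c("missense", "nonsense", "frameshift", "inframe_indel",
                  "splice_region", "synonymous", "start_loss", "structural")
ird_clinical_classes <- c("P", "LP", "VUS", "LB", "B")
ird_zygosities <- c("het", "hom", "hemi")
ird_phases <- c("in_trans", "in_cis", "unknown", "not_applicable")
ird_inheritances <- c("isolated", "AR", "AD", "XL", "unknown")
ird_sexes <- c("male", "female")
ird_statuses <- c("unsolved", "uncertain", "likely_solved", "solved")
ird_marker_genotypes <- c("AA", "AB", "BB", "missing")

# Diagnostic statuses ordered for the monotone-upgrade contract:
# unsolved < uncertain < likely_solved < solved.
status_rank <- function(status) match(status, ird_statuses)

#' Round half away from zero
#'
#' Report-table rounding convention: halves round up in magnitude (0.5 -> 1),
#' unlike [base::round()]'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits to keep.
#' @return Numeric vector rounded half-up.
#' @examples
#' round_half_up(75.65, 0)   # 76
#' round_half_up(107.468, 1) # 107.5
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

assert_cols <- function(df, cols, what = deparse(substitute(df))) {
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing_cols, collapse = ", ")))
  }
  invisible(df)
}

assert_values <- function(x, allowed, what) {
  bad <- setdiff(unique(x[!is.na(x)]), allowed)
  if (length(bad) > 0) {
    abort(sprintf("invalid %s value(s): %s (allowed: %s)",
                  what, paste(bad, collapse = ", "),
                  paste(allowed, collapse = ", ")))
  }
  invisible(x)
}

# Natural chromosome ordering: 1..22, X, Y, MT; anything else after.
chrom_order <- function(chrom) {
  levels <- c(as.character(1:22), "X", "Y", "MT")
  idx <- match(chrom, levels)
  idx[is.na(idx)] <- length(levels) + 1L
  idx
}

strip_chr_prefix <- function(chrom) sub("^chr", "", chrom)

# Lower-median convention: for even n, the lower of the two middle values.
lower_median <- function(x) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n == 0) return(NA_real_)
  x[floor((n + 1) / 2)]
}

is_plp <- function(clinical_class) clinical_class %in% c("P", "LP")
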