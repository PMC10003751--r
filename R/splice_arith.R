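# Consequence arithmetic for alternative splice-donor usage: an activated
# donor `shift_nt` exonic nucleotides upstream of the canonical donor
# removes that many nucleotides from the transcript, shortening the RT-PCR
# amplicon by the same amount and shifting the frame unless the loss is a
# multiple of three.

#' Frame consequence of a donor shift
#'
#' @param shift_nt Positive integer distance(s) of the alternative donor
#'   upstream of the canonical one, in exonic nucleotides.
#' @return A tibble: `shift_nt`, `consequence` ("frameshift" or
#'   "in_frame"), `codons_deleted` (`NA` for frameshifts).
#' @examples
#' frame_consequence(129)  # in-frame loss of 43 codons
#' frame_consequence(16)   # frameshift
#' @export
frame_consequence <- function(shift_nt) {
  if (any(shift_nt <= 0) || any(shift_nt != round(shift_nt))) {
    abort("shift_nt must be a positive integer")
  }
  in_frame <- shift_nt %% 3 == 0
  tibble::tibble(
    shift_nt = as.integer(shift_nt),
    consequence = ifelse(in_frame, "in_frame", "frameshift"),
    codons_deleted = ifelse(in_frame, shift_nt %/% 3, NA_integer_))
}

#' RT-PCR amplicon size of a shifted isoform
#'
#' @param canonical_amplicon_bp Amplicon size of the canonical transcript.
#' @param shift_nt Donor shift (0 allowed: identity).
#' @return Amplicon size(s) in bp; a non-positive result is an error.
#' @examples
#' isoform_amplicon_size(250, c(16, 129))  # 234 and 121 bp
#' @export
isoform_amplicon_size <- function(canonical_amplicon_bp, shift_nt) {
  if (any(shift_nt < 0)) abort("shift_nt must be non-negative")
  size <- canonical_amplicon_bp - shift_nt
  if (any(size <= 0)) abort("shift exceeds the canonical amplicon size")
  size
}

#' Summarize donor-shift events
#'
#' One row per alternative donor: amplicon size, frame consequence, codons
#' deleted, and (when a coding sequence is supplied) the codon index of the
#' first premature stop introduced by a frameshift.
#'
#' @param canonical_amplicon_bp Canonical amplicon size in bp.
#' @param shifts Vector of donor shifts (exonic nt upstream of the
#'   canonical donor).
#' @param cds Optional coding sequence (single string, A/C/G/T) for
#'   premature-stop localization; without it the stop codon is reported as
#'   `NA` ("requires transcript").
#' @param junction_cds_pos CDS position (1-based) of the last exonic base
#'   before the canonical donor; required with `cds`.
#' @return A tibble: `isoform`, `shift_nt`, `amplicon_bp`, `consequence`,
#'   `codons_deleted`, `stop_codon`.
#' @export
donor_shift_summary <- function(canonical_amplicon_bp, shifts, cds = NULL,
                                junction_cds_pos = NULL) {
  if (any(shifts >= canonical_amplicon_bp)) {
    abort("shift_nt must be below the canonical amplicon size")
  }
  out <- frame_consequence(shifts)
  out$amplicon_bp <- isoform_amplicon_size(canonical_amplicon_bp, shifts)
  out$isoform <- seq_along(shifts)
  out$stop_codon <- NA_integer_
  if (!is.null(cds)) {
    if (is.null(junction_cds_pos)) {
      abort("junction_cds_pos is required when cds is supplied")
    }
    out$stop_codon <- vapply(shifts, function(s) {
      premature_stop_codon(cds, junction_cds_pos, s)
    }, integer(1))
  }
  out[, c("isoform", "shift_nt", "amplicon_bp", "consequence",
          "codons_deleted", "stop_codon")]
}

# First stop codon of the CDS after deleting the shift_nt bases ending at
# the canonical junction. Returns the 1-based codon index or NA.
premature_stop_codon <- function(cds, junction_cds_pos, shift_nt) {
  cds <- toupper(cds)
  if (junction_cds_pos > nchar(cds) || junction_cds_pos < shift_nt + 1) {
    abort("junction_cds_pos incompatible with cds length / shift")
  }
  kept <- paste0(substr(cds, 1, junction_cds_pos - shift_nt),
                 substr(cds, junction_cds_pos + 1, nchar(cds)))
  n_codon <- nchar(kept) %/% 3
  if (n_codon == 0) return(NA_integer_)
  codons <- substring(kept, 3 * seq_len(n_codon) - 2, 3 * seq_len(n_codon))
  hit <- which(codons %in% c("TAA", "TAG", "TGA"))
  if (length(hit) == 0) NA_integer_ else hit[1]
}
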