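# Synthetic reference model used by the cohort generator.
#
# The karyotype is a deliberately scaled-down stand-in for the human genome
# (22 autosomes + X, 40-60 Mb each) so that genome-wide marker tracks at 3 kb
# spacing stay small enough to simulate by the hundreds. The gene table uses
# real IRD gene symbols so downstream tables read naturally, but coordinates
# and exon structures are synthetic.

#' Synthetic karyotype
#'
#' @return A tibble with columns `chrom` (character, no "chr" prefix) and
#'   `length` (bp). 22 autosomes plus X; lengths are fixed (no randomness).
#' @export
ird_genome <- function() {
  chrom <- c(as.character(1:22), "X")
  # 60 Mb down to ~41 Mb across autosomes, X at 50 Mb
  length <- c(round(seq(60e6, 41e6, length.out = 22)), 50e6)
  tibble::tibble(chrom = chrom, length = as.integer(length))
}

# (gene, chrom, n_exons, tier) assignments; positions derived deterministically.
ird_gene_defs <- function() {
  tier1 <- tibble::tribble(
    ~gene,     ~chrom, ~n_exons,
    "EYS",     "6",    43L,
    "ABCA4",   "1",    50L,
    "USH2A",   "1",    72L,
    "DRAM2",   "1",    9L,
    "CRB1",    "1",    12L,
    "RPE65",   "1",    14L,
    "NR2E3",   "15",   8L,
    "CNGB3",   "8",    18L,
    "CNGA3",   "2",    8L,
    "CEP290",  "12",   54L,
    "GUCY2D",  "17",   20L,
    "AIPL1",   "17",   6L,
    "GRK1",    "13",   7L,
    "RHO",     "3",    5L,
    "PDE6B",   "4",    22L,
    "PDE6A",   "5",    22L,
    "PROM1",   "4",    27L,
    "LCA5",    "6",    9L,
    "TULP1",   "6",    15L,
    "RP1",     "8",    4L,
    "KCNV2",   "9",    2L,
    "BEST1",   "11",   11L,
    "MYO7A",   "11",   49L,
    "CDH23",   "10",   70L,
    "PCDH15",  "10",   39L,
    "RDH12",   "14",   9L,
    "SPATA7",  "14",   12L,
    "RLBP1",   "15",   9L,
    "CERKL",   "2",    14L,
    "MERTK",   "2",    19L,
    "SAG",     "2",    16L,
    "IMPG2",   "3",    19L,
    "CLN3",    "16",   16L,
    "CRX",     "19",   4L,
    "PRPH2",   "6",    3L,
    "RP2",     "X",    5L,
    "RPGR",    "X",    19L,
    "CHM",     "X",    15L,
    "RS1",     "X",    6L,
    "CACNA1F", "X",    48L,
    "RAB28",   "4",    8L,
    "POC1B",   "12",   12L
  )
  tier1$tier <- 1L
  tier2 <- tibble::tribble(
    ~gene,    ~chrom, ~n_exons,
    "HGSNAT", "8",    18L,
    "PEX1",   "7",    24L,
    "PEX6",   "6",    17L,
    "AHI1",   "6",    29L,
    "COL2A1", "12",   54L,
    "PNPLA6", "19",   34L,
    "WDR19",  "4",    37L,
    "ALMS1",  "2",    23L
  )
  tier2$tier <- 2L
  dplyr::bind_rows(tier1, tier2)
}

#' Synthetic IRD gene table
#'
#' Deterministic gene coordinates on the synthetic karyotype. Genes on the
#' same chromosome are laid out in order with 2 Mb of flanking spacing,
#' starting at 5 Mb; each gene spans `n_exons * 25 kb`.
#'
#' @return A tibble: `gene`, `chrom`, `start`, `end`, `n_exons`,
#'   `tier` (1 = retinal-disease gene panel, 2 = wider Mendelian-disease set).
#' @export
ird_gene_table <- function() {
  defs <- ird_gene_defs()
  defs |>
    dplyr::arrange(chrom_order(.data$chrom), .data$gene) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(
      span = .data$n_exons * 25000L,
      start = 5000000L + cumsum(dplyr::lag(.data$span + 2000000L, default = 0L)),
      end = .data$start + .data$span - 1L
    ) |>
    dplyr::ungroup() |>
    dplyr::select("gene", "chrom", "start", "end", "n_exons", "tier")
}

#' Synthetic exon model for a gene
#'
#' Exons of 200 bp placed at the start of equal-width slots across the gene
#' span (introns fill the remainder of each slot). Deterministic.
#'
#' @param gene Gene symbol present in [ird_gene_table()].
#' @return A tibble: `gene`, `exon`, `chrom`, `start`, `end` (1-based
#'   inclusive, non-overlapping, ordered).
#' @export
ird_exon_model <- function(gene) {
  tab <- ird_gene_table()
  row <- tab[tab$gene == gene, ]
  if (nrow(row) == 0) abort(sprintf("unknown gene: %s", gene))
  slot <- (row$end - row$start + 1L) %/% row$n_exons
  starts <- row$start + (seq_len(row$n_exons) - 1L) * slot
  tibble::tibble(
    gene = gene,
    exon = seq_len(row$n_exons),
    chrom = row$chrom,
    start = as.integer(starts),
    end = as.integer(starts + 199L)
  )
}

#' Default gene tier sets
#'
#' Convenience accessors for the prioritization cascade: tier 1 emulates a
#' retinal-disease gene panel (RetNet-style), tier 2 a wider Mendelian set
#' (OMIM-style); everything else is tier 3.
#' @return Character vector of gene symbols.
#' @export
ird_tier1_genes <- function() ird_gene_table()$gene[ird_gene_table()$tier == 1L]

#' @rdname ird_tier1_genes
#' @export
ird_tier2_genes <- function() ird_gene_table()$gene[ird_gene_table()$tier == 2L]
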