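# Minimal VCF v4.2 dialect used by the pipeline.
#
# Fixed columns CHROM POS ID REF ALT QUAL FILTER INFO FORMAT plus one column
# per sample. SNVs/indels carry literal REF/ALT; CNVs and mobile-element
# insertions are written as symbolic <DEL>/<DUP>/<INS:ME> with END in INFO.
# Annotations travel in INFO (GENE, KIND, PROFILE, CLASS, NOVEL, END and,
# when present, MAF, GERP, ADA); zygosity and phase evidence travel in the
# per-sample field (GT:PH:PP, PH = phase label, PP = partner variant id) so
# that read_vcf(write_vcf(x)) reproduces the genotype table exactly.
# Out of scope: phased pipe genotypes and multi-allelic records.

vcf_header <- function(samples) {
  c("##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position (1-based inclusive)\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Structural variant type\">",
    "##INFO=<ID=KIND,Number=1,Type=String,Description=\"Variant kind (snv/indel/cnv_del/cnv_dup/mei)\">",
    "##INFO=<ID=PROFILE,Number=1,Type=String,Description=\"Molecular profile\">",
    "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Minor allele frequency in population databases\">",
    "##INFO=<ID=GERP,Number=1,Type=Float,Description=\"GERP conservation score\">",
    "##INFO=<ID=ADA,Number=1,Type=Float,Description=\"dbscSNV-ADA-style splice score\">",
    "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Clinical class (P/LP/VUS/LB/B)\">",
    "##INFO=<ID=NOVEL,Number=1,Type=Integer,Description=\"1 if never reported before\">",
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##ALT=<ID=DUP,Description=\"Duplication\">",
    "##ALT=<ID=INS:ME,Description=\"Mobile element insertion\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=PH,Number=1,Type=String,Description=\"Phase evidence (in_trans/in_cis/unknown/not_applicable)\">",
    "##FORMAT=<ID=PP,Number=1,Type=String,Description=\"Phase partner variant id\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

symbolic_alt <- c(cnv_del = "<DEL>", cnv_dup = "<DUP>", mei = "<INS:ME>")
svtype_of <- c(cnv_del = "DEL", cnv_dup = "DUP", mei = "INS")

#' Write variants and genotype calls as a VCF subset
#'
#' @param variants Variant tibble (see [read_variants()]).
#' @param genotypes Genotype-call tibble (may be empty).
#' @param path Output file path.
#' @return `path`, invisibly. Records with missing coordinates are an error
#'   (they cannot be sorted).
#' @export
write_vcf <- function(variants, genotypes, path) {
  validate_variants(variants)
  if (any(is.na(variants$chrom) | is.na(variants$start))) {
    abort("cannot sort variants with missing chrom/start for VCF output")
  }
  v <- dplyr::arrange(variants, chrom_order(.data$chrom), .data$start,
                      .data$variant_id)
  samples <- sort(unique(genotypes$patient_id))

  info <- purrr::pmap_chr(v, function(variant_id, gene, chrom, start, end,
                                      ref, alt, kind, profile, maf, gerp,
                                      splice_score, clinical_class, novel,
                                      ...) {
    parts <- c(paste0("GENE=", gene), paste0("END=", end))
    if (kind %in% names(svtype_of)) {
      parts <- c(parts, paste0("SVTYPE=", svtype_of[[kind]]))
    }
    parts <- c(parts, paste0("KIND=", kind), paste0("PROFILE=", profile))
    if (!is.na(maf)) parts <- c(parts, paste0("MAF=", as.character(maf)))
    if (!is.na(gerp)) parts <- c(parts, paste0("GERP=", as.character(gerp)))
    if (!is.na(splice_score)) {
      parts <- c(parts, paste0("ADA=", as.character(splice_score)))
    }
    parts <- c(parts, paste0("CLASS=", clinical_class),
               paste0("NOVEL=", as.integer(novel)))
    paste(parts, collapse = ";")
  })

  ref_out <- ifelse(v$kind %in% names(symbolic_alt) | v$ref == "", "N", v$ref)
  alt_out <- ifelse(v$kind %in% names(symbolic_alt),
                    symbolic_alt[v$kind], v$alt)

  gt_field <- function(variant_id) {
    g <- genotypes[genotypes$variant_id == variant_id, ]
    out <- setNames(rep("./.:.:.", length(samples)), samples)
    if (nrow(g) > 0) {
      gt <- c(het = "0/1", hom = "1/1", hemi = "1")[g$zygosity]
      ph <- ifelse(is.na(g$phase), ".", g$phase)
      pp <- ifelse(is.na(g$phase_partner), ".", g$phase_partner)
      out[g$patient_id] <- paste(gt, ph, pp, sep = ":")
    }
    out
  }

  lines <- vapply(seq_len(nrow(v)), function(i) {
    fields <- c(v$chrom[i], v$start[i], v$variant_id[i], ref_out[i],
                alt_out[i], ".", "PASS", info[i])
    if (length(samples) > 0) {
      fields <- c(fields, "GT:PH:PP", gt_field(v$variant_id[i]))
    }
    paste(fields, collapse = "\t")
  }, character(1))

  writeLines(c(vcf_header(samples), lines), path)
  invisible(path)
}

info_get <- function(info_pairs, key) {
  hit <- grep(paste0("^", key, "="), info_pairs, value = TRUE)
  if (length(hit) == 0) NA_character_ else sub(paste0("^", key, "="), "", hit[1])
}

#' Read the VCF subset written by [write_vcf()]
#'
#' @param path File path.
#' @return A list with tibbles `variants` and `genotypes`.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  hdr_idx <- grep("^#CHROM", lines)
  if (length(hdr_idx) != 1) {
    abort(sprintf("malformed VCF %s: missing #CHROM header line", path))
  }
  hdr <- strsplit(lines[hdr_idx], "\t", fixed = TRUE)[[1]]
  samples <- if (length(hdr) > 9) hdr[10:length(hdr)] else character()
  data_idx <- which(!startsWith(lines, "#") & nzchar(lines))

  variants <- vector("list", length(data_idx))
  genolist <- vector("list", length(data_idx))
  for (k in seq_along(data_idx)) {
    i <- data_idx[k]
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 8) {
      abort(sprintf("malformed line in %s: line %d has %d field(s)",
                    path, i, length(fields)))
    }
    info_pairs <- strsplit(fields[8], ";", fixed = TRUE)[[1]]
    kind <- info_get(info_pairs, "KIND")
    if (is.na(kind)) {
      abort(sprintf("malformed line in %s: line %d lacks KIND in INFO",
                    path, i))
    }
    symbolic <- kind %in% names(symbolic_alt)
    end_chr <- info_get(info_pairs, "END")
    variants[[k]] <- tibble::tibble(
      variant_id = fields[3],
      gene = info_get(info_pairs, "GENE"),
      chrom = strip_chr_prefix(fields[1]),
      start = as.integer(fields[2]),
      end = if (is.na(end_chr)) as.integer(fields[2]) else as.integer(end_chr),
      ref = if (symbolic) "" else fields[4],
      alt = if (symbolic) "" else fields[5],
      kind = kind,
      profile = info_get(info_pairs, "PROFILE"),
      maf = as.numeric(info_get(info_pairs, "MAF")),
      gerp = as.numeric(info_get(info_pairs, "GERP")),
      splice_score = as.numeric(info_get(info_pairs, "ADA")),
      clinical_class = info_get(info_pairs, "CLASS"),
      novel = info_get(info_pairs, "NOVEL") == "1"
    )
    if (length(samples) > 0 && length(fields) >= 10) {
      calls <- strsplit(fields[10:length(fields)], ":", fixed = TRUE)
      gt <- vapply(calls, `[`, character(1), 1)
      ph <- vapply(calls, function(x) x[2] %||% ".", character(1))
      pp <- vapply(calls, function(x) x[3] %||% ".", character(1))
      called <- gt %in% c("0/1", "1/1", "1")
      if (any(called)) {
        genolist[[k]] <- tibble::tibble(
          patient_id = samples[called],
          variant_id = fields[3],
          zygosity = unname(c("0/1" = "het", "1/1" = "hom",
                              "1" = "hemi")[gt[called]]),
          phase_partner = ifelse(pp[called] == ".", NA_character_, pp[called]),
          phase = ifelse(ph[called] == ".", NA_character_, ph[called])
        )
      }
    }
  }
  variants <- dplyr::bind_rows(variants)
  genotypes <- dplyr::bind_rows(genolist)
  if (nrow(genotypes) == 0) {
    genotypes <- tibble::tibble(patient_id = character(),
                                variant_id = character(),
                                zygosity = character(),
                                phase_partner = character(),
                                phase = character())
  }
  genotypes <- dplyr::arrange(genotypes, .data$patient_id, .data$variant_id)
  validate_variants(variants)
  list(variants = variants, genotypes = genotypes)
}
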