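# Synthetic-cohort generator.
#
# Emulates the statistical structure the downstream analysis assumes:
# founder recessive alleles at skewed recurrence (many alleles seen twice or
# more), homozygous causal genotypes embedded in planted runs of
# homozygosity, an inheritance-mode mixture dominated by isolated and
# recessive cases, and copy-number signal in exon coverage. Planted ground
# truth is always emitted alongside the data; no analysis stage reads it.

#' Simulation configuration
#'
#' Defaults describe the cohort structure the pipeline was designed around:
#' 230 index cases; inheritance mixture 48% isolated / 37% recessive /
#' 7% dominant / 7% X-linked (remainder unknown); 76% of patients planted
#' with a diagnosable genotype (65% solved + 11% likely solved); 51% of
#' diagnosed recessive cases homozygous; founder alleles with fixed
#' occurrence targets (the largest a 17-occurrence exon-deletion CNV);
#' marker tracks at 3 kb spacing with 35% background heterozygosity and a
#' 0.2% per-marker genotyping error inside true ROHs; exon depth around a
#' 150x mean with negative-binomial noise.
#'
#' @param n_index Number of index cases.
#' @param inheritance_mix Named fractions over isolated/AR/AD/XL; must sum
#'   to at most 1, the remainder is "unknown".
#' @param phenotype_mix Named fractions over phenotype classes.
#' @param status_mix Named fractions over planted diagnostic statuses
#'   (solved/likely_solved/uncertain/unsolved); normalized to sum to 1.
#' @param founder_alleles Tibble with columns `gene`, `target_occurrences`,
#'   `kind`: recurrent recessive alleles planted at fixed allele-copy counts
#'   (hom carriers contribute 2).
#' @param private_allele_rate Probability that a non-founder causal allele
#'   is a new private variant rather than a reuse of an existing one.
#' @param hom_fraction Probability that a diagnosed recessive case is
#'   homozygous rather than compound heterozygous.
#' @param roh_mean_length_mb Mean of the exponential ROH length
#'   distribution, in Mb.
#' @param background_roh_rate Mean number of non-causal ROHs per genome.
#' @param marker_spacing_bp Marker grid spacing for simulated tracks.
#' @param background_het_rate Fraction of heterozygous markers outside ROHs.
#' @param het_error_rate Per-marker probability of a spurious heterozygous
#'   call inside a true ROH.
#' @param missing_rate Per-marker missing-genotype probability.
#' @param depth_mean,depth_dispersion Negative-binomial mean (diploid) and
#'   size parameter for exon depth.
#' @param roh_exception_patients Number of homozygous causal genotypes to
#'   plant *outside* any ROH (emulating rare WES-genotyping false negatives
#'   of autozygosity).
#' @param xl_female_fraction Fraction of X-linked index cases that are
#'   manifesting heterozygous females.
#' @param seed Integer RNG seed; all generator randomness derives from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_index = 230,
                       inheritance_mix = c(isolated = 0.48, AR = 0.37,
                                           AD = 0.07, XL = 0.07),
                       phenotype_mix = c(RP = 0.47, cone_rod_dystrophy = 0.14,
                                         LCA = 0.10, Usher = 0.06,
                                         Stargardt_macular = 0.06,
                                         cone_dystrophy = 0.05, other = 0.12),
                       status_mix = c(solved = 0.65, likely_solved = 0.11,
                                      uncertain = 0.08, unsolved = 0.16),
                       founder_alleles = default_founder_alleles(),
                       private_allele_rate = 0.5,
                       hom_fraction = 0.51,
                       roh_mean_length_mb = 5,
                       background_roh_rate = 3,
                       marker_spacing_bp = 3000,
                       background_het_rate = 0.35,
                       het_error_rate = 0.002,
                       missing_rate = 0,
                       depth_mean = 150,
                       depth_dispersion = 100,
                       roh_exception_patients = 0,
                       xl_female_fraction = 0.15,
                       seed = 1) {
  cfg <- list(n_index = n_index, inheritance_mix = inheritance_mix,
              phenotype_mix = phenotype_mix, status_mix = status_mix,
              founder_alleles = founder_alleles,
              private_allele_rate = private_allele_rate,
              hom_fraction = hom_fraction,
              roh_mean_length_mb = roh_mean_length_mb,
              background_roh_rate = background_roh_rate,
              marker_spacing_bp = marker_spacing_bp,
              background_het_rate = background_het_rate,
              het_error_rate = het_error_rate, missing_rate = missing_rate,
              depth_mean = depth_mean, depth_dispersion = depth_dispersion,
              roh_exception_patients = roh_exception_patients,
              xl_female_fraction = xl_female_fraction, seed = seed)
  if (n_index < 0) abort("n_index must be non-negative")
  if (sum(inheritance_mix) > 1 + 1e-9) {
    abort("inheritance_mix fractions must sum to at most 1")
  }
  rates <- c(private_allele_rate, hom_fraction, background_het_rate,
             het_error_rate, missing_rate, xl_female_fraction,
             inheritance_mix, status_mix)
  if (any(rates < 0 | rates > 1)) abort("all rates must lie in [0, 1]")
  cfg$status_mix <- status_mix / sum(status_mix)
  structure(cfg, class = "sim_config")
}

#' Default founder-allele plan
#'
#' Occurrence targets chosen to reproduce a recurrence spectrum where
#' alleles seen three or more times dominate, headed by a 17-occurrence
#' exon-deletion founder CNV in a recessive retinal-disease gene.
#' @return A tibble: `gene`, `target_occurrences`, `kind`.
#' @export
default_founder_alleles <- function() {
  tibble::tribble(
    ~gene,    ~target_occurrences, ~kind,
    "EYS",    17L,                 "cnv_del",
    "ABCA4",  10L,                 "snv",
    "USH2A",  8L,                  "snv",
    "CRB1",   6L,                  "snv",
    "RPE65",  5L,                  "snv",
    "CNGB3",  5L,                  "indel",
    "RAB28",  4L,                  "snv",
    "CEP290", 4L,                  "snv",
    "MYO7A",  3L,                  "snv",
    "PDE6B",  3L,                  "snv",
    "CDH23",  2L,                  "indel",
    "AIPL1",  2L,                  "snv"
  )
}

# Genes used for dominant planting (autosomal tier-1 genes with plausible
# dominant disease forms in the synthetic model).
ad_gene_pool <- c("RHO", "CRX", "PRPH2", "BEST1", "GUCY2D", "RP1",
                  "IMPG2", "NR2E3")

empty_genotypes <- function() {
  tibble::tibble(patient_id = character(), variant_id = character(),
                 zygosity = character(), phase_partner = character(),
                 phase = character())
}

empty_variants <- function() {
  tibble::tibble(variant_id = character(), gene = character(),
                 chrom = character(), start = integer(), end = integer(),
                 ref = character(), alt = character(), kind = character(),
                 profile = character(), maf = double(), gerp = double(),
                 splice_score = double(), clinical_class = character(),
                 novel = logical())
}

#' Simulate a synthetic IRD cohort
#'
#' Generates patients, a variant table, genotype calls, a planted-truth
#' table, and an ROH plan (causal + background autozygous intervals) that
#' [simulate_marker_track()] can turn into marker tracks. Deterministic
#' given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list of class `ird_cohort` with tibbles `patients`, `variants`,
#'   `genotypes`, `truth` (planted causal genotypes and expected statuses;
#'   for tests only), and `roh_plan` (planted autozygous intervals).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_index
  if (n == 0) {
    return(structure(list(patients = tibble::tibble(
      patient_id = character(), sex = character(), inheritance = character(),
      phenotype_class = character(), birth_year = integer()),
      variants = empty_variants(), genotypes = empty_genotypes(),
      truth = tibble::tibble(), roh_plan = tibble::tibble(),
      config = config), class = "ird_cohort"))
  }
  if (any(config$founder_alleles$target_occurrences > 2 * n)) {
    abort("infeasible founder target: occurrences exceed 2 * n_index")
  }

  inh_p <- c(config$inheritance_mix,
             unknown = max(0, 1 - sum(config$inheritance_mix)))
  inheritance <- sample(names(inh_p), n, replace = TRUE, prob = inh_p)
  sex <- ifelse(inheritance == "XL",
                ifelse(runif(n) < config$xl_female_fraction,
                       "female", "male"),
                sample(ird_sexes, n, replace = TRUE))
  patients <- tibble::tibble(
    patient_id = sprintf("P%04d", seq_len(n)),
    sex = sex,
    inheritance = inheritance,
    phenotype_class = sample(names(config$phenotype_mix), n, replace = TRUE,
                             prob = config$phenotype_mix),
    birth_year = sample(1935:2005, n, replace = TRUE)
  )
  planted <- sample(names(config$status_mix), n, replace = TRUE,
                    prob = config$status_mix)
  # likely_solved is a recessive-only status under the decision rules
  planted[planted == "likely_solved" &
            inheritance %in% c("AD", "XL")] <- "solved"

  gene_tab <- ird_gene_table()
  ar_genes <- gene_tab$gene[gene_tab$tier == 1L & gene_tab$chrom != "X"]
  x_genes <- gene_tab$gene[gene_tab$tier == 1L & gene_tab$chrom == "X"]

  state <- new.env(parent = emptyenv())
  state$variants <- list()
  state$genotypes <- list()
  state$truth <- list()
  state$counter <- 0L
  state$reusable <- character()  # non-founder causal variant ids open to reuse
  state$var_gene <- character()  # variant_id -> gene lookup

  new_variant <- function(gene, kind = NULL, clinical_class = "P",
                          novel = NA) {
    g <- gene_tab[gene_tab$gene == gene, ]
    state$counter <- state$counter + 1L
    id <- sprintf("v%04d", state$counter)
    if (is.null(kind)) {
      kind <- sample(c("snv", "indel"), 1, prob = c(0.75, 0.25))
    }
    if (is.na(novel)) novel <- runif(1) < 0.2
    if (kind == "cnv_del" || kind == "cnv_dup") {
      ex <- ird_exon_model(gene)
      first <- sample(seq_len(max(1, nrow(ex) - 1L)), 1)
      last <- min(nrow(ex), first + sample(0:2, 1))
      start <- ex$start[first]
      end <- ex$end[last]
      profile <- "structural"
      ref <- ""
      alt <- ""
    } else {
      start <- as.integer(sample(g$start:g$end, 1))
      end <- if (kind == "indel") start + sample(0:8, 1) else start
      profile <- if (kind == "mei") "structural" else if (kind == "indel") {
        sample(c("frameshift", "inframe_indel"), 1, prob = c(0.7, 0.3))
      } else {
        sample(c("missense", "nonsense", "splice_region", "start_loss"), 1,
               prob = c(0.5, 0.25, 0.2, 0.05))
      }
      bases <- c("A", "C", "G", "T")
      ref <- sample(bases, 1)
      alt <- sample(setdiff(bases, ref), 1)
      if (kind == "indel") alt <- paste0(ref, sample(bases, 1))
    }
    maf <- if (novel) NA_real_ else round(runif(1, 0, 0.005), 6)
    gerp <- if (clinical_class == "VUS") round(runif(1, 4.1, 6), 3) else
      round(runif(1, 2, 6), 3)
    splice_score <- if (profile == "splice_region") {
      round(runif(1, 0.6, 1), 3)
    } else {
      NA_real_
    }
    state$variants[[id]] <- list(
      variant_id = id, gene = gene, chrom = g$chrom,
      start = as.integer(start), end = as.integer(end), ref = ref, alt = alt,
      kind = kind, profile = profile, maf = maf, gerp = gerp,
      splice_score = splice_score, clinical_class = clinical_class,
      novel = novel)
    state$var_gene[id] <- gene
    id
  }

  add_call <- function(pid, vid, zygosity, phase = "not_applicable",
                       partner = NA_character_) {
    state$genotypes[[length(state$genotypes) + 1L]] <- list(
      patient_id = pid, variant_id = vid, zygosity = zygosity,
      phase_partner = partner, phase = phase)
  }

  add_truth <- function(pid, status, gene, v1, v2 = NA_character_,
                        zclass = "none") {
    state$truth[[length(state$truth) + 1L]] <- list(
      patient_id = pid, true_status = status, gene = gene,
      variant_id = v1, variant_id_2 = v2, zygosity_class = zclass)
  }

  pick_causal <- function(pref_class = c("P", "LP")) {
    sample(pref_class, 1, prob = c(0.7, 0.3)[seq_along(pref_class)])
  }

  # Draw a causal allele: reuse an existing recurrent allele or mint a
  # private one, returning (variant_id, gene).
  draw_allele <- function() {
    if (length(state$reusable) > 0 &&
        runif(1) >= config$private_allele_rate) {
      vid <- sample(state$reusable, 1)
      list(vid = vid, gene = state$var_gene[[vid]])
    } else {
      gene <- sample(ar_genes, 1)
      vid <- new_variant(gene, clinical_class = pick_causal())
      state$reusable <- c(state$reusable, vid)
      list(vid = vid, gene = gene)
    }
  }

  recessive <- inheritance %in% c("AR", "isolated", "unknown")
  solved_rec_pool <- sample(which(planted == "solved" & recessive))

  # --- founder allele allocation -------------------------------------------
  fa <- config$founder_alleles
  for (i in seq_len(nrow(fa))) {
    vid <- new_variant(fa$gene[i], kind = fa$kind[i],
                       clinical_class = "P", novel = FALSE)
    remaining <- fa$target_occurrences[i]
    while (remaining >= 1 && length(solved_rec_pool) > 0) {
      idx <- solved_rec_pool[1]
      solved_rec_pool <- solved_rec_pool[-1]
      pid <- patients$patient_id[idx]
      if (remaining >= 2 && runif(1) < config$hom_fraction) {
        add_call(pid, vid, "hom")
        add_truth(pid, "solved", fa$gene[i], vid, zclass = "AR_hom")
        remaining <- remaining - 2L
      } else {
        partner <- new_variant(fa$gene[i], clinical_class = pick_causal())
        add_call(pid, vid, "het", "in_trans", partner)
        add_call(pid, partner, "het", "in_trans", vid)
        add_truth(pid, "solved", fa$gene[i], vid, partner, "AR_comp_het")
        remaining <- remaining - 1L
      }
    }
  }

  # --- remaining solved recessive/isolated cases ---------------------------
  for (idx in solved_rec_pool) {
    pid <- patients$patient_id[idx]
    a <- draw_allele()
    if (runif(1) < config$hom_fraction) {
      add_call(pid, a$vid, "hom")
      add_truth(pid, "solved", a$gene, a$vid, zclass = "AR_hom")
    } else {
      partner <- new_variant(a$gene, clinical_class = pick_causal())
      add_call(pid, a$vid, "het", "in_trans", partner)
      add_call(pid, partner, "het", "in_trans", a$vid)
      add_truth(pid, "solved", a$gene, a$vid, partner, "AR_comp_het")
    }
  }

  # --- solved dominant and X-linked cases ----------------------------------
  for (idx in which(planted == "solved" & inheritance == "AD")) {
    pid <- patients$patient_id[idx]
    gene <- sample(ad_gene_pool, 1)
    vid <- new_variant(gene, clinical_class = pick_causal())
    add_call(pid, vid, "het", "unknown")
    add_truth(pid, "solved", gene, vid, zclass = "AD_het")
  }
  for (idx in which(planted == "solved" & inheritance == "XL")) {
    pid <- patients$patient_id[idx]
    gene <- sample(x_genes, 1)
    vid <- new_variant(gene, clinical_class = pick_causal())
    if (patients$sex[idx] == "male") {
      add_call(pid, vid, "hemi")
      add_truth(pid, "solved", gene, vid, zclass = "XL_hemi")
    } else {
      add_call(pid, vid, "het", "unknown")
      add_truth(pid, "solved", gene, vid, zclass = "XL_het_female")
    }
  }

  # --- likely solved (recessive only) --------------------------------------
  for (idx in which(planted == "likely_solved")) {
    pid <- patients$patient_id[idx]
    gene <- sample(ar_genes, 1)
    v1 <- new_variant(gene, clinical_class = pick_causal())
    if (runif(1) < 0.5) {  # PLP + VUS demonstrated in trans
      v2 <- new_variant(gene, clinical_class = "VUS")
      add_call(pid, v1, "het", "in_trans", v2)
      add_call(pid, v2, "het", "in_trans", v1)
    } else {               # two PLP, phase unresolved
      v2 <- new_variant(gene, clinical_class = pick_causal())
      add_call(pid, v1, "het", "unknown", v2)
      add_call(pid, v2, "het", "unknown", v1)
    }
    add_truth(pid, "likely_solved", gene, v1, v2, "AR_comp_het")
  }

  # --- uncertain -----------------------------------------------------------
  for (idx in which(planted == "uncertain")) {
    pid <- patients$patient_id[idx]
    inh <- inheritance[idx]
    if (inh == "AD") {
      gene <- sample(ad_gene_pool, 1)
      vid <- new_variant(gene, clinical_class = "VUS")
      add_call(pid, vid, "het", "unknown")
      add_truth(pid, "uncertain", gene, vid)
    } else if (inh == "XL") {
      gene <- sample(x_genes, 1)
      vid <- new_variant(gene, clinical_class = "VUS")
      if (patients$sex[idx] == "male") {
        add_call(pid, vid, "hemi")
      } else {
        add_call(pid, vid, "het", "unknown")
      }
      add_truth(pid, "uncertain", gene, vid)
    } else {
      gene <- sample(ar_genes, 1)
      form <- sample(c("vus_vus_trans", "plp_vus_unknown",
                       "vus_vus_unknown", "hom_vus"), 1)
      if (form == "hom_vus") {
        vid <- new_variant(gene, clinical_class = "VUS")
        add_call(pid, vid, "hom")
        add_truth(pid, "uncertain", gene, vid)
      } else {
        c1 <- if (form == "plp_vus_unknown") pick_causal() else "VUS"
        phase <- if (form == "vus_vus_trans") "in_trans" else "unknown"
        v1 <- new_variant(gene, clinical_class = c1)
        v2 <- new_variant(gene, clinical_class = "VUS")
        add_call(pid, v1, "het", phase, v2)
        add_call(pid, v2, "het", phase, v1)
        add_truth(pid, "uncertain", gene, v1, v2)
      }
    }
  }

  # --- unsolved ------------------------------------------------------------
  for (idx in which(planted == "unsolved")) {
    pid <- patients$patient_id[idx]
    form <- sample(c("single_plp", "single_vus", "none"), 1,
                   prob = c(0.4, 0.2, 0.4))
    if (form == "none" || !recessive[idx]) {
      add_truth(pid, "unsolved", NA_character_, NA_character_)
      next
    }
    gene <- sample(ar_genes, 1)
    cls <- if (form == "single_plp") pick_causal() else "VUS"
    vid <- new_variant(gene, clinical_class = cls)
    add_call(pid, vid, "het", "unknown")
    add_truth(pid, "unsolved", gene, vid)
  }

  variants <- dplyr::bind_rows(state$variants)
  genotypes <- dplyr::bind_rows(state$genotypes)
  if (nrow(genotypes) == 0) genotypes <- empty_genotypes()
  truth <- dplyr::bind_rows(state$truth) |>
    dplyr::arrange(.data$patient_id)

  roh_plan <- plant_roh_intervals(patients, truth, variants, config)
  truth <- dplyr::left_join(
    truth,
    roh_plan |>
      dplyr::filter(.data$kind == "causal") |>
      dplyr::distinct(.data$patient_id) |>
      dplyr::mutate(in_roh = TRUE),
    by = "patient_id")
  truth$in_roh[is.na(truth$in_roh)] <- FALSE

  structure(list(patients = patients, variants = variants,
                 genotypes = genotypes, truth = truth, roh_plan = roh_plan,
                 config = config),
            class = "ird_cohort")
}

#' @export
print.ird_cohort <- function(x, ...) {
  cat(sprintf("<ird_cohort> %d patients, %d variants, %d genotype calls\n",
              nrow(x$patients), nrow(x$variants), nrow(x$genotypes)))
  invisible(x)
}

# Plant causal ROHs around homozygous causal variants (except the configured
# exception count) plus background ROHs per genome.
plant_roh_intervals <- function(patients, truth, variants, config) {
  genome <- ird_genome()
  rows <- list()
  seen <- new.env(parent = emptyenv())  # (pid, chrom) -> start/end matrix
  add_interval <- function(pid, chrom, start, end, kind) {
    len <- genome$length[genome$chrom == chrom]
    start <- max(1L, as.integer(start))
    end <- min(len, as.integer(end))
    if (end <= start) return(FALSE)
    key <- paste(pid, chrom)
    same <- seen[[key]]
    if (!is.null(same) &&
        any(start <= same[, 2] & end >= same[, 1])) {
      return(FALSE)
    }
    seen[[key]] <- rbind(same, c(start, end))
    rows[[length(rows) + 1L]] <<- list(
      patient_id = pid, chrom = chrom, start = start, end = end, kind = kind)
    TRUE
  }

  hom_truth <- truth[truth$zygosity_class %in% "AR_hom", ]
  except <- character()
  if (config$roh_exception_patients > 0 && nrow(hom_truth) > 0) {
    except <- sample(hom_truth$patient_id,
                     min(config$roh_exception_patients, nrow(hom_truth)))
  }
  for (i in seq_len(nrow(hom_truth))) {
    pid <- hom_truth$patient_id[i]
    if (pid %in% except) next
    v <- variants[variants$variant_id == hom_truth$variant_id[i], ]
    len <- max(1.2e6, rexp(1, 1 / (config$roh_mean_length_mb * 1e6)))
    offset <- floor(runif(1, 0.1, 0.9) * len)
    add_interval(pid, v$chrom, v$start - offset, v$start - offset + len,
                 "causal")
  }
  for (pid in patients$patient_id) {
    n_bg <- rpois(1, config$background_roh_rate)
    for (k in seq_len(n_bg)) {
      chrom <- sample(genome$chrom, 1)
      clen <- genome$length[genome$chrom == chrom]
      len <- rexp(1, 1 / (config$roh_mean_length_mb * 1e6))
      start <- floor(runif(1, 1, max(2, clen - len)))
      add_interval(pid, chrom, start, start + len, "background")
    }
  }
  out <- dplyr::bind_rows(rows)
  if (is.null(out) || nrow(out) == 0) {
    return(tibble::tibble(patient_id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          kind = character()))
  }
  dplyr::arrange(out, .data$patient_id, chrom_order(.data$chrom), .data$start)
}

#' Simulate a biallelic marker track
#'
#' Markers are laid on a regular grid. Inside planted autozygous intervals
#' genotypes are homozygous except for Bernoulli(`het_error_rate`) spurious
#' heterozygous calls; outside, a fraction `background_het_rate` of markers
#' are heterozygous. Draws from the current RNG stream (seed it, or use
#' [simulate_marker_tracks()] / [simulate_cohort()] which seed from the
#' configuration).
#'
#' @param patient_id Patient identifier for the track.
#' @param chrom Chromosome name.
#' @param planted_roh Tibble with `start`, `end` (1-based inclusive) of
#'   autozygous intervals to plant; may be `NULL` or empty. Overlapping
#'   intervals are an error, as are intervals outside the chromosome.
#' @param config A [sim_config()] (marker spacing, heterozygosity and error
#'   rates).
#' @param chrom_length Chromosome length in bp; defaults to the synthetic
#'   karyotype [ird_genome()].
#' @return A marker-track tibble: `patient_id`, `chrom`, `pos`, `gt`.
#' @export
simulate_marker_track <- function(patient_id, chrom, planted_roh = NULL,
                                  config = sim_config(),
                                  chrom_length = NULL) {
  if (is.null(chrom_length)) {
    genome <- ird_genome()
    chrom_length <- genome$length[genome$chrom == strip_chr_prefix(chrom)]
    if (length(chrom_length) == 0) {
      abort(sprintf("unknown chromosome %s (supply chrom_length)", chrom))
    }
  }
  if (!is.null(planted_roh) && nrow(planted_roh) > 0) {
    iv <- dplyr::arrange(planted_roh, .data$start)
    if (any(iv$start < 1 | iv$end > chrom_length)) {
      abort("planted interval outside chromosome bounds")
    }
    if (nrow(iv) > 1 && any(iv$start[-1] <= iv$end[-nrow(iv)])) {
      abort("overlapping planted ROH intervals")
    }
  } else {
    iv <- NULL
  }
  pos <- seq.int(config$marker_spacing_bp, chrom_length,
                 by = config$marker_spacing_bp)
  n <- length(pos)
  inside <- rep(FALSE, n)
  if (!is.null(iv)) {
    for (i in seq_len(nrow(iv))) {
      inside <- inside | (pos >= iv$start[i] & pos <= iv$end[i])
    }
  }
  het_p <- ifelse(inside, config$het_error_rate, config$background_het_rate)
  is_het <- runif(n) < het_p
  gt <- ifelse(is_het, "AB", ifelse(runif(n) < 0.5, "AA", "BB"))
  if (config$missing_rate > 0) {
    gt[runif(n) < config$missing_rate] <- "missing"
  }
  tibble::tibble(patient_id = patient_id, chrom = strip_chr_prefix(chrom),
                 pos = as.integer(pos), gt = gt)
}

#' Simulate marker tracks for a cohort's ROH plan
#'
#' Seeds the RNG from `config$seed` (offset by one so tracks are independent
#' of the cohort draw) and generates one track per requested patient x
#' chromosome, planting the cohort's `roh_plan` intervals.
#'
#' @param cohort An `ird_cohort` from [simulate_cohort()].
#' @param chroms Chromosomes to generate (default: all with planted ROHs).
#' @param patients Patients to generate (default: all).
#' @param config Simulation configuration (default: the cohort's).
#' @return A marker-track tibble covering all requested tracks.
#' @export
simulate_marker_tracks <- function(cohort, chroms = NULL, patients = NULL,
                                   config = NULL) {
  config <- config %||% cohort$config
  set.seed(config$seed + 1L)
  patients <- patients %||% cohort$patients$patient_id
  chroms <- chroms %||% unique(cohort$roh_plan$chrom)
  grid <- expand.grid(patient_id = patients, chrom = chroms,
                      stringsAsFactors = FALSE)
  purrr::pmap(grid, function(patient_id, chrom) {
    iv <- cohort$roh_plan[cohort$roh_plan$patient_id == patient_id &
                            cohort$roh_plan$chrom == chrom, ]
    simulate_marker_track(patient_id, chrom, iv, config)
  }) |> dplyr::bind_rows()
}

#' Simulate an exon coverage matrix
#'
#' Depth is drawn per (exon, sample) from a negative binomial with mean
#' `depth_mean x library factor x exon capture factor x copy_number / 2`;
#' copy number is 2 except where `carriers` plants a deletion or
#' duplication. Draws from the current RNG stream.
#'
#' @param gene_model Exon tibble (`gene`, `exon`, `chrom`, `start`, `end`),
#'   e.g. [ird_exon_model()].
#' @param samples Character vector of sample ids (columns of the output).
#' @param carriers Optional tibble `patient_id`, `first_exon`, `last_exon`,
#'   `copy_state` (hom_del/het_del/dup -> copy number 0/1/3). Spans must lie
#'   within the gene model.
#' @param config A [sim_config()] (depth mean and dispersion).
#' @return A wide coverage tibble (see [read_coverage()]).
#' @export
simulate_coverage <- function(gene_model, samples, carriers = NULL,
                              config = sim_config()) {
  if (config$depth_mean < 0) abort("depth_mean must be non-negative")
  assert_cols(gene_model, c("gene", "exon", "chrom", "start", "end"))
  n_exon <- nrow(gene_model)
  n_s <- length(samples)
  cn <- matrix(2, nrow = n_exon, ncol = n_s,
               dimnames = list(NULL, samples))
  if (!is.null(carriers) && nrow(carriers) > 0) {
    assert_cols(carriers, c("patient_id", "first_exon", "last_exon",
                            "copy_state"))
    if (!all(carriers$patient_id %in% samples)) {
      abort("carriers must be a subset of samples")
    }
    if (any(carriers$first_exon < min(gene_model$exon)) ||
        any(carriers$last_exon > max(gene_model$exon))) {
      abort("carrier exon span outside gene model")
    }
    cn_of <- c(hom_del = 0, het_del = 1, dup = 3)
    for (i in seq_len(nrow(carriers))) {
      rows <- gene_model$exon >= carriers$first_exon[i] &
        gene_model$exon <= carriers$last_exon[i]
      cn[rows, carriers$patient_id[i]] <- cn_of[[carriers$copy_state[i]]]
    }
  }
  lib <- rlnorm(n_s, 0, 0.15)
  exf <- rlnorm(n_exon, 0, 0.2)
  mu <- config$depth_mean * outer(exf, lib) * cn / 2
  depth <- matrix(rnbinom(length(mu), size = config$depth_dispersion,
                          mu = mu),
                  nrow = n_exon, dimnames = list(NULL, samples))
  dplyr::bind_cols(gene_model[, c("gene", "exon", "chrom", "start", "end")],
                   tibble::as_tibble(depth))
}
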