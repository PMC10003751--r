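# Independent statement of the patient-classification rules as a lookup
# keyed by (context, genotype pattern); deliberately table-shaped rather
# than rule-ordered so it does not share structure with the implementation.

expected_status <- function(inheritance, sex, classes, zyg, phase,
                            policy = "solved") {
  ctx <- switch(inheritance,
                AR = , isolated = , unknown = "recessive",
                AD = "dominant",
                XL = if (sex == "male") "xl_male" else "xl_female")
  plp <- function(i) classes[i] %in% c("P", "LP")
  n <- length(classes)
  if (n == 1) {
    key <- paste(ctx, zyg[1], if (plp(1)) "PLP" else "VUS")
    tab <- c(
      "recessive het PLP" = "unsolved",
      "recessive het VUS" = "unsolved",
      "recessive hom PLP" = "solved",
      "recessive hom VUS" = "uncertain",
      "recessive hemi PLP" = "solved",
      "recessive hemi VUS" = "uncertain",
      "dominant het PLP" = "solved",
      "dominant het VUS" = "uncertain",
      "dominant hom PLP" = "solved",
      "dominant hom VUS" = "uncertain",
      "dominant hemi PLP" = "solved",
      "dominant hemi VUS" = "uncertain",
      "xl_male hemi PLP" = "solved",
      "xl_male hemi VUS" = "uncertain",
      "xl_male hom PLP" = "solved",
      "xl_male hom VUS" = "uncertain",
      "xl_male het PLP" = "unsolved",
      "xl_male het VUS" = "unsolved",
      "xl_female hom PLP" = "solved",
      "xl_female hom VUS" = "uncertain",
      "xl_female het PLP" = if (policy == "solved") "solved" else "unsolved",
      "xl_female het VUS" = if (policy == "solved") "uncertain"
                            else "unsolved")
    return(unname(tab[key]))
  }
  # pairs: both heterozygous
  n_plp <- sum(plp(1), plp(2))
  if (ctx == "xl_male") return("unsolved")
  if (ctx == "dominant") {
    return(if (n_plp >= 1) "solved" else "uncertain")
  }
  # recessive contexts (incl. the X-linked female biallelic case)
  key <- paste(phase[1], n_plp)
  tab <- c("in_cis 0" = "unsolved", "in_cis 1" = "unsolved",
           "in_cis 2" = "unsolved",
           "in_trans 2" = "solved", "in_trans 1" = "likely_solved",
           "in_trans 0" = "uncertain",
           "unknown 2" = "likely_solved", "unknown 1" = "uncertain",
           "unknown 0" = "uncertain")
  unname(tab[key])
}

enumerate_assortments <- function() {
  singles <- expand.grid(
    inheritance = c("isolated", "AR", "AD", "XL", "unknown"),
    sex = c("male", "female"),
    class1 = c("P", "LP", "VUS"),
    zyg1 = c("het", "hom", "hemi"),
    stringsAsFactors = FALSE)
  singles <- singles[!(singles$zyg1 == "hemi" & singles$sex == "female"), ]
  singles$class2 <- NA_character_
  singles$phase <- NA_character_
  pairs <- expand.grid(
    inheritance = c("isolated", "AR", "AD", "XL", "unknown"),
    sex = c("male", "female"),
    class1 = c("P", "LP", "VUS"),
    class2 = c("P", "LP", "VUS"),
    phase = c("in_trans", "in_cis", "unknown"),
    stringsAsFactors = FALSE)
  pairs$zyg1 <- "het"
  dplyr::bind_rows(singles, pairs)
}

# run classify_patient over one enumerated row
classify_enumerated <- function(cs, policy = "solved") {
  single <- is.na(cs$class2)
  classes <- if (single) cs$class1 else c(cs$class1, cs$class2)
  zyg <- if (single) cs$zyg1 else c("het", "het")
  phase <- if (single) {
    if (cs$zyg1 == "het") "unknown" else "not_applicable"
  } else {
    rep(cs$phase, 2)
  }
  list(got = classify_patient(cs$inheritance, cs$sex, classes, zyg, phase,
                              xl_female_het_policy = policy),
       want = expected_status(cs$inheritance, cs$sex, classes, zyg, phase,
                              policy))
}
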