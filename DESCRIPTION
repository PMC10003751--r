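Package: irdscape
Title: Molecular-Diagnosis Landscape Analysis for Inherited Retinal Disease Cohorts
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for cohort-level molecular diagnosis of
    inherited retinal diseases (IRDs): variant prioritization by molecular
    profile, population frequency, conservation and splice prediction; a
    rule-based mapping from genotype assortments to solved / likely solved /
    uncertain / unsolved diagnostic statuses; runs-of-homozygosity calling from
    biallelic marker tracks with shared-haplotype (minimal critical region)
    detection for founder alleles; exon-resolution copy-number calling from
    depth ratios with breakpoint refinement and deletion/junction arithmetic;
    splice donor-shift consequence arithmetic; and cohort landscape statistics
    (diagnostic yield, allele recurrence spectra, zygosity breakdown,
    birth-cohort trends). A synthetic-cohort generator with planted ground
    truth makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
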