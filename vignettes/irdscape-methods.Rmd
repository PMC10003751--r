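---
title: "Methods: cohort-level molecular diagnosis of inherited retinal disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cohort-level molecular diagnosis of inherited retinal disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irdscape)
```

Inherited retinal diseases (IRDs) are monogenic photoreceptor/RPE
degenerations with extreme locus heterogeneity (hundreds of disease genes)
and strongly population-specific allele spectra. In founder-rich
populations a large share of patients carry *recurrent recessive alleles in
homozygosis*, sitting inside long runs of homozygosity (ROHs) inherited
from a common ancestor. irdscape implements the full analytic chain that a
cohort study of this kind runs after variant calling: variant
prioritization, genotype-to-diagnosis classification, homozygosity mapping
and shared-haplotype detection, read-depth CNV calling with breakpoint and
junction arithmetic, splice donor-shift arithmetic, and cohort landscape
statistics — together with a synthetic-cohort generator that makes the
whole chain testable without patient data.

This vignette documents the models, the tunable parameters, the numerical
choices, and what the synthetic data does and does not establish.

## The decision model for molecular diagnosis

Each index patient is classified from the pathogenic (P), likely
pathogenic (LP) and unknown-significance (VUS) variants retained in their
top candidate gene, conditional on the reported inheritance mode. Writing
PLP for P-or-LP, the rules implemented by `classify_patient()` are:

| context | genotype | status |
|---|---|---|
| recessive / isolated | two PLP in trans, or homozygous PLP | solved |
| recessive / isolated | PLP + VUS in trans; two PLP, phase unknown | likely solved |
| recessive / isolated | two VUS in trans; PLP + VUS phase unknown; two VUS phase unknown; homozygous VUS | uncertain |
| dominant | one heterozygous PLP | solved |
| dominant | one heterozygous VUS | uncertain |
| X-linked male | hemizygous PLP / VUS | solved / uncertain |
| anything else (single het PLP in a recessive context, any pair in cis) | | unsolved |

Design choices where the clinical convention leaves room:

* **Homozygous PLP counts as biallelic-in-trans** (solved): homozygosity
  implies both chromosomes carry the allele, and recurrent founder
  homozygotes are the dominant diagnosed genotype in this setting.
* **X-linked heterozygous females.** Manifesting carriers exist (and X
  genes such as *RPGR* produce them); the package classifies a het PLP in
  an XL female as solved by default, flags the patient in the output
  (`xl_female_het`), and offers `xl_female_het_policy = "unsolved"` for a
  stricter reading. The VUS analogue follows the policy (uncertain under
  the default), which preserves the monotone-upgrade ordering.
* **Isolated and unknown inheritance are handled under the recessive
  rules**: a sporadic case is most often a recessive genotype in this
  disease group, and treating unknowns the same keeps the rule set total.
* **A hom + het pair** is decided by the homozygous variant alone (it is
  already biallelic).

Two properties are enforced by exhaustive enumeration in the test suite:
every valid assortment maps to exactly one status, and promoting any VUS
to LP never lowers the status (unsolved < uncertain < likely solved <
solved). Diagnostic yield is (solved + likely solved)/index cases, and
report percentages round half-up (174/230 prints as 76%).

## Homozygosity mapping

`call_roh()` scans a biallelic marker track (genotypes AA/AB/BB/missing on
a position grid) for maximal runs in which **every window of
`window_markers` consecutive markers contains at most
`max_het_per_window` heterozygous calls**. The formal definition used —
and checked against a brute-force window-scanning oracle in the tests — is
that a run is valid iff it contains no H+1 heterozygous markers whose
index span is below W. Boundaries are reported at the outermost
*homozygous* markers (stable under window-size changes); runs separated by
less than `stitch_gap_bp` merge; the output is filtered by `min_length_bp`
and `min_markers`.

One ordering choice matters numerically: only runs individually supported
by `min_markers` take part in stitching. At 35% background heterozygosity
the inter-ROH sea is full of few-marker valid runs; if those were stitched
first, every sub-500 kb gap would chain and the caller would return whole
chromosomes. Requiring per-run support keeps background runs out while the
two or three pieces of a genuine multi-Mb segment split by isolated
genotyping errors (expected ~6 errors in a 9.5 Mb run at 0.2% error) still
merge.

Defaults (50-marker windows, 1 het allowed, 1 Mb / 25 markers minimum,
500 kb stitch gap) are tuned for ~3 kb marker spacing and 0.2% genotyping
error; all are exposed in `roh_params()`.

`shared_roh()` unions each patient's segments, sweeps segment endpoints,
and reports maximal intervals covered by at least `min_patients` genomes;
for each it also reports the **minimal critical region** — the
intersection of the supporting segments — which is the interval that
localizes a founder allele. `total_autozygosity()` sums segment lengths in
Mb; per-patient totals exclude X-chromosome segments in males, because
hemizygosity is not autozygosity. Medians by genotype class use the lower
median, so a reported value is always an observed genome.

## Depth-ratio CNV calling

`normalize_depth()` converts a (exon x sample) depth matrix to copy
ratios: library-size factors by a two-pass median-of-ratios (the second
pass masks exons that look copy-altered after the first, so a sample's
own large deletion cannot deflate its size factor), then a leave-one-out
per-exon cohort median as the diploid reference. `call_cnv()` assigns
bands — ratio at or below 0.15: homozygous deletion; 0.35–0.65:
heterozygous deletion; at or above 1.35: duplication — and reports maximal
consecutive-exon runs per state, down to single-exon events with no upper
span limit. The thresholds are this module's choices (the bands sit
between the theoretical 0 / 0.5 / 1 / 1.5 ratios) and are exposed in
`cnv_params()`.

Sensitivity is governed by the exon-level depth CV. At a 150x mean and
~13% CV a two-exon heterozygous deletion is recovered in >95% of
simulations; a *single-exon* het deletion is markedly less reliable,
because its one ratio must fall inside a 0.3-wide band against noise of
comparable scale. That is a real property of per-exon threshold calling,
not an artifact — multi-exon events are correspondingly easier, and
homozygous deletions (ratio near 0) are essentially always recovered.
Homozygous-deletion false calls on diploid samples are below 1% per
sample at defaults.

`refine_breakpoints()` locates each breakpoint inside the flanking intron
as the interval between the last position still at the outside copy state
(at or above 50% of the flanking median, for a homozygous deletion) and the
first clearly inside (<15%), after running-median smoothing (window 101).
On noiseless step-function depth this collapses to width-1 intervals; with
negative-binomial noise the interval brackets the true breakpoint in >95%
of simulations. If no transition is found the whole intron is returned as
the uncertainty interval.

Deletion arithmetic is 1-based inclusive: `deletion_length(g_start,
g_end)` is `g_end - g_start + 1` bp (the 107,468 bp founder-deletion
example prints as 107.5 kb after half-up rounding to one decimal), and a
junction-PCR product across a deletion is the undeleted template span
minus the deleted length.

## Splice donor-shift arithmetic

An activated alternative donor `s` exonic nucleotides upstream of the
canonical donor removes `s` nucleotides from the mature transcript:
amplicons shorten by exactly `s` (`isoform_amplicon_size()`), and the
reading frame is lost unless `s` is a multiple of 3, in which case `s/3`
codons are deleted (`frame_consequence()`). Locating the premature stop of
a frameshifted isoform requires the transcript's coding sequence, which
the package does not embed; `donor_shift_summary()` reports the stop codon
only when a CDS is supplied and `NA` ("requires transcript") otherwise.
Donor strength itself is consumed as an observation (e.g. a
dbscSNV-ADA-style score), never recomputed.

## Variant prioritization

The cascade in `prioritize_variants()` applies conjunctive filters —
optional call-quality floor, population frequency (keep iff MAF missing or
strictly below 1%), molecular profile (nonsense, frameshift, missense,
splice, start-loss, structural, in-frame indel; synonymous only when a
splice predictor at or above `splice_score_min` rescues it) — and, for
VUS-class variants, a retention gate: frequency below 1%, protein-level or
splice-predicted impact, and (GERP above 4 OR qualifying splice
prediction). Because the filters are conjunctive, the kept set equals the
intersection of the single-filter kept sets, and tightening any threshold
can only shrink it; both properties are tested.

Asymmetries worth stating: a *missing MAF passes* the frequency filters
(novel alleles have no population record; absence is not evidence of
frequency), while a *missing GERP fails* the VUS conservation arm
(conservative on unknown significance, permissive on novelty). The
internal-inventory frequency check is implemented as an allele frequency.
`splice_score_min` defaults to 0.6, below which none of the retained
splice-predicted variants in the motivating data would survive; it is a
configurable threshold, not a recomputed prediction. Candidate genotypes
are enumerated per inheritance mode (`inheritance_candidates()`): a single
heterozygous call is never a recessive candidate; unknown inheritance
takes the union of all patterns. Genes are ranked in three tiers
(retinal-panel, wider Mendelian set, rest) and candidates reported in tier
order.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the analysis
assumes, on a deliberately scaled-down synthetic genome (22 autosomes +
X, 40–60 Mb each; real IRD gene symbols with synthetic coordinates and
exon grids). Defaults are the study conditions the pipeline was designed
around:

* 230 index cases; inheritance mixture 48% isolated / 37% recessive /
  7% dominant / 7% X-linked, remainder unknown;
* planted status mixture solved 0.65 / likely solved 0.11 / uncertain
  0.08 / unsolved 0.16 — solved + likely solved = 0.76, the diagnostic
  yield the pipeline should report back;
* 51% of solved recessive cases homozygous (`hom_fraction`), the rest
  compound heterozygous with the comp-het partner private;
* founder alleles at fixed allele-copy targets (default plan headed by a
  17-copy exon-deletion CNV), consumed by assigning homozygotes (2
  copies) or comp-het carriers (1 copy) until the target is met — so the
  simulated occurrence count equals the target up to the odd forced
  heterozygote;
* marker tracks on a 3 kb grid: 35% heterozygous markers outside ROHs,
  Bernoulli(0.002) spurious hets inside;
* ROH lengths exponential with 5 Mb mean (the simplest one-parameter
  family consistent with per-genome totals varying over tens of Mb),
  causal ROHs guaranteed to contain the homozygous causal variant unless
  the `roh_exception_patients` flag plants outliers;
* exon depth negative-binomial, 150x diploid mean, size 100 (~13%
  exon-level CV, typical of well-behaved >150x targeted capture).

Every planted causal genotype and its expected status is emitted in a
truth table that only tests may read. Determinism is by `set.seed` from
`config$seed` (R's default Mersenne-Twister integer stream), with marker
tracks and coverage drawing from the current stream so callers can manage
seeds explicitly.

What the generator does **not** model — and hence what passing tests do
not establish about real data: linkage disequilibrium between background
markers (ROH structure is imposed directly), recombination and pedigree
structure, GC-dependent coverage bias (a hook exists in the CNV config
but the generator carries no GC signal), mosaicism, and any quantitative
model of endogamy — the birth-year autozygosity trend can be planted via
configuration but is not produced by a population model. Real marker
tracks have LD-driven background runs that make short spurious ROHs more
common than in simulation; the 1 Mb / 25-marker floor is what guards
against them in practice.

## Problem sizes used in the checks

The simulation-recovery checks run at the scale the statistics need, not
larger: ROH recovery uses 20 seeds of one 4.5 Mb track and 20 seeds of 50
tracks with 8 carriers of a 9.5 Mb haplotype (medians within 5% of the
planted lengths); the CNV caller is exercised over 100 seeds of a
12-sample, 18-exon panel (sensitivity at least 95%, hom-deletion false calls
below 1%); cohort fraction recovery uses three cohorts of 1,000 index cases
(recurrence and zygosity fractions within 3 points of the planted values);
the inheritance-mixture sanity check runs once at 10,000. The acceptance
script reruns the two ROH quantities from scratch at the same sizes.

## Known limitations

* The caller reports ROHs from genotype runs only; it does not phase, date
  segments, or detect uniparental isodisomy.
* CNV calling is per-exon thresholding with a cohort reference; it has no
  likelihood model, no GC correction, and needs at least
  `min_reference_samples` (default 8) samples to normalize against.
* The VUS gate consumes pre-computed annotation scores; the package never
  recomputes conservation or splice predictions.
* Clinical classes (P/LP/VUS) are inputs; no ACMG evidence-code scoring is
  performed.
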