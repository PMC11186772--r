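---
title: "Strand-resolved analysis of lesion segregation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strand-resolved analysis of lesion segregation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesionseg)
library(data.table)
```

## The scientific problem

A single burst of DNA base damage (for example a dose of an alkylating
mutagen) leaves adducts — lesions — on both strands of the double helix.
Lesions that survive until replication act as reduced-fidelity templates,
and because the two sister chromatids segregate into different daughter
cells, each tumour founded by one daughter carries mutations phased
overwhelmingly to one parental strand per chromosomal region. This
*lesion segregation* shows up as chromosome-scale runs of one-sided
mutational asymmetry: in a region where the founder kept the forward
strand's lesions, essentially all mutations "from T" sit on the forward
strand.

`lesionseg` implements the analysis layer that exploits this structure:

* phasing the lesion-containing strand per genomic segment and tumour
  from mutational asymmetry;
* strand-resolved, composition-weighted mutation and multiallelic rates;
* transcription-coupled repair (TCR) curves across expression strata;
* replication timing / fork directionality strand analyses and a windowed
  multivariate regression;
* translesion-synthesis mutation clusters with permutation nulls,
  including the enumeration of equally optimal indel–substitution
  alignments;
* positional damage-versus-repair profiles around genomic features; and
* the variant-allele-frequency (VAF) signatures of translesion
  resynthesis-induced mutagenesis (NER-TRIM).

Because the original study's sequencing data are not required here, the
package ships a first-class synthetic cohort generator
(`simulate_annotation()`, `simulate_tumour()`, `simulate_cohort()`) that
produces all inputs with ground-truth labels, which the test suite uses
for parameter-recovery and null-calibration checks.

## Core statistics

**Asymmetry score.** For a genomic segment, `S = (F − R)/(F + R)`, where
`F` and `R` are the rates of mutations from T on the forward and reverse
strands (mutations from A on the forward strand are mutations from T on
the reverse strand). Rates are composition-normalised by the segment's T
and A base counts. A segment is classified as carrying forward-strand
lesions when `S > 0.33`, reverse-strand lesions when `S < −0.33`, and is
otherwise unresolved; ties at the threshold are unresolved. A tumour is
flagged *symmetric* when more than 99% of its autosomal mutations lie in
segments with `|S| < 0.2`.

**Segmentation.** The change-point search is a binary segmentation over
the Bernoulli sequence of informative-mutation strand labels
(substitutions from T on either strand, VAF > 10%), accepting a split
when the binomial log-likelihood gain exceeds `2·log(n)` (a BIC-style
penalty) with at least 50 informative mutations per segment. Segment
boundaries are placed midway between flanking informative mutations, so
segments tile each chromosome exactly. The minimum informative count is
exposed as configuration because the source analyses do not state one;
the recovery requirement (≥ 95% of mutated bp correctly classified) is
insensitive to boundary placement at that granularity.

**Mutation rates.** Spectra are 192-category vectors (4 reference bases ×
3 alternates × 16 flanking contexts), oriented to the lesion-containing
strand: calls and sequence composition in reverse-lesion segments are
reverse complemented before tallying. A single aggregate rate is the
weighted mean of per-context rates (counts divided by ploidy-weighted
context occurrences; autosomes diploid, X haploid), with weights given by
a reference trinucleotide composition (whole genome by default).
Multiallelic rate is the weighted fraction of sites with three or four
alleles supported by ≥ 2 reads each, with weights renormalised over the
occupied contexts; sites with fewer than two supported alleles are
excluded. Multiallelism proxies lesion persistence, so it separates slow
repair (more multiallelism per mutation) from excess damage (more
mutations at unchanged multiallelism per mutation).

**Replication.** Replication time is the tags-per-million relative
enrichment `(E − L)/(E + L)` after a centred five-window (50 kb on a 10 kb
grid) rolling mean; fork directionality from replication time is the
central difference `(rt[i+1] − rt[i−1])/2`, and from Okazaki-fragment
counts `(R − F)/(R + F)`. Both tracks are split into 21 quantile bins with
stable tie-breaking; a window is concordant when the two bin labels
differ by strictly fewer than 4 bins (the strict reading of "less than
19% of the category range"; the threshold is configurable). Over a
lesion-containing template, a rightward fork with forward-strand lesions
is consensus lagging-strand synthesis — `(F,+) = lagging`,
`(R,−) = lagging`, `(F,−) = leading`, `(R,+) = leading`. For aggregation,
strand-resolved replication measures are re-oriented so the lesion strand
is the reverse strand (RSB); relative enrichments enter the regression
rescaled to the unit interval as `f = 1 − (1 − r)/2`.

**Regression.** The genome is tiled into 10 kb windows; windows wholly
inside a classified segment contribute a per-bp mutation rate aggregated
across tumours. Predictors are the expressed template and non-template
strand fractions, the residual genic fraction, and rescaled replication
time and RSB. The fit is ordinary least squares with t-based p-values;
rank-deficient designs are rejected with the collinear columns named.

**Clusters.** Clusters are maximal chains of same-tumour substitutions
spaced strictly less than `X` nt apart (`X` = 11, 101 or 201), so chains
can span more than `X`. The null preserves per-tumour mutation counts by
drawing proxy positions from the other tumours without replacement, and
enrichment is a two-sided Fisher test of clustered/unclustered counts
against the permuted mean. Cluster members are oriented by the direction
of nascent-strand synthesis over the lesion-containing template (leftmost
member first for reverse-strand lesions). For indel–substitution pairs,
every contiguous single-gap placement of the alignment is enumerated;
placements with exactly one gap and one mismatch are the equally optimal
solutions and are weighted `1/n_solutions`: a single-base deletion in a 4-mer
homopolymer with one distant substitution has four solutions at 0.25
each, while a uniquely placed pair scores 1. Pairs whose solutions all agree
on the substitution's side feed the up/down bias
`(down − up)/(down + up)` with a 10,000-permutation lesion-strand
relabelling null and an add-one empirical P, `(b + 1)/(n + 1)`. Note the
add-one estimator on a ±1 statistic is conservative (sub-uniform) at
small pair counts; the calibration tests therefore use enough pairs that
the statistic's granularity is below the resolution of the KS check.

**NER-TRIM.** Each autosomal point mutation's VAF quantile is its ECDF
position within its tumour (`rank/n`, ties at the maximum rank), grouped
into 200 bins of 0.005. Per bin, a 2×2 table of stratum-6 gene overlap ×
(focal vs background tumours) gives the sample cross-product odds ratio
(Haldane–Anscombe corrected and flagged when a cell is zero) and a
two-tailed Fisher P. Mutations created by resynthesis over an
opposite-strand lesion are shared by both daughters, so in symmetric
two-daughter tumours they have roughly doubled VAF and concentrate in the
top bins inside highly expressed genes.

## The synthetic cohort generator

`sim_config()` fixes the study conditions. The defaults describe a
desk-scale analogue of the mutagenised mouse-liver system, and were
chosen while designing the generator, not adjusted to test outcomes:

* **Genome**: two 6 Mb autosomes plus a 6 Mb haploid X, random sequence,
  12.7% masked (the study masked 12.7% of the genome). Lesions are placed
  per chromosome copy (autosomes ×2).
* **Lesion rates**: per strand-bp, `T = 1.5e-3 ≫ C = 2e-4 > G = 7e-5 >
  A = 1.5e-5`, so that over 75% of substitutions originate from T lesions
  as reported for this mutagen. The absolute scale is roughly tenfold the
  real per-bp rate because the genome is ~140-fold smaller than the real
  one: NER-TRIM needs two opposite-strand lesions within a 26 nt span, a
  density-squared phenomenon, and at realistic per-bp rates an 18 Mb
  genome would produce no analysable TRIM events at all. The A rate sits
  below G so that, as in the real system, A-origin mutations on the
  expressed template strand are dominated by TRIM rather than direct
  damage.
* **Segregation**: one retained strand per 1.5 Mb block (a scaled-down
  stand-in for the chromosome-scale segments; 10 Mb blocks would leave
  no within-chromosome transitions at this genome size). Symmetric tumours (2.7% by default, matching the reported
  fraction) retain both daughters at half VAF, with shared TRIM mutations
  at full clonal VAF.
* **Persistence**: lesions survive each cell cycle with probability
  `p_persist · (1 − p_repair)` over 4 generations, miscoding with
  probability 0.6 per replication; distinct alleles across generations
  produce multiallelic sites whose VAF follows a halving geometric
  series. Depths are Poisson(50) with beta-distributed VAF noise, and
  alleles require ≥ 2 supporting reads (the base-quality filtering is
  applied by the generator, not re-derived from reads).
* **Repair**: a global probability `0.25 + 0.30 × accessibility`,
  modulated within ±73 bp of nucleosome dyads by
  `0.7 · (1 − 0.6·cos(2πd/10.3))` (inward-facing major groove least
  repaired), plus TCR for template-strand lesions rising log-linearly
  from 0.287 TPM to saturation at 10 TPM with maximal removal 0.8 and a
  20% TCR-invisible lesion fraction. The log-linear response with a
  saturation floor reflects the reported log-linear expression–rate
  relationship and the plateau above ~10 TPM; a removal probability
  linear in TPM would concentrate the whole effect in the top stratum
  and cannot reproduce that shape.
* **TLS artefacts**: collateral mutations 1–10 nt downstream of 1% of
  clonal substitutions, drawn at non-A template bases with a G→T
  preference; 1 bp T skip-deletions (1% of surviving T lesions) with
  downstream A→C/G→T substitutions; 1 bp insertions downstream of 0.4% of
  substitutions; strand-unbiased background indels at 3e-6/bp.
* **TRIM**: every generation-1 repaired lesion with an opposite-strand
  lesion within 26 nt templates a resynthesis mutation with probability
  0.9, flagged shared-between-daughters.
* **Annotation**: ~300 non-overlapping genes with log-normal nascent TPM
  (log-sd 1.8), 70% co-oriented with the local fork direction; a smooth
  sinusoidal replication-time field (3 Mb wavelength) from which
  early/late and Okazaki counts are drawn; planted genome-matching motifs
  with an information-content profile (damage multiplier 0.4 at
  high-information positions, optional single-offset hotspot) and
  accessibility peaks; dyads every 200 bp.

What the generator does *not* emulate: sequence-context-realistic damage
chemistry (lesion placement ignores flanking bases), copy-number and
structural variation, cellularity and contamination, independently
segregating homologs, mappability artefacts, or signature mixtures.
Passing recovery tests therefore demonstrates that the analysis correctly
inverts this generative model at desk scale, not that it is robust to
every artefact of real sequencing data.

## Numerical and design choices

* Coordinates are 0-based half-open internally; 1-based tables are
  converted at the reader boundary. Indels are stored anchored
  (VCF-style); alignment ambiguity is handled only in the enumeration
  step, which supersedes any single normalisation.
* N-containing contexts and chromosome-edge positions are excluded from
  spectra and composition.
* Quantile bins break ties by input order (stable), so a larger value
  never receives a smaller bin.
* Bootstrap intervals are percentile 95% with 50–100 replicates,
  resampling the natural unit (segments, genes, regions, or tumours) and
  always seeded.
* Empty strata, all-zero spectra, zero-coverage windows and degenerate
  expression distributions return flagged missing values or a
  single-stratum fallback rather than errors.
* `strata_assign()` fits the flat–sloped–flat rate–expression curve by
  grid search (50 log-spaced candidates per breakpoint, least squares,
  no continuity constraint); `assign_strata_by_tpm()` applies fixed
  breakpoints (0.287 and 3.73 TPM) when the fitted ones are not wanted.
  Recovery is validated to within 25% of planted breakpoints.
* The damage/repair classification calls a position `excess_damage` when
  mutation enrichment is elevated without a matching multiallelism
  increase, and `protected` when reduced without a matching decrease;
  repair-driven changes move both metrics in the same direction, so
  same-direction pairs other than (up, up) are neutral.
* Problem sizes in the tests (8–12 tumours of ~9,000 mutations on an
  18 Mb genome, 1,000-instance oracle sweeps, 200-replicate calibration
  loops) were chosen so the full suite completes in a few minutes while
  leaving each statistical check clearly powered.

## Known limitations

* The segmentation is a simple binary search, not a reimplementation of
  the original study's segmentation; agreement is at the ≥ 95%
  mutated-bp level, not boundary-exact.
* Headline statistics from the real 237-tumour cohort (odds ratios of
  11.9, 103, 16.5, 2.84, regression p-values below 1e-300) are functions
  of that cohort's size and genome and are not reproducible at desk
  scale; the pipeline reproduces their directions and, where density
  permits, their magnitudes.
* The empirical P of the up/down bias is conservative by construction at
  small pair counts (add-one correction on a discrete statistic).
* Read-level evidence is abstracted to per-site allele depths plus a
  read co-occurrence table; no BAM parsing is performed.
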