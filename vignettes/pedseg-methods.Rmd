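---
title: "Methods: models, parameters and design choices in pedseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in pedseg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedseg)
```

`pedseg` analyses the joint contribution of rare single-nucleotide
variants (SNVs) and copy-number variants (CNVs) to a phenotype segregating
in a family. This vignette documents the statistical models behind each
stage, the parameters a user may want to change, and the design decisions
that were genuinely open — together with why we resolved them the way we
did.

## The prioritization cascade

The cascade reduces a multi-sample exome call set to a handful of
candidate lesions. Stages, in order, with defaults from
`cascade_config()`:

* **Read depth** — every exome used for the sharing analysis must cover
  the site with *strictly more than* `min_depth = 10` reads. The bound is
  strict (depth 10 fails) because the source protocol states the filter
  as "greater than 10" and boundary conventions matter when counts are
  small.
* **Population frequency** — every *available* frequency among ExAC,
  gnomAD and 1000G must be below `maf_threshold = 0.01`. Missing cells
  pass: a variant absent from a database is evidence of rarity, not of
  commonness, and coercing `NA` to 0 or to "fail" would silently change
  the candidate set (one of the final candidates is unobserved in 1000G).
  A variant missing from *all three* databases passes with a warning.
* **Consequence** — missense only by default; stop-gains are counted
  separately (before this filter) so that "no nonsense variants
  survived" is a checkable statement rather than a tautology.
* **Sharing** — carriers (het or hom-alt) in every sequenced affected
  member of the nuclear family, homozygous reference in the sequenced
  unaffected member. A missing genotype in either set drops the variant:
  sharing that cannot be established is not sharing. Members affected by
  non-psychotic mental disorders belong to *neither* set — they are
  uninformative for a psychosis-specific lesion.
* **Conservation** — the source analysis used "conserved region
  according to several algorithms" without an operational rule, so one
  had to be chosen here: a site is conserved when SiPhy ≥ `siphy_min = 8`
  (29-mammal log-odds; strong evidence on its own), or when GERP RS ≥
  `gerp_min = 4` *and* phyloP100 ≥ `phylop_min = 1` agree at vertebrate
  scale. This is the loosest standard-practice rule under which all 19
  published profiles pass (their minimum SiPhy is 8.383) while typical
  neutral profiles (SiPhy ≈ 2, phyloP < 1) fail. All three bounds are
  configurable.

Survivors are then triaged rather than filtered: cortex expression at any
level (`yes`, `yes_low`, `yes_very_low`) keeps a variant, only a blank
expression cell fails; the VUS subset, its protein-impact consensus
subset, and the disease-associated subset are computed on the expressed
survivors. The **consensus rule** counts damaging calls over the 8
categorical predictors (SIFT = D; PolyPhen2 ∈ {D, P}; MutationAssessor ∈
{H, M}; MetaSVM = D; MetaLR = D; FATHMM = D; LRT = D; MutationTaster ∈
{A, D}) and flags a variant at `min_calls = 6` of 8. "Almost all
algorithms" is not a number; 6-of-8 is the threshold that separates the
clearly consensus-damaging profiles (7, 7 and 8 calls) from everything
else (≤ 5) in the packaged tables, and `NA` cells never count. VEST3
reports only a score, no call, and is excluded from the count.

Final candidates are the intersection of the VUS and disease-associated
views. Disease-associated variants classified benign or likely benign are
*retained* as caveat candidates rather than discarded — clinical
classifiers are calibrated for Mendelian penetrance, not for risk alleles,
and a segregation follow-up is cheap. Gene constraint ranking
(`rank_intolerance()`) is RVIS-primary with LOEUF as tie-break; the two
scores measure different things (common functional variation vs
loss-of-function depletion) and no principled precedence exists, so the
package picks the older, better-calibrated-at-the-time score first and
documents the choice.

## The BAF/LRR segmentation model

Array CNV callers of the PennCNV family model two per-probe summaries: the
B-allele frequency (BAF), which splits heterozygous probes from 0.5 into
1/3 and 2/3 bands under a single-copy gain, and the log R ratio
(LRR = log2 of observed over expected intensity), which shifts by
`log2(3/2) ≈ +0.585` for three copies in the ideal case. The commercial
algorithm that produced the original calls is unpublished, so `pedseg`
implements the standard construction its outputs imply: a three-state
(CN 1/2/3) hidden Markov model over position-sorted probes, decoded by
Viterbi, per chromosome.

Emissions (`cnv_config()`):

* LRR ~ Normal(state mean, `lrr_sd = 0.2`) with state means
  `-lrr_del = -0.6`, 0, `+lrr_dup = +0.4`. The duplication mean is
  attenuated from the ideal 0.585 because array intensities saturate;
  +0.4 is the empirical textbook value.
* BAF, for probes in the heterozygous range only, is a Gaussian mixture
  over the state's het clusters (0.5 for CN2; 1/3 and 2/3, equal weights,
  for CN3; none for CN1) with `baf_sd = 0.05`. Probes with BAF within
  `hom_cut = 0.15` of 0 or 1, and no-call probes, are uninformative for
  BAF and contribute through LRR alone — homozygous probes look identical
  in every state.
* Every density is mixed with a flat outlier component
  (`outlier_frac = 0.01`) so single aberrant probes cannot dominate a
  log-likelihood.

The transition probability between copy-number states is
`trans_prob = 1e-4` per probe: at 2 kb spacing this encodes an expected
segment scale of megabases, matching the size of reportable germline
CNVs. Runs of non-diploid state shorter than `min_probes = 10` are not
reported, and `filter_segments()` removes calls spanning fewer than
80,000 bp (closed-interval span), the size filter used in the source
protocol. Reported breakpoints are the positions of the first and last
probe in the run — resolution is therefore one probe spacing, and the
recovery tests require breakpoints within two spacings of the planted
truth.

Sample QC precedes calling: a missing call rate above 1% (strictly; a
rate of exactly 0.01 passes) fails the sample, since an elevated no-call
rate with distorted BAF/LRR is the signature of contamination. States are
limited to CN 1–3; homozygous deletions and high-order amplifications are
out of scope (the copy-number field reserves the values).

## The ddPCR Poisson model

Partitioning a sample into `n` droplets Poisson-distributes template
copies, so the concentration follows from the positive fraction
`p⁺ = k/n` as `λ = −ln(1 − p⁺)` copies per droplet. Copy number is the
reference-scaled ratio `CN = 2 λ_t / λ_r`; droplet volume cancels, which
is why the package never asks for it. The 95% interval propagates the
binomial variance of each fraction on the log scale
(`var(ln λ) = p / (n (1−p) λ²)`) — the delta method is accurate here
because tens of thousands of droplets make the fractions nearly Gaussian.
A saturated well (every droplet positive) carries no concentration
information and is an error, as is a reference well with no positives.

Carrier calls require the whole interval to clear the boundary:
`duplication` when the lower limit exceeds 2.5, `deletion` when the upper
limit is below 1.5, `normal` when the interval lies inside (1.5, 2.5),
otherwise `ambiguous`. The 1.5/2.5 midpoints between integer copy numbers
are a package decision (the source only states that values "close to 3"
indicate duplication); the CI guard keeps the type-I rate of the carrier
call far below 5% at 20,000 droplets.

## Evidence integration and the digenic model

`build_carrier_matrix()` merges platform evidence into one state per
(member, lesion): Sanger overrides exome genotypes for SNVs and ddPCR
overrides the array for CNVs, because those are the validation assays;
a same-tier contradiction leaves the state `unknown` with a warning.
Removing evidence can only move states toward `unknown`, never flip a
carrier to a non-carrier — a property the tests enforce.

`evaluate_digenic()` scores a rule "carrier of the SNV and of ≥ 1 named
duplication ⇒ at risk" by its consistency with affection. Members are
excluded from the denominator when their affection is neither psychosis
nor unaffected, or when the rule's required states cannot be determined.
The default `strict` mode assumes complete penetrance of the *rule*; the
`asymmetric` mode, in which only affected members lacking the risk
genotype count as inconsistent, exists because duplication penetrance in
such pedigrees is plausibly low and a user should be able to score under
that assumption without redefining consistency by hand.
`exhaustive_model_scan()` enumerates every single-SNV × duplication-subset
rule (the pool is capped at 12 lesions; enumeration is exact, no search
heuristics) and breaks consistency ties toward fewer required lesions —
the more parsimonious rule.

A seven-member family cannot support a segregation likelihood or LOD
score, and the package deliberately computes none; consistency fractions
describe the configuration, they do not test a hypothesis.

## What the generator emulates — and what it does not

`simulate_pedigree_vcf()` draws founder genotypes under Hardy–Weinberg at
configurable frequencies and transmits alleles by fair Mendelian
segregation; planted variants force heterozygous carrier sets and reject
configurations impossible without a de novo event. Depths are
Poisson(`depth_mean = 40`) truncated at 1 — typical exome coverage —
except where a test sets them deterministically.
`simulate_array_track()` places probes at fixed spacing (default 2 kb,
the density of a ~700k-probe array over a ~3 Gb genome), draws each
probe's B-dose binomially in the local copy number at population
frequency 0.5, and adds Gaussian noise (`baf_sd = 0.03`,
`lrr_sd = 0.15`, mid-range values for modern arrays) with BAF clipped to
[0, 1]; clipped Gaussian noise was chosen over a beta model for
transparency — the caller must not be tested against its own emission
model, and the slight boundary pile-up the clipping produces is exactly
the kind of mild misspecification a robust caller should tolerate.
No-calls are injected as an exact count to hit a target missing rate.
`simulate_ddpcr_wells()` thins Poisson occupancy into binomial positive
counts, which is the exact partition model.

The generator does **not** emulate: GC waves and spatial artefacts on
arrays, genotyping-cluster asymmetries, linkage disequilibrium between
background variants, sequencing error in genotypes, or droplet "rain".
Passing tests therefore demonstrate correctness of the statistical
machinery under the stated models, not robustness to every real-data
artefact; the outlier components and QC gates are the package's only
defences there, and real-data validation (e.g. the ddPCR tier) remains
essential, as it was in the source study.

## Numerical choices and degenerate inputs

Viterbi decoding runs in log space with ties broken toward the
lower-indexed state (deterministic). Chromosomes are processed
independently; segments never span chromosomes. Coordinates are 1-based
inclusive everywhere, with closed-interval overlap for gene annotation —
the VCF convention, so published positions can be compared directly.
Multi-allelic VCF rows are decomposed per ALT allele with the per-sample
depth duplicated onto each record. Empty inputs propagate as empty
tibbles with correct types and a failure exit status (3) in the pipeline
report, never as errors. All randomness flows through explicit `seed`
arguments; a fixed seed reproduces every output byte-identically,
including the written report files.

## Problem sizes used by the test-suite

The shipped tests run the study at desk scale: 2,000-probe chromosomes
(50 seeds per duplication locus for recovery rates), 200 replicates of
20,000-droplet well pairs for estimator calibration, 200 random
instances of ≤ 12 variants × ≤ 6 samples for the brute-force cascade
cross-check, and the 13-member family bundle for end-to-end runs. These
sizes give Monte-Carlo standard errors comfortably below the asserted
tolerances while keeping a full run under a minute.

## Known limitations

* Conservation and consensus thresholds are calibrated to reproduce a
  specific published analysis; other cohorts may warrant different cuts
  (all are exposed in `cascade_config()`).
* Gene constraint scores ship only for the gene the source reports
  (RVIS −3.92 at the 0.21 percentile, LOEUF 0.084); other genes load as
  `NA` and rank last rather than being imputed.
* The expression filter is categorical; per-tissue TPM thresholds would
  require expression matrices the annotation fixture does not carry.
* INDELs, phased genotypes, structural-variant ALT syntax and
  INFO-field annotations are out of scope for the VCF layer.
* CN 0 and CN ≥ 4 states, raw-intensity normalization and fluorescence
  gating are out of scope for the CNV/ddPCR layers.
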