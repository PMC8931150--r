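---
title: "Dosage-based molecular sexing: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dosage-based molecular sexing: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvsex)
```

## The dosage model

In species with X0/XX sex determination, males carry a single X chromosome
and females two. Any single-copy X-linked gene is therefore present in one
copy per diploid genome in males and two in females, while an autosomal
single-copy gene sits at two copies in everyone. The copy number of the
X-linked *target* gene, normalised by the autosomal *reference* gene,

$$\mathrm{CNV} = 2 \cdot \frac{q_\text{target}}{q_\text{reference}},$$

is thus 1 in males and 2 in females, whatever the amount or quality of
input DNA — both quantities are measured from the same extract, so the
input mass cancels. `cnvsex` implements the two standard ways of measuring
that ratio and the statistics used to validate the resulting sex calls.
The shipped assay panel (`ld_assays()`) is the Colorado potato beetle
pair: the X-linked voltage-sensitive sodium channel gene as target and the
autosomal ubiquitin-protein ligase E3B gene as reference, with amplicons of
243 and 250 bp under 1-based inclusive primer coordinates.

## Droplet digital PCR backend

A ddPCR reaction is partitioned into $N$ droplets of volume $v$; template
molecules land in droplets approximately independently, so the number per
droplet is Poisson with mean $\lambda = c\,v$ for template concentration
$c$. A droplet is *negative* when it received no template, which happens
with probability $e^{-\lambda}$. `poisson_concentration()` inverts the
observed negative fraction:

$$\hat\lambda = -\ln\frac{n_\text{neg}}{n_\text{neg}+n_\text{pos}}, \qquad
  \hat c = \hat\lambda / v.$$

`cnv_ddpcr()` then forms $2\,\hat c_\text{target}/\hat c_\text{reference}$.
Numerical edge cases: a well with no negative droplets is saturated and the
concentration is not estimable (an error naming the condition, not a
clamped value); a well with no droplets at all is rejected; a well with no
positive droplets legitimately estimates $c = 0$, which then triggers a
division error (naming the reference gene) only if it is the reference.

Parameters that matter:

* `droplet_volume_nl` (default 0.85 nL) — the vendor partition volume.
  Absolute concentrations scale inversely with it, but it cancels in the
  CNV ratio, so sexing is insensitive to the exact value. Published
  per-well concentrations produced by vendor software are not a
  reproduction surface for this reason.
* `min_droplets` (default 10,000) — wells with fewer accepted droplets are
  excluded and reported via the `excluded_wells` attribute. Routine runs
  accept ~15,000–20,000 droplets; the default is a conservative floor, and
  no published threshold exists, so it is configurable.

"Rain" (intermediate-amplitude) droplets are out of scope: inputs are
already-thresholded positive/negative counts.

## Real-time PCR backend

### Standard curves and efficiency

A dilution series (defaults mirror a 20, 10, 5, 2.5, 1.25 ng design) gives
the regression $Ct = b + m\,\log_{10}(\text{input})$, fitted by ordinary
least squares in `fit_standard_curve()`. The per-cycle amplification
factor is $E = 10^{-1/m}$ (2 for perfect doubling, slope $-3.3219$) and
the conventional percent efficiency is $(E-1)\times 100$. Throughout the
package, the `E` entering the quantification formula is the *factor*
(≈ 2), never the percent — the formula needs the base of exponential
amplification, and percents printed in assay reports convert as
$E = 1 + \%/100$.

Raw-Ct relative quantification assumes comparable efficiencies for the two
genes. `validate_slope_difference()` implements the usual admissibility
rule: the absolute slope difference must not exceed 0.1. `qpcr_pipeline()`
refuses to run when the rule fails unless explicitly overridden (the
override is logged via a warning).

### Calibrator-relative quantification

Technical replicates are aggregated by the arithmetic mean of Ct
(`mean_ct()`), matching how such assays report replicate means. A replicate
SD above 0.5 cycles, or a dropped-out replicate (no amplification), flags
the aggregate but does not discard it: the mean of the remaining replicates
is used, mirroring routine practice when one well of a triplicate fails.

Each run designates one male *calibrator*. Relative to a single-copy male,
the efficiency-corrected ratio (`pfaffl_cnv()`)

$$\mathrm{CNV} =
  \frac{E_\text{target}^{\Delta Ct_\text{target}}}
       {E_\text{reference}^{\Delta Ct_\text{reference}}},
\qquad \Delta Ct = \overline{Ct}_\text{calibrator} - \overline{Ct}_\text{sample},$$

is directly the target copy number. Sign convention: with the calibrator's
mean Ct first, a female's target amplifies about one cycle *earlier* than
the male calibrator's, so $\Delta Ct_\text{target} \approx +1$ and the
ratio is ≈ 2. The calibrator's own CNV is exactly 1 by construction.

`select_calibrator()` encodes the two policies:

* sexes known (adults scored morphologically): a uniformly random male,
  reproducible under a seed — using a random male rather than a fixed one
  reflects how large multi-run studies operate;
* sexes unknown (larvae): the specimen maximising
  $\overline{Ct}_\text{target} - \overline{Ct}_\text{reference}$. A
  single-copy male has half the target template and so amplifies the
  target roughly one cycle later; the maximiser is the most probable male.
  This is a design choice on a genuinely ambiguous point: the informal
  field heuristic is phrased as "lowest ΔCt", which corresponds to the
  opposite sign convention for ΔCt; under the convention above the male is
  the *highest*. The policy here follows the biology, not the phrasing.

Because the run offset (plate effects, master-mix batch, instrument drift)
enters every Ct of a run additively and identically for both genes, the
calibrator-relative difference cancels it exactly. This is why CNVs are
computed and interpreted within runs, and why no universal cross-run
calibrator is supported: cross-run comparability of raw Ct is exactly what
cannot be assumed.

## Sex calling

`call_sex()` thresholds at 1.5, the midpoint between the expected copy
numbers — published validations of this assay rely on visually separated
bimodal clusters and state no numeric rule, so the midpoint is the natural
default, and it is configurable. A value exactly at the threshold is
`ambiguous` (a measure-zero event in practice; the explicit category
avoids a silent arbitrary tie-break). Calls further than
`band_halfwidth = 0.5` from their expected copy number keep their call but
are flagged `in_band = FALSE`: field data contain correct calls as far out
as 0.32 or 2.67, so out-of-band values are a quality signal, not a
rejection. When two biological replicates disagree across the threshold,
`call_cohort()` returns `ambiguous` with a conflict flag rather than
voting — the conservative behaviour for a diagnostic.

## Validation statistics

`validate_cohort()` assembles the battery used to validate the assay:

* **Descriptive summaries** per called sex: n, mean, sample SD, t-based
  95% CI half-width, min, max, CV. For a two-replicate design the
  summaries are computed over per-specimen means (n = number of
  specimens), which is the scale at which such tables are reported.
* **Paired t-test** (`paired_t()`) on per-specimen CNVs of the two
  biological replicates, two-sided, via `stats::t.test`; a zero-variance
  difference vector is a degenerate-test error rather than t = NaN.
* **Shapiro–Wilk** (`shapiro_wilk()`) on the replicate differences, via
  `stats::shapiro.test` (Royston approximation), as the normality
  prerequisite of the paired t.
* **Phi coefficient** (`phi_coefficient()`):
  $\Phi = (ad-bc)/\sqrt{(a+b)(c+d)(a+c)(b+d)}$ with p from
  $\chi^2 = n\Phi^2$, df = 1. Any zero margin makes the coefficient
  undefined and is an error.
* **Chi-square 1:1 goodness of fit** (`chi_square_1to1()`), Pearson's
  uncorrected formula, df = 1, no continuity correction. For a 27:23
  split this gives 0.32 (and 0.18 with Yates correction); a published
  value of 0.16 for that split matches neither standard formula and is
  documented here rather than matched.
* **Bimodality amplitude** (`bimodality_amplitude()`):
  $BA = (A_s - A_v)/A_s$ with $A_s$ the count of the smaller of the two
  highest local-maximum bins and $A_v$ the minimum count between them.
  The underlying statistic is defined only up to a binning; this package
  fixes 0.1-wide bins over [0, 3] (a resolution that separates clusters
  of SD ≈ 0.05–0.25 without fragmenting them). Published BA values
  computed under unstated binning are therefore treated as qualitative:
  the package uses BA > 0 as the bimodality prerequisite for calling, and
  does not attempt to reproduce specific printed BA numbers. Plateaus in
  the histogram count once (at their left edge); with fewer than two
  local maxima BA is 0 by convention.

Two-sided p-values throughout; no multiple-testing correction is applied,
matching how such validation batteries are reported.

## The synthetic-data generator

`simulate_cohort()` draws sexes i.i.d. with `female_fraction` (default
0.5) and assigns true copy numbers (target 2/1, reference 2).
`simulate_qpcr()` is the forward model of the quantification equation:

$$Ct = b_g + m_g \log_{10}\!\big(\text{input}_\text{ng}\, k/2\big)
       + u_\text{run} + \varepsilon,$$

with $k$ the true copy number of gene $g$,
$u_\text{run} \sim N(0, \texttt{sd\_run})$ shared by *all* wells of a run
(both genes — which is what makes calibrator-relative CNV run-invariant by
construction), and $\varepsilon \sim N(0, \texttt{sd\_tech})$ independent
per technical replicate. `simulate_ddpcr()` draws positive-droplet counts
binomially with occupancy $1 - e^{-cv}$ at a concentration of
`copies_per_haploid` (default 300 copies/µL, a typical mid-dynamic-range
loading; configurable) per gene copy.

Defaults are the conditions of a routine assay of this design: curves
(−3.324, 38.476) and (−3.341, 36.528); 20 ng input; technical triplicates;
`sd_tech` = 0.15 cycles; `sd_run` = 1.0 cycles; 17,000 droplets of
0.85 nL. Under this model the estimated CNV SD in females is twice that in
males (both inherit the same log-scale Ct noise, and the female mean is
twice as large): at the default `sd_tech` the simulated SDs are ≈ 0.24 (F)
and ≈ 0.11 (M), bracketing the 0.227/0.147 dispersion observed in
field-scale data. The field ratio (≈ 1.5) is not exactly 2, suggesting a
noise component the Ct-level model does not carry (e.g. per-extract
quality effects); the generator deliberately stays with the simpler
mechanistic model rather than adding an ad-hoc term to match both SDs.

What the generator emulates: gene-dosage signal, amplification-efficiency
differences between genes, run offsets, technical-replicate noise, droplet
sampling noise. What it does not: PCR inhibition and extract-quality
variation, droplet rain, pipetting-volume error, cross-run efficiency
drift, and any deviation from Poisson droplet loading. Passing recovery
tests therefore demonstrate correctness of the estimators under the stated
noise model, not robustness to every artefact of real plates.

All generators are deterministic given `seed`; sub-streams for sexes, Ct
noise, and droplet counts use fixed offsets from it, so enlarging one part
of a simulation does not reshuffle another.

## Problem sizes and reproducibility

The packaged analyses use desk-scale sizes chosen to make every stage
legible: the 20-specimen reference fixture for the statistics battery;
noise-free cohorts of ~20 for exactness checks; 448 individuals over 28
runs (16 per plate, one random male calibrator each) repeated over 20
seeds for the field-scale recovery experiment, which completes in seconds
and yields mean accuracy ≈ 0.995 and Φ ≈ 0.99 under default noise.
`scripts/acceptance.R` recomputes the headline quantities from scratch;
`analysis/01..03` are the narrative drivers writing the same tables under
`results/`.

## Known limitations

* One reference gene; multi-reference normalisation is out of scope.
* Copy numbers above 2 (e.g. duplicated targets) are outside the calling
  model — calls are binary with an ambiguity category.
* The ddPCR backend consumes thresholded droplet counts; fluorescence
  thresholding and merged-well confidence intervals are not implemented.
* Between-run CNV comparison is intentionally unsupported (see the
  calibrator section).
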