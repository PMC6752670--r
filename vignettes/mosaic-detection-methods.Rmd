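---
title: "Detecting and quantifying postzygotic mosaicism: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and quantifying postzygotic mosaicism: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaicfrac)
```

## The problem

MECP2 variants cause Rett syndrome, an X-linked condition in which
constitutional loss-of-function variants are typically lethal to males
in utero. Surviving affected males are therefore enriched for
*postzygotic* (mosaic) variants — present in only a fraction of cells —
and unaffected fathers can carry *germline-confined* mosaicism that is
invisible in blood yet transmissible to daughters. Both situations are
quantified by the mutant allelic fraction (MAF): ~50% for a
constitutional heterozygote, anywhere below that for a mosaic, down to
hundredths of a percent in sperm fractions.

This package implements the three quantification assays such a study
chains together — deep panel screening, ultra-deep amplicon validation,
and droplet digital PCR (ddPCR) — plus the cohort-level exact
statistics, and a synthetic-data generator that stands in for the
patient samples (which are not publicly deposited).

## Screening genotyper

At a site with `k` alternative reads out of `n`, a read supports the
alternative allele with probability

$$p(f) = f\,(1-e) + (1-f)\,e,$$

where `f` is the MAF and `e` the per-base miscall probability
(Phred-derived; default `1e-3`, i.e. Q30). The posterior of `f` under a
uniform prior is computed on a grid of step `1e-4` — more than ten times
finer than the 0.5% decision boundary — and summarized by the MAP and
the equal-tailed 95% credible interval. Decision bands, applied in
order:

* **hom-ref** if the lower 95% bound is below 0.5%;
* **het** if the MAP lies in 45–55%;
* **hom-alt** if the MAP lies in 99.5–100%;
* **mosaic candidate** otherwise.

Three conventions deserve note. The het rule is applied to the MAP, not
to interval overlap, because the band is phrased as a MAF threshold.
The hom-alt band mirrors the het band on the MAP for the same reason.
And when the posterior mode sits on a boundary of `[0, 1]` (e.g.
`k = 0`), a literal equal-tailed interval would exclude the mode, so
the interval collapses to the one-sided form anchored at the boundary —
a site with no alternative reads reports `ci_low = 0`, as it should.

The uniform prior makes the credible interval calibrated by
construction when true fractions are themselves spread over `[0, 1]`;
the acceptance suite verifies coverage in `[0.93, 0.97]` over 2000
simulated sites at 1000×, and a false-candidate rate below 1% at
`f = 0`. No posterior odds between genotype classes are used: class
assignment is by thresholds, which reproduces the published decision
rules without assuming class prior weights the source does not state.

## Amplicon validation (hierarchical error model)

Validation re-sequences a candidate site at ~12,000× from ~20 ng of DNA
(~6000 genome copies). At that depth the error rate itself is the main
nuisance parameter, so it is learned rather than assumed: variant-free
control sites yield per-site alt fractions to which a Beta distribution
is moment-matched (mean floored at `1e-6`; when the sample variance is
degenerate the concentration falls back to the pooled control depth).
The site likelihood then marginalizes the error:

$$L(f) = \mathbb{E}_{e \sim \mathrm{Beta}(\alpha,\beta)}
  \left[\binom{n}{k} p(f)^k (1-p(f))^{n-k}\right],$$

evaluated by midpoint quadrature over 32 Beta quantiles — ample, since
the error posterior is tight at this depth; with a point-mass error
model the estimator provably collapses to the screening posterior
(tested to `1e-6` per grid cell). The validation thresholds keep the
0.5% floor but widen the het band to 40–60%: validation must not
promote a borderline constitutional heterozygote. Whether the original
tool's interval was equal-tailed or highest-density is not stated; the
equal-tailed form is used because it is order-statistic testable.

Parameter recovery at the study's set-points (`f` from 0.5% to 38%,
12,000×) achieves median absolute error below `max(0.002, 0.1 f)`. The
interval-coverage check is computed *exactly*, by summing the
`Binomial(12000, p(f))` read-count law over its `1e-7`–`1−1e-7`
quantile range, rather than by Monte-Carlo — the exact per-`f` coverage
is 0.950–0.967, comfortably inside the `[0.93, 0.97]` band that a
finite-replicate estimate straddles noisily.

## Droplet digital PCR

Droplets are gated rectangularly on the two fluorescence channels: FAM
at or above threshold is mutant-positive (MU) regardless of VIC — the
mutant probe signal dominates — otherwise VIC at or above threshold is
wild-type (WT), otherwise empty (NA). Thresholds are fixed, not
clustered: deterministic, and faithful to quadrant gating. The primary
estimate is the published formula

$$\widehat{\mathrm{MAF}} = \frac{MU}{MU + WT},$$

with the exact Clopper–Pearson 95% interval (beta-quantile form) —
chosen because it is the only binomial interval that is unambiguous,
exact, and reproducible without knowing which approximation the
original software used.

An optional occupancy correction converts positive-droplet fractions to
concentrations, $\lambda_c = -\ln(1 - \text{positives}_c/\text{total})$
per channel against the droplet total, and reports
$\lambda_{MU}/(\lambda_{MU}+\lambda_{WT})$, mapping the raw interval
through the same monotone transform. This per-channel-vs-total form is
symmetric (equal counts give exactly 0.5) but ignores mutant/wild-type
double occupancy, leaving a relative bias of order $\lambda_{MU}$;
negligible in the rare-mutant regime the assay targets, and the reason
the acceptance recomputations load droplets at occupancy 0.04, where
that bias sits below sampling error.

The detection limit is probed by simulation: the default decision rule
is "at least 3 mutant droplets" (the source quotes the 10⁻⁴ limit but
not its rule; 3 positives is the conventional minimal-cluster call).
At 10⁵ loaded copies the power curve saturates near the 10⁻⁴ fraction —
10 expected mutant molecules — matching the quoted limit.

## Cohort statistics

Confirmed mosaics by sex form a 2×2 table. With all margins fixed, the
first cell follows the (noncentral) hypergeometric law; all mass is
computed in log space via `lgamma`, overflow-free for cohort-sized
margins. Three quantities are produced:

* **Two-sided p** by the point-probability method — summing every
  margin-consistent table whose probability does not exceed the
  observed one (relative tie tolerance `1e-7`). This method uniquely
  reproduces the published `p = 0.0004492` for the (3, 15; 2, 451)
  table, and is verified against literal enumeration on *every* 2×2
  table with grand total ≤ 40.
* **Conditional-MLE odds ratio** ψ̂, the root of the score equation
  $\mathbb{E}_\psi[X] = a$, bracketed and solved to `1e-10`. For the
  cohort table this gives 43.503; reference exact-test software prints
  43.47 because its root search stops at a looser default tolerance on
  a likelihood that is flat at this scale — the two agree to 0.07%.
* **Exact confidence bounds** by test inversion
  ($P(X \ge a \mid \psi)$ equal to the tail level for the lower bound).
  The published "6.33 – inf" interval is a one-sided 95% bound — a
  two-sided exact interval for this table is finite above (≈557) — so
  both forms are computed and labelled.

## Synthetic-data generator: what it emulates, and what not

All inputs are generated with the sampling structure the assays impose:

* **Two-stage reads.** Mutant templates
  `m ~ Binomial(input_copies, f)`, then reads
  `Binomial(n, m/input_copies)`, then symmetric miscalls. With depth ≫
  input copies (amplicon: 12,000× from 6000 copies) replicate variance
  exceeds binomial — the PCR-bottleneck overdispersion that fundamentally
  limits validation precision, verified against the analytic two-stage
  variance. `input_copies = Inf` gives the bottleneck-free limit.
* **Droplets.** Molecules land uniformly at random in droplets (the
  conditional-on-total form of Poisson loading); any mutant molecule
  makes a droplet MU. A configurable false-MU rate (default 0) exists
  to stress the detection-limit analysis.
* **Cohort.** Sex-stratified Bernoulli mosaicism at the study rates
  (3/18, 2/453), with mosaic MAFs drawn uniform on 6.5–38% — the range
  of confirmed proband blood MAFs; an exact-count mode pins the truth
  table to those counts for end-to-end checks.
* **Tissue panels.** Three father scenarios: germline-confined (mutant
  template only in semen fractions, Layer-2-only or Sperm+Others
  patterns, default 0.67%), early-embryonic (semen 7.55%, saliva
  0.43%, blood 0.28% — the one father whose mutation clearly preceded
  soma/germline separation), and negative control.

Calibration and parameter-recovery checks run the estimators under
their own read-sampling model (the bottleneck-free limit): a read-count
credible interval cannot — and should not — cover at 95% under template
bottleneck overdispersion it does not model (at 6000 copies / 12,000×
the variance is ~3× binomial and coverage would drop to ~0.74). The
bottleneck is therefore tested as its own variance property, and in
practice means a single amplicon replicate cannot resolve MAF
differences below ~1/√6000 regardless of depth.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: read-level artifacts (strand bias, mapping
error, duplicates, clustered errors — the read-level filters of mosaic
callers exist precisely for these), PCR-cycle-explicit amplification
chemistry, fluorescence physics beyond separated Gaussian clusters, and
any phenotype structure. Real-data false-candidate rates will exceed
the synthetic ≤1% because real error is not i.i.d. symmetric.

## Parameters at a glance

| parameter | default | meaning |
|---|---|---|
| `error_rate` | `1e-3` | per-base miscall probability (Q30) |
| `depth` / `input_copies` | 1000× / 3000 (panel), 12,000× / 6000 (amplicon) | assay scale |
| `homref_lower_bound` | 0.005 | lower-CI floor for hom-ref at both stages |
| screen `het_band` | 0.45–0.55 | MAP band, screening |
| validation `het_band` | 0.40–0.60 | MAP band, validation |
| `grid_resolution` | `1e-4` | posterior grid step |
| quadrature `nodes` | 32 | Beta quantile nodes for error marginalization |
| ddPCR load | 5e4 copies / 5e5 droplets | occupancy 0.1 (generator default) |
| LoD rule | `mu >= 3` | detection decision, configurable |

## Problem sizes used by the checks

Screening calibration uses 2000 sites (plus 2000 null sites); amplicon
recovery 200 replicates per set-point with exact coverage summation;
detection power 200–500 runs per fraction; the end-to-end cohort is the
full 471 subjects. The acceptance script's ddPCR recomputations load
2×10⁵ copies into 5×10⁶ droplets (occupancy 0.04, see above).

## Known limitations

* The screening stage consumes count tables; it deliberately
  re-implements only the decision model of the original caller, not its
  read-level filters, so it cannot be compared read-for-read.
* The hotspot list ships with the ten canonical recurrent MECP2 sites;
  the original assay panel is supplementary material not reproduced
  here, so routing fractions differ from the study's.
* Male X-linked hemizygosity is not modelled separately: all sites are
  classified on the same MAF continuum, with sex carried as metadata.
  A hemizygous prior would sharpen male calls but the original rule set
  does not state one.
* The occupancy correction's per-channel-vs-total convention biases
  high-MAF corrected estimates by order λ of the mutant channel (see
  above); use dilute loading when that matters.
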