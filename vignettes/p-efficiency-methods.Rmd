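---
title: "Phosphorus efficiency metrics, the composite P indicator, and cross-platform agreement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phosphorus efficiency metrics, the composite P indicator, and cross-platform agreement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pindicator)
```

## The problem

Screening wheat germplasm for tolerance to phosphorus (P) deficiency
requires condensing a factorial trial — many genotypes grown at an optimal
(P+) and a deficient (P−) P supply — into quantities a breeder can rank on.
This package implements that condensation for rhizotron (Rhizotube) trials:
five per-genotype efficiency metrics, a composite 0–5 score (the
"P indicator"), a four-class efficiency/responsiveness typology, and the
agreement statistics used to compare two phenotyping platforms that ran the
same genotype panel. A companion imaging chain extracts the projected root
area from rotational rhizotron photographs, and generators with known
ground truth exercise every stage.

## The five metrics

With $U$ the whole-plant P uptake (g), $A$ the P supplied (g), $W$ the
plant dry weight (g), $W_r$ the root dry weight (g) and $c$ the tissue P
concentration:

* **PAE** $= U/A \cdot 100$ — the percentage of supplied P recovered in
  the plant. Jointly rescaling $U$ and $A$ (per tube versus per litre of
  substrate) cancels, which is why the ambiguous unit basis of the supply
  is harmless as long as uptake is expressed on the same basis.
* **PUE** $= W^2/c$ — the balance-method utilization efficiency. The
  squared-biomass form is implemented literally even though its units are
  unusual; the concentration unit (nominally mM) is carried through and
  never converted silently.
* **PRAE** $= U/W_r$ — P acquired per unit of the acquiring organ.
* **APUE** $= (W_{P+}-W_{P-})/(A_{P+}-A_{P-})$ — extra dry matter per
  extra unit of available P, computed on genotype means; negative
  responses are preserved.
* **PRE** $= W_{P-}/W_{P+} \cdot 100$ — biomass plasticity under
  deficiency (100 = no penalty).

Aggregation follows the replicate-then-mean convention: PAE, PRAE and PUE
are computed per tube and summarised as mean ± sample (n−1) SD per
genotype × level, matching how such trials report them; APUE and PRE are
single per-genotype values computed from genotype-mean dry weight. The
defining formulas say "dry weight" without naming a compartment, so the
default basis is whole-plant (shoot + root), switchable to shoot-only via
`metric_config(dw_basis = "shoot")`.

## The P indicator

For one condition (P− by default, since the score is meant to flag the
best performers *under deficiency*), the five metrics
{PAE, PRAE, PUE at that level; PRE; APUE} are each min–max normalized to
[0, 1] across genotypes and summed. All five are treated as
higher-is-better. The score is provably in [0, 5]; a genotype extreme in
all five metrics attains the exact bound. Ranks are dense (1, 2, 2, 3) on
descending score. A constant metric column normalizes to all 0.5 with a
warning — every genotype equally mid-scale — rather than an arbitrary 0
or 1.

Because min–max normalization removes any positive affine rescaling of a
single metric, the indicator is invariant to per-metric unit changes; this
is verified property-style in the test suite.

`normalization = "rank"` replaces each metric by the min–max of its
average ranks. It has the same bounds and ordering logic but is robust to
inputs whose resolution has been truncated (e.g. tables printed at one or
two significant digits). See "Reconstruction caveats" below for why this
variant is reported alongside the default.

## Quadrant classification

Crossing efficiency (whole-plant dry weight at P−) with responsiveness
(APUE) at thresholds computed across genotypes yields the four classes ER,
ENR, NER, NENR. Two conventions are fixed deliberately: thresholds default
to the across-genotype *mean* (the convention of the coffee-trial
classification this scheme follows; `rule = "median"` is available), and
boundary genotypes are classified upward (`>=`), which makes the
classification deterministic. Group sizes always sum to the panel size,
and switching mean→median can only move genotypes lying between the two
thresholds — both tested properties.

## Platform agreement

Three complementary statistics compare genotype-level series from two
platforms:

* Pearson r with the exact t-based two-sided p (n − 2 df) — linear
  association only.
* Lin's concordance correlation coefficient,
  $\mathrm{CCC} = 2 s_{xy} / (s_x^2 + s_y^2 + (\bar x - \bar y)^2)$ with
  population (1/n) moments, which additionally penalises location and
  scale shift; $|\mathrm{CCC}| \le |r|$ always. No installed package
  provides the CCC, so it is implemented here from the moments; the test
  oracle recomputes it longhand. Its significance uses the Fisher
  z-transform with Lin's (1989) asymptotic standard error — the original
  report does not state its p-value method, so this choice is ours.
* Bland–Altman limits of agreement: mean ± 1.96 × sample SD of the paired
  differences, with pairs outside the limits flagged. The 1.96 multiplier
  is the standard construction (configurable); under normal differences
  about 5% of pairs fall outside, a calibration asserted at n = 10,000 in
  the tests.

Metric correlation matrices across genotype means use the same Pearson
machinery, masking cells at p ≥ 0.05 without multiplicity correction —
the convention of the correlation figures they mirror (only significant
coefficients are shown). Correlations are computed on genotype means
(n = 26), the granularity of the published tables.

## Supporting inference

Two-way ANOVA (genotype × P level) uses the classical decomposition on
balanced data and Type II sums of squares when unbalanced — Type II tests
each main effect adjusted for the other and does not depend on factor
order, a reasonable default for mildly unbalanced harvests. Levene's test
is run in its Brown–Forsythe (median-centred) form — the robust variant —
because the original analysis names only "Levene"; Shapiro–Wilk runs on
the full model's residuals. Within-genotype P+ vs P− contrasts use
pooled-variance Student t-tests ("Student's t-test" being named, not
Welch), Bonferroni-adjusted by the number of genotypes tested. Cells with
zero pooled variance are handled deterministically: equal means give
p = 1, unequal means p = 0. The mixed-effects B-spline growth modelling of
the source analysis is deliberately out of scope; the package offers
descriptive per-tube B-spline fits only.

## The imaging chain

Six views at 60° intervals are merged into a panorama by horizontal
translation registration (1-D normalized cross-correlation of boundary
strips); full cylindrical unwarping is out of scope. SVD truncation
denoises the panorama — by Eckart–Young the approximation error is
non-increasing in rank, so the rank (default 60) trades noise against thin
structure. Segmentation is LoG-based: the Laplacian-of-Gaussian response at
scale `sigma` (about half the expected stroke width; default 1.5 px)
delimits root support out to the zero crossing, an Otsu threshold computed
over the intensities inside that support separates root from background,
candidate components not corroborated by the support are dropped, and
interior holes below ~16σ² px (where thick root clusters drive the
response negative) are filled while larger encircled background regions
are not. The upstream pipeline this mirrors published no LoG scale, SVD
rank or threshold rule, so these defaults are ours and exposed as
arguments. Cleaning keeps the largest 8-connected component whose topmost
pixel lies in the top 10% of rows ("from the top" being otherwise
unquantified); it never adds pixels. The projected area is the foreground
pixel count, converted with the pixel-size coefficient 0.0042 as printed
upstream — note that 600 dpi would imply 25.4/600 ≈ 0.0423 mm/px, so the
printed value is kept as a configurable default rather than resolved.

On rendered scenes (stroke ≥ 3 px, noise SD ≤ 0.05) the full chain
recovers the true area within 10% — typically within ~3% — and stitching
recovers the true view offsets within ±2 px.

## The generators

`simulate_trial()` emulates the statistical structure the analysis
assumes: a latent standard-normal efficiency per genotype drives log-scale
dry weight (slope 0.10 at P+, 0.25 at P− — tolerant genotypes lose less
biomass, making PRE informative), tissue P concentration (slope 0.05 —
efficient acquirers carry more P), and hence uptake
(= total DW × concentration, consistent by construction). A
genotype × level interaction (log-SD 0.05) and multiplicative log-normal
residual noise (CV 10%) complete the model; biomass being positive, CVs
rather than SDs are the natural error scale. Baselines (shoot 2.0 g at
P+, 0.35 g at P−; root:shoot 0.5/0.6; P fraction 1.3%/0.12%; supply
0.130/0.0014 g per tube, the Hoagland contrast integrated over a four-week
trial) were set once so the simulated metric ranges bracket the published
large-trial ranges (PAE roughly 10–90, PUE(P+) roughly 70–350, PRE below
100). Ground truth is produced by pushing the noise-free expectations
through `compute_metric_table()` itself, so no formula is re-derived when
scoring recovery.

`simulate_paired_platforms()` draws two latent vectors with correlation
`rho_true` and maps each through platform-distorted baselines; min–max
normalization inside the indicator removes the distortions, so the
cross-platform indicator correlation estimates `rho_true`
(0.447 recovered at 0.45 over 500 draws in the acceptance run).
`simulate_growth_series()` produces logistic per-tube area curves with
genotype asymptotes/midpoints and a P− asymptote multiplier (default
0.85). `render_root_scene()` grows one connected branching random-walk
root system from the top of the frame (lateral steps clamped to one pixel
per row so the dilated stroke stays 8-connected), composes a dark-root
image with additive Gaussian noise, and cuts it into six overlapping views
with known offsets.

What the generators do *not* emulate: spatial greenhouse gradients and
block effects, measurement censoring, heteroscedasticity beyond the
CV-scale, genotype-specific root/shoot allocation strategies, and real
root-image texture (soil particles, condensation, uneven illumination).
Passing recovery tests therefore demonstrates internal consistency of the
pipeline under its own assumptions, not field validity.

## Reconstruction caveats

Two published quantities are only partially reproducible from the printed
genotype-mean tables that ship with the package:

* Of the five metric correlations, four reproduce within ±0.03 from
  genotype means; the 4PMI P+ PAE–PUE cell gives 0.77 against the printed
  0.81, consistent with the original having been computed on
  replicate-level data (n = 156), which the printed means cannot recover.
* The cross-platform indicator agreement from the min–max construction on
  the printed means gives r = 0.30, CCC = 0.26 against the published
  0.426/0.424. All documented alternative constructions (P+ components,
  averaged or mixed conditions, pooled or joint normalization,
  replicate-range-approximated normalization using the printed SDs) fall
  further away, and a jitter study bounds the effect of the coarsest
  printed column (the ALSIA PRAE values carry one to two significant
  digits) to r ∈ [0.26, 0.35] — printing precision alone cannot close the
  gap. The rank-normalized variant, which discards the damaged resolution,
  gives r = 0.41, CCC = 0.40, consistent with the published values; this
  is why `compute_indicator()` exposes it and why the acceptance outputs
  report both constructions.

## Problem sizes and numerical choices

Simulation-based checks use: 500 trial replicates for latent-efficiency
recovery and for the paired-platform calibration; 1,000 random pairs for
the CCC properties; 10,000 pairs for the Bland–Altman calibration;
300–400 replicates for the ANOVA-null, Levene type-I and familywise-error
checks; and a handful of 240 × 360 rendered scenes for the imaging chain —
sizes at which each check is stable under reseeding while the whole suite
stays quick. Ties in ranks are dense; quadrant boundaries classify upward;
constant inputs to normalization yield 0.5 with a warning; degenerate
t-cells yield deterministic p ∈ {0, 1}; a flat image segments to an empty
mask; spline fits require at least df + 1 points and strictly increasing
times.
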