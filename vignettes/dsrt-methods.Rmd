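---
title: "Methods: from raw viability plates to drug sensitivity, target addiction and synergy scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw viability plates to drug sensitivity, target addiction and synergy scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsrtools)
```

## Scope and model

`dsrtools` implements the analysis layer of ex vivo drug sensitivity and
resistance testing (DSRT) for patient-derived cancer cells (PDCs): 384-well
luminescence viability screens of an oncology drug library at five
concentrations spanning a 10,000-fold range, normalized against in-plate
DMSO (negative, 0% inhibition) and benzethonium chloride (positive, 100%
inhibition) controls, fitted per (sample, drug) with a four-parameter
logistic (4PL) model, and summarized as drug sensitivity scores (DSS).
Downstream layers transform DSS profiles into selective scores against
healthy-control cells, target addiction scores (TAS) through drug–target
polypharmacology, highest single agent (HSA) synergy scores for dose
combination matrices, and cohort-level statistics across histological
tumour subtypes (here labelled HGSOC, LGSOC, MUCOC for the emulated
epithelial ovarian cancer setting).

### Normalization

With per-plate pooled control means $\mu_{neg} > \mu_{pos}$,

$$\mathrm{inhibition} = 100\,\frac{\mu_{neg} - \mathrm{signal}}
{\mu_{neg} - \mu_{pos}},$$

an affine, order-reversing map: lower signal means more killing. Values
outside $[0, 100]$ are deliberately *not* clipped — the fit layer enforces
biological bounds, and out-of-range values carry QC information. Controls
are pooled per plate because no within-plate layout model is assumed; no
edge-effect correction is attempted. Plate quality is tracked with
$Z' = 1 - 3(\sigma_{neg} + \sigma_{pos})/(\mu_{neg} - \mu_{pos})$.
Replicate wells are averaged arithmetically; series with fewer than 4
distinct doses are excluded with a logged count rather than fitted.

### Dose-response model

$$y(x) = b + \frac{a - b}{1 + 10^{\,s (m - x)}}, \qquad x = \log_{10}
(\mathrm{conc\ in\ nM}),$$

with bottom $b$ fixed at 0 by default (five points cannot support four
free parameters), top asymptote $a \in [0, 100]$, log10-EC50
$m \in [x_{min} - 1,\, x_{max} + 1]$ of the tested range, and slope
$s \in [0.1, 10]$. Fitting is box-constrained least squares seeded by a
coarse multistart grid ($m$ in 0.5-unit steps, $s \in \{0.5, 1, 2\}$) with
$a$ profiled in closed form at each grid point — for fixed $(m, s)$ the
optimal $a$ is a linear-regression coefficient — so only the best few
starts need quasi-Newton refinement. Equal-RSS ties break towards the
smaller $a$, then smaller $s$ (conservative sensitivity calls).
All-constant series return the constant as $a$ with `converged = FALSE`;
fits of inactive curves are legitimate converged fits that simply score 0
downstream.

### DSS

The score integrates the fitted curve over an *activity window* from
$t = 10$% to 100% inhibition and a *dose window* from
$x_1 = \max(x_{min}, y^{-1}(t))$ to $x_2 = x_{max}$:

$$I = \int_{x_1}^{x_2} \big(\min(y(x), 100) - t\big)\,dx,$$

evaluated in closed form from the logistic antiderivative
$\int y\,dx = b\,x + \frac{a - b}{s \ln 10}\ln(1 + 10^{s(x - m)})$ (a
numerically stable `log1p` variant is used for large arguments), and
cross-checked against adaptive quadrature in the test suite. Then

$$\mathrm{DSS1} = \frac{100\, I}{(100 - t)(x_{max} - x_{min})}, \qquad
\mathrm{DSS3} = \mathrm{DSS1}\cdot
\frac{x_2 - x_1}{x_{max} - x_{min}} \cdot \frac{1}{\log_{10} a},$$

with $a$ clipped to $(t, 100]$ inside the logarithm. DSS3 (the default
metric) penalizes shallow curves that never reach a strong maximal
response. Curves with $a \le t$ score exactly 0 with an empty window. The
full DSS3 normalization constant is centralized in `compute_dss()`;
property tests rely only on bounds, monotonicity in $a$ and $m$, and
invariance under joint rescaling of concentration units, not on the
constant itself. Scores are computed on the nM log-scale by default; a
µM convention shifts $m$, $x_1$, $x_2$ jointly and leaves DSS unchanged.

A drug is called *moderately-to-strongly effective* at the fixed threshold
DSS ≥ 10 (the emulated cohort's 85% pooled quantile); the empirical 85th
percentile (linear interpolation between order statistics) is reported
alongside for comparison but does not govern the calls.

### Selective DSS

$\mathrm{sDSS} = \mathrm{DSS}_{sample} - \overline{\mathrm{DSS}}_{controls}$
against healthy bone-marrow-derived mononuclear cell profiles (2 donors by
default), discounting generally cytotoxic compounds. Drugs missing from
every control donor are flagged `NA`, never silently zeroed.

### TAS

For target $t$ with $n_t$ potent inhibitors,
$\mathrm{TAS}_t = \sum_{i=1}^{n_t} \mathrm{DSS}_i / n_t$. Membership comes
from a quantitative drug–target bioactivity table (Kd/Ki/IC50 potencies in
nM), deduplicated per (drug, target) keeping the most potent record and
thresholded at 1000 nM (the conventional "potent interaction" cutoff; the
source methodology states none, so it is a config key, as is the
minimum of 2 drugs per scored target and an optional kinase-only
restriction, off by default). Significance: the DSS vector is permuted
across drug identities with membership fixed — this preserves the
target-size structure the statistic depends on, unlike rewiring the map —
and $p_t = (1 + \#\{\mathrm{perm}: \mathrm{TAS}^{perm}_t \ge
\mathrm{TAS}^{obs}_t\})/(n_{perm} + 1)$, one-sided with add-one
correction, so $p$ is never 0 and a target containing the whole library
gets $p = 1$. Drugs without a DSS (the library changed mid-study in the
emulated setting) are excluded per target, not imputed as 0.

### HSA synergy

For a 7×7 matrix whose row/column 0 hold monotherapies,
$\mathrm{excess}(i,j) = \mathrm{inhibition}(i,j) -
\max(\mathrm{inhibition}(i,0), \mathrm{inhibition}(0,j))$ for interior
cells. The summary score is the mean interior excess; the highest mean
over any contiguous 3×3 interior window is reported alongside (dose-region
synergy can be diluted by a flat global mean). No Loewe/Bliss/ZIP
baselines are provided — HSA only. Inhibition (not viability) is the fixed
sign convention: positive excess means synergy.

### Cohort statistics

Per-sample effective-drug fractions (all / chemotherapy / targeted) are
aggregated per subtype as mean ± SEM, compared pairwise with two-tailed
Welch t tests and across three groups with classic one-way ANOVA; groups
of size < 2 yield `NA`, never fabricated zeros. Pairwise subtype
similarity uses Spearman rank correlation (average ranks on ties) of
per-drug subtype-mean DSS. Sample clustering is Ward linkage (`ward.D2`)
on Euclidean distances; PCA is column-centred, unit-variance scaled by
default, with signs fixed so the largest-magnitude loading of each
component is positive. Differential drug sensitivity between two sample
groups uses an empirical-Bayes moderated t: per-drug pooled variances are
shrunk towards a prior $s_0^2$ with $d_0$ prior degrees of freedom
obtained by moment matching of the variance distribution
($\mathrm{Var}/\mathrm{Mean}^2 = 2(d + d_0 - 2)/(d(d_0 - 4))$ under a
scaled-F model). Voom-style precision weights are deliberately *not*
used: they model count-data mean–variance trends and DSS is not a count.
A plain Welch t is available as a config alternative. Drugs enter the
differential analysis when DSS ≥ 10 in at least one compared sample
(threshold and quantifier configurable); Benjamini–Hochberg adjustment
runs across the included drugs, and both raw and adjusted p are emitted.

## The synthetic cohort: what it emulates, and what it does not

No patient-level screen data are publicly available for the motivating
cohort, so `simulate_screen()` generates a stated stand-in world (all
outputs are labelled synthetic):

* **Cohort**: 5 HGSOC, 5 LGSOC, 3 MUCOC patients; two LGSOC patients
  contribute 3 and 2 serial samples (16 samples, 13 patients). Serial
  samples share identical true parameters and differ only by plate noise,
  reproducing the "serial profiles are more alike than any cross-patient
  pair" property.
* **Library**: 526 drugs, 20% chemotherapy, mechanism tags drawn from a
  fixed vocabulary. Per-drug base 4PL parameters: a 60% inactive mass
  (top asymptote uniform on [0, 10]) and an active mass uniform on
  [40, 100]; log-EC50 uniform over the tested range and one decade above
  it; slope log-normal around 1. This long-tailed mixture puts the pooled
  85% DSS quantile near 10, matching the effectiveness convention.
  Chemotherapy is more broadly active than targeted agents
  (class-conditional inactive probability 2/3 vs. >1 of the marginal,
  marginal kept at the configured value).
* **Doses/plates**: 5 doses, 1–10,000 nM (a single shared range; real
  libraries vary ranges per drug, which affects nothing downstream of the
  per-series `x_min`/`x_max` bookkeeping), 384-well plates with 16 DMSO
  and 16 positive-control wells each. Noise is Gaussian on the raw-signal
  scale with CV 0.1, *not* on %inhibition, so control-based normalization
  is genuinely exercised; plate layout and control counts are configurable
  defaults, not claims about any specific screening facility.
* **Planted subtype effects**: LGSOC gains MDM2/ERBB/MEK/ERK sensitivity,
  MUCOC MEK/ERK, HGSOC CHK1/WEE1/SMAC — shifts of +45 top-asymptote
  points and −1.5 log10-EC50 units on tagged drugs. The magnitude was
  chosen once, on the grounds that planted sensitive mechanisms in the
  emulated setting are strong potent hits (DSS ≈ 15–30 with clear
  waterfall separation), not marginal shifts; weaker planting (e.g. +30
  on the asymptote alone) leaves subtype effective-fraction differences
  inside sampling noise.
* **Healthy controls**: 2 donors; targeted drugs draw half-normal scores
  (mean < 5), chemotherapy draws moderate gamma scores, so cytotoxics are
  discounted by sDSS as intended.
* **Synergy**: interior combination cells follow
  $\min(100, \max(\mathrm{mono}_A, \mathrm{mono}_B) + \mathrm{excess})$
  with the planted excess recorded post-ceiling in the ground-truth
  sidecar.

A green cohort test therefore establishes that the pipeline *recovers
planted structure through the full raw-signal → DSS → statistics path*;
it says nothing about real PDC biology, inter-laboratory reproducibility,
spatial plate artefacts, or drugs with bell-shaped (biphasic) responses,
none of which the generator emulates.

## Numerical choices and degenerate inputs

* Closed-form partial AUC with a stable $\ln(1+10^z)$ for $z > 25$;
  quadrature is used only as an independent oracle in tests.
* `dose_at_inhibition()` returns `NA` (not an error) when a threshold is
  never reached; DSS treats that as an empty window.
* Control inversion ($\mu_{neg} \le \mu_{pos}$) and missing control
  classes abort normalization with explicit errors.
* Permutation p-values are add-one corrected; uniformity under an
  i.i.d. null is verified by a KS test in the acceptance suite.
* All generators and permutations take explicit integer seeds; the
  pipeline manifest contains no timestamps, so a rerun with the same seed
  is byte-identical (verified by MD5 in the tests).
* `hclust` breaks ties by merge index, giving a deterministic leaf
  order.

## Known limitations

Single shared dose range across the library; no spatial/edge plate
models; no biphasic dose-response support; HSA is the only synergy
baseline; the moderated-t prior uses moment matching rather than the
maximum-likelihood F-fit of heavier machinery, which is slightly less
efficient for very small libraries. The TAS permutation randomizes drug
identities, which is one of several defensible nulls; alternatives that
rewire the target map would test a different hypothesis.
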