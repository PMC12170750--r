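---
title: "Sectioning points, D-values and discriminant functions for burnt patellae"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sectioning points, D-values and discriminant functions for burnt patellae}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteosex)
```

## The problem

Metric sex estimation treats a skeletal measurement as a draw from one of
two sex-specific distributions and asks which is more probable. The
patella is a convenient element for this: it is compact, survives
taphonomy and fire relatively well, and its maximum height (MAXH),
thickness (MAXT) and width (MAXW, all mm) are sexually dimorphic.
Burning complicates matters — bone shrinks with heat, more so in
trabecular-rich dimensions, and shrinkage need not be equal between the
sexes — so a method calibrated on unburnt bone cannot be assumed to
transfer. `osteosex` implements the analysis battery for exactly this
setting: dimorphism screening, Gaussian sectioning points with D-values,
cut-off classification, two-group linear discriminant analysis (LDA) with
leave-one-out cross-validation (LOOCV), observer-error statistics, and a
synthetic generator of paired unburnt/burnt datasets.

## The sectioning model

Each sex's measurement is modelled as normal: females
$N(\bar x_f, s_f^2)$, males $N(\bar x_m, s_m^2)$, with means and *sample*
SDs (divisor $n-1$) estimated per group. The sectioning point $x_0$ is
where the two densities intersect between the means: the midpoint
$(\bar x_f + \bar x_m)/2$ when $s_f = s_m$, otherwise the root of the
quadratic obtained by equating log-densities that lies strictly between
the means. A measurement below $x_0$ classifies as female, at or above as
male — the boundary goes to male, because only values *below* the cut-off
are female under the rule.

Dimorphism at $x_0$ is quantified by the D-value,
$$D = F(x_0 \mid \bar x_f, s_f^2) - F(x_0 \mid \bar x_m, s_m^2),$$
the area of non-overlap of the two fitted normals: 0 for identical
distributions, 1 for complete separation. Since
$\partial D/\partial x_0$ is the difference of the two densities, $D$ is
maximised exactly at an in-interval density crossing. That equivalence
drives a numerical decision: with strongly unequal variances the
quadratic's roots can both fall outside the interval between the means.
`fit_cutoff()` then maximises $D$ over the closed interval between the
means instead (`stats::optimize`, tolerance 1e-10) and flags the result
(`method = "dvalue_maximization"`) — $D$ is the quantity of scientific
interest, and this fallback extends its maximiser continuously to the
no-crossing regime. Should the female mean exceed the male mean, the
groups are swapped internally and the result flagged `reversed`; the
orientation assumption (females smaller) holds for every patellar
measurement in practice.

Equal-variance sanity anchor, tested to 1e-10: at the midpoint,
$D = 2\Phi(\Delta/2s) - 1$ with $\Delta$ the mean difference.

## The screening battery

Before sectioning, each measurement is screened per sex group: adjusted
Fisher–Pearson skewness $G_1 = g_1\sqrt{n(n-1)}/(n-2)$ (the common
package default; $|G_1| < 1$ read as low skewness), Shapiro-Wilk
normality per group (per group, not pooled — a pooled test would mostly
detect the sex difference itself), and a mean-centred Levene test of
equal variances across groups. Sex difference is tested by the
Mann-Whitney U with midranks, the tie-corrected normal approximation and
no continuity correction; $z$ is signed so that it is negative when
females tend lower, matching how such tables are conventionally printed.
An exact-enumeration p-value is available for groups of at most 10 as a
cross-check. All p-values follow the standard reading: $p < \alpha$
indicates a significant departure or difference.

## The discriminant function

The two-group LDA is reported in the unstandardized-coefficient
convention of osteometric work. With pooled within-group covariance $S$
(divisor $n - 2$) and mean vectors $\bar{\mathbf x}_f, \bar{\mathbf x}_m$:

- direction $\mathbf w \propto S^{-1}(\bar{\mathbf x}_m - \bar{\mathbf x}_f)$,
  rescaled so $\mathbf w' S \mathbf w = 1$ (unit pooled within-group score
  variance);
- constant $c = -\mathbf w'\bar{\mathbf x}$ with $\bar{\mathbf x}$ the
  case-weighted grand mean, so the $n$-weighted average of the two group
  centroids is zero;
- males score higher by construction; classification threshold at the
  centroid midpoint, i.e. equal priors (the usual package default; scores
  exactly on the threshold go to female, so both classifiers'
  tie-breaks are fixed and documented, one per side).

This scaling convention is not arbitrary: published centroid pairs in
this literature satisfy the $n$-weighted zero-sum identity (e.g.
$18\cdot(-0.569) + 14\cdot 0.732 \approx 0$), which identifies exactly
this parameterisation. Incomplete cases are dropped listwise per
function. LOOCV refits the model for every held-out case — $O(n)$ full
refits, transparent and cheap at study sizes — and is fully
deterministic. The package's fit is cross-checked in the test suite
against an independent reference implementation (`MASS::lda`): collinear
directions and case-by-case identical classifications under equal priors.

## Observer error

For $n$ subjects measured twice, $\mathrm{TEM} = \sqrt{\sum d_i^2 / 2n}$
(mm), $\%\mathrm{TEM} = 100\,\mathrm{TEM}/\text{grand mean}$, and
$R = 1 - \mathrm{TEM}^2/s^2$. The literature admits variants of $s^2$;
here it is fixed as the sample variance (divisor $n-1$) of the
per-subject means, and exactly two replicates are supported — the
intra-/inter-observer design — because the two-replicate formulas are
unambiguous. The %TEM denominator is the grand mean *per measurement*,
since each measurement is analysed separately throughout.

## What the synthetic generator emulates

`synthetic_config()` describes a study-shaped population; defaults are
fixed once as the conditions the package is meant to emulate:

| parameter | default | rationale |
|---|---|---|
| `n_female`, `n_male` | 18, 14 | the reference study's composition (56.2% female) |
| unburnt means/SDs | published unburnt per-sex summaries | e.g. female MAXH 37.95 ± 2.98, male 42.45 ± 2.23 mm |
| `correlation` | 0.6 common | patellar dimensions are strongly but not perfectly correlated; no published value, so configurable and sensitivity-tested |
| `shrinkage_mean` | F 0.10, M 0.12 | multiplicative heat shrinkage, higher for males as reported qualitatively; magnitudes are *placeholders*, not estimates of the study's values |
| `shrinkage_sd` | 0.03 | per-individual spread, truncated normal on [0, 0.5] |
| `missing_prob_burnt` | 24/56 | fraction of burnt patellae rendered unmeasurable |
| ages | uniform, F 62–92, M 60–93 | printed elderly ranges; ages feed no downstream computation |
| burn metadata | T ~ U(450, 1100) °C, t ~ U(90, 240) min | the experimental furnace ranges; colour white iff T ≥ 800 °C |

Each individual gets one unburnt (left) trivariate-normal draw and one
burnt (right) antimere: a single shrinkage factor per individual scales
all three dimensions (real shrinkage is anisotropic; a per-dimension
extension would be straightforward but is deliberately not the default),
and with probability `missing_prob_burnt` the whole burnt triplet is
absent — missingness hits patellae, not single calipers. The colour rule
is tied deterministically to the 800 °C calcination boundary so the
calcined filter is exercised; real calcination also depends on duration
and oxygen, which the generator ignores. Everything is statistical: no
biomechanics, no fracture, no warping, and normality holds by
construction — so passing tests demonstrate correctness of the
*computations*, not that real burnt assemblages are this well-behaved.
Generation is deterministic given `seed` (mandatory), and the global RNG
state is restored afterwards.

The generator also encodes the qualitative consequence to expect: with
male-heavier shrinkage, burnt-sample D-values fall below the unburnt
D-values of the same population — the property tests verify this at
large n.

## Numerical and reporting choices

- Sample SD divisor $n-1$ everywhere; this convention reproduces the
  published unburnt sectioning points exactly from the printed summaries.
- Published summary tables shipped as fixtures are transcribed verbatim,
  including a few internally inconsistent printed min/max cells
  (validation is relaxed for transcriptions only); a weighted checksum
  over every fixture number is frozen in the tests.
- Report CSVs round to 2 decimals for mm, 3 for D-values, 1 for
  percentages; a parallel `results_full.yaml` retains full precision.
- The pipeline writes no timestamps, so identical configs and seeds give
  byte-identical reports; the YAML run log embeds the full configuration
  and replays exactly via `read_pipeline_config()`.
- Test problem sizes: asymptotic properties use 5,000 individuals per
  sex; Monte-Carlo bands use 200–500 replicates at study size — large
  enough that the checked bands are stable across seeds.

## Limitations

- Strictly two groups, three measurements, univariate sectioning and
  linear discriminants; no quadratic discriminant, stepwise selection or
  non-Gaussian sectioning.
- The normal model is an approximation; with n ≈ 14–18 per sex,
  sectioning points and D-values carry substantial sampling error that
  the point estimates do not express.
- Cut-offs and coefficients derived from one elderly Portuguese sample
  do not transfer across populations, ages or burning regimes — the
  external-cut-off evaluation machinery exists precisely to quantify
  that.
- The shrinkage magnitudes in the generator are placeholders; do not
  read simulated burnt/unburnt contrasts as estimates of real shrinkage.
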