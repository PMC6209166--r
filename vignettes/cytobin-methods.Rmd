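---
title: "Equal-frequency binning for gating-free cytometry comparison: methods and design"
author: "cytobin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equal-frequency binning for gating-free cytometry comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytobin)
```

## The problem

Flow and mass cytometry measure tens of markers on 10^4^--10^6^ single
cells per sample. The classical way to compare donor groups is manual
gating: an analyst draws regions on a sequence of 2D scatter plots and
compares the resulting population frequencies. Gating is subjective,
labor-intensive, and biased toward populations the analyst already
expects. `cytobin` replaces it with an automated screen over *every*
marker pair that makes no assumptions about where populations lie and
requires no density estimation or clustering.

## The representation: equal-frequency boxes

For one sample and one ordered marker pair (x-marker A, y-marker B),
each marker is independently divided into $b$ *equal-frequency* bins:
bin 1 holds the cells with the lowest expression, bin $b$ the highest,
and every bin holds the same number of cells by construction. Overlaying
the two binnings forms a $b \times b$ grid of **boxes**; the percentage
of cells in box $(i, j)$ estimates the joint probability
$P(A_i, B_j)$ that a cell sits in expression stratum $i$ of marker A and
stratum $j$ of marker B. If the two markers were independent, every box
would hold about $100/b^2$ percent of the cells; any deviation encodes
the shape of the 2D point pattern. The $b^2$ percentages, straightened
row-major (x-marker bin outer), are the sample's feature vector for that
pair. Box $(i,j)$ is labeled `Bij`, e.g. `B32` = x-bin 3, y-bin 2.

Because bins are defined by ranks within each sample, the representation
is invariant under any strictly increasing transform of a marker --- the
choice of display transform (logicle or otherwise) cannot change any
downstream result --- and it is robust to sample-to-sample shifts in
absolute intensity, which act approximately monotonically.

### Ties and bin occupancy

Cytometry values are heavily tied (zeroes, detector quantization).
Threshold-based quantile cuts can then produce badly unequal bins, which
would break the equal-frequency premise. `percentileBinIndices()`
therefore assigns bins by *rank with stable tie-breaking* (ties keep
their original row order): the cell at sorted position $k$ (0-based)
lands in bin $\lfloor kb/n \rfloor + 1$, so every bin holds
$\lfloor n/b \rfloor$ or $\lceil n/b \rceil$ cells no matter how many
values coincide.

### The compositional log-ratio transform

Box percentages sum to 100 and are therefore compositional. Before
classification each sample's vector is divided by its median and
log~2~-transformed. Zeros are first replaced by half the smallest
positive percentage in the same vector; this keeps the transform finite
without disturbing the ordering of boxes. The median is taken after the
replacement (for even $b^2$, the mean of the two central order
statistics). If more than half the boxes are empty, the median-ratio
transform is degenerate and the package raises an error advising fewer
bins rather than producing unstable features.

## Selecting marker pairs

The cohort is split once into a training set and a holdout set
(`balancedSplit()`, default 20% holdout). For every unordered marker
pair (minus a configurable blocklist, e.g. a viability dye), a
soft-margin linear support-vector classifier with cost $C = 10$ is fit
on the training samples' log-ratio features and scored on both sets.
A pair is **selected** when training and holdout accuracy are both
exactly 100%: its two markers then jointly carry enough information to
separate the groups perfectly, and the separation generalizes.

Feature vectors are standardized (zero mean, unit variance per box)
inside the fit --- the conventional preprocessing for SVMs when feature
variances differ by orders of magnitude, as box percentages do between
dense and sparse boxes; zero-variance features carry no class
information and are dropped. One shared split is used for all pairs so
that selected pairs are comparable.

Two split modes handle unequal group sizes. `strict` (default) chooses
per-group holdout counts so the two *training* groups come out exactly
equal --- the smaller group gives up $\lceil f \cdot n_{small} \rceil$
samples, the larger additionally its surplus --- because the bin-number
rule below assumes equal training groups. `proportional` takes
$\lfloor f \cdot n_g \rfloor$ from each group, leaving the training
ratio as observed; with groups of 34 and 22 at $f = 0.2$ this produces
the 6 + 4 holdout / 28 + 18 training split typical of published cohort
reanalyses. Neither mode is uniformly better; the choice is exposed.

## How many bins? Calibrating against overfitting

Larger $b$ resolves finer sub-populations but inflates the feature
dimension ($b^2$) relative to the number of *samples* (typically tens),
and a linear classifier in enough dimensions separates anything. The
package calibrates this directly: `estimateFPR()` repeatedly splits the
cohort into two random equal halves *ignoring the true labels*, fits
the same linear SVM, and records how often a random labeling is
classified with 100% training (resubstitution) accuracy. The mean of
this frequency over marker pairs estimates the **false positive rate**
of perfect classification at that $b$. Resubstitution accuracy is the
right quantity here: it measures the classifier's capacity to fit
arbitrary labels at dimension $b^2$, which is exactly the overfitting
risk; held-out accuracy under random labels hovers near 50% for every
$b$ and carries no signal about capacity.

`fprCurve()` sweeps candidate bin numbers and recommends the largest
$b$ with FPR below a threshold (default 0.05; a threshold of 0 gives
the stringent criterion appropriate when hundreds of pairs will be
screened). On 20-sample synthetic cohorts the curve crosses 0.05
between $b = 3$ and $b = 4$; with 60 samples, between $b = 6$ and
$b = 7$. At $b = 1$ the single feature is constant and the FPR is
exactly zero.

A closed-form shortcut tracks the simulation: the largest safe bin
number is about $\sqrt{n/2}$ for $n$ training samples,
`maxBinsRule(n) = round(sqrt(n/2))` (round half up). For 46 training
samples this gives 5; for 60, also 5.

## Which boxes differ?

For every selected pair, each box's per-sample percentages are compared
between the groups with a two-sided Mann-Whitney U test --- on the raw
percentages, not the log-ratio features: rank tests are invariant to
that monotone transform, and percentages are the interpretable scale.
The exact null distribution is used whenever the smaller group has at
most 25 samples and there are no ties; ties force the tie-corrected
normal approximation with continuity correction. All boxes of all
selected pairs form a single Bonferroni family of size
$(\#\text{pairs}) \times b^2$; a box is **important** when its adjusted
p falls below $\alpha = 0.001$ (configurable; Benjamini-Hochberg is
available behind a flag). Pairs contributing no important box are
pruned from the selection.

With $n = m = 10$ samples per group the exact two-sided p cannot fall
below $2/\binom{20}{10} \approx 1.08 \times 10^{-5}$; under complete
separation every strongly differing box sits exactly at this floor, so
adjusted p-values saturate (e.g. $36 \times 2/\binom{20}{10} \approx
3.9 \times 10^{-4}$ for the 36-box family at $b = 6$). Reported boxes
are therefore ordered by adjusted p with ties broken by effect size
(absolute difference of group medians), which is what "most different
box" means in this package.

Per-box mean intensities over all markers (`boxProfile()`) characterize
what cell population a box contains --- e.g. a box high in both CD8 and
CCR7 in a PBMC panel reads as a naive/central-memory CD8 region ---
without the package itself assigning biological labels.

## The synthetic cohort generator

`makePatternA()`/`makePatternB()` generate the two-marker point
patterns used for calibration and validation. Both share two large
isotropic Gaussian clusters (5,000 points each at $(0, 4)$ and
$(0, -4)$, sd 2). Pattern A adds a cluster at $(4, 0)$, sd 1, whose
size is drawn uniformly in 1112..2500 so that it forms exactly 10--20%
of the cells --- a moderately abundant sub-population. Pattern B
instead adds 200--500 points at $(-4, 6)$, sd 1, about 2--5% of cells
--- a rare sub-population. At $b = 3$ the abundant cluster dominates
box `B32`; the rare cluster only becomes visible at $b = 6$ (box
`B16`), which is the motivating example for the bin-number trade-off.

`makeCohort()` draws labeled cohorts with one deterministic child seed
per sample (a splittable hash of master seed, group, and index), so
cohorts are exactly reproducible and extending a cohort never perturbs
existing samples. Calibration cohorts default to mixed A + B groups;
homogeneous cohorts (same generator twice) are available and are what
the null-result tests use.

The generator emulates cluster structure, abundance variation, and
sampling noise. It does **not** emulate fluorescence spillover,
autofluorescence, batch effects, heavy zero-inflation, or acquisition
drift; passing tests on synthetic cohorts therefore demonstrates the
statistical machinery, not robustness to instrument artifacts. Points
are generated untruncated.

## Reading real data

`readFCS()` parses FCS 2.0/3.0/3.1 list-mode files (float32/float64 and
plain integer data, both byte orders), preferring stain names (`$PnS`)
over detector names (`$PnN`) since analyses are phrased in marker
terms. A `$SPILLOVER`/`SPILL` matrix in the file is attached to the
sample and applied only on explicit request (`applyCompensation()`,
standard unmixing by the inverse spill matrix) --- many public files are
already compensated. `logicleTransform()` implements the standard
biexponential logicle scale (width $w$, top of scale $t$, decades $m$,
extra negative decades $a$): the forward map inverts the biexponential
by bracketed root finding at absolute tolerance 10^-10^ on the relative
scale, anchored so that 0 maps to $w$ and $t$ maps to $m$ for any $a$.
Because binning is rank-based, transformation is optional for the
statistics and matters only for mean-intensity profiles and display;
it is always an explicit, user-controlled step, since public
repositories are inconsistent about whether exported events are already
transformed. A tab-delimited text format (`readCellMatrix()` /
`writeCellMatrix()`, 9 significant digits, lossless round trip) covers
data that did not come from FCS files.

## Defaults at a glance

| parameter | default | meaning |
|---|---|---|
| `b` | `"auto"` = `maxBinsRule(n_train)` | bins per marker |
| holdout fraction | 0.2 | share of samples held out |
| balance mode | `"strict"` | equal training groups |
| SVM cost C | 10 | soft-margin penalty, linear kernel |
| FPR iterations | 100 | random relabelings per bin number |
| FPR threshold | 0.05 | largest acceptable overfitting rate |
| alpha | 0.001 | Bonferroni-adjusted significance level |
| logicle | w 0.5, t 262144, m 4.5, a 0 | 18-bit flow defaults |

## Numerical and design choices

* **Stable rank binning** rather than quantile thresholds: guarantees
  equal occupancy under ties (see above).
* **Zero handling** in the log-ratio: half-minimum substitution, chosen
  to preserve ordering and finiteness; degenerate vectors error out.
* **SVM standardization**: enabled; with unstandardized features the
  relabeling FPR curve rises roughly one to two bin numbers later,
  understating overfitting risk for the dense boxes that dominate the
  unscaled geometry.
* **Exact vs approximate Mann-Whitney**: exact whenever
  $\min(n, m) \le 25$ and tie-free, because cohort sizes in this domain
  are small enough that the normal approximation is visibly off at the
  extreme tails where the interesting boxes live.
* **Tie-breaking in reports**: adjusted p, then absolute median
  difference --- needed because exact p-values saturate at their
  combinatorial floor.
* **Pair orientation**: within a pair the x-marker is the
  lexicographically first name, and all outputs state the orientation,
  so `Bij` labels are unambiguous.
* **Seeding**: a single master seed fans out to per-stage and
  per-sample child seeds via a multiplicative hash; stages are
  independently reproducible.

## Problem sizes in the test suite

The shipped tests exercise cohorts of 10 + 10 and 30 + 30 synthetic
samples (the two sizes whose calibration behavior anchors the method),
100 relabeling iterations per bin number, null-cohort screens over 20
master seeds, and text round trips at 2 x 10^4 cells x 41 markers;
the FCS integration test subsamples to ~1,500 cells per sample, which
keeps the scalar logicle inversion cheap while leaving every
statistical conclusion unchanged. These sizes were chosen as the
smallest that make the stochastic assertions stable.

## Known limitations

* Two-group comparisons only; no multi-class screening.
* The FPR calibration is empirical; no analytical separability theory
  is used.
* Equal-frequency binning destroys marginal (single-marker) abundance
  differences by construction --- only joint structure is visible. A
  pure marginal shift with no joint signature will not be found.
* The exact Mann-Whitney floor bounds attainable significance at small
  n; with 5 + 5 samples no box can pass $\alpha = 0.001$ after any
  multiple-testing correction, and the package will (correctly) report
  nothing.
* FCS support covers standard list-mode files; exotic dialects should
  go through the text format.
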