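---
title: "Wavelet-based discovery of time-series shapelets: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet-based discovery of time-series shapelets: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wtss)
```

## The problem

Shapelets are short, class-discriminative subsequences of labeled time
series. Once a set of shapelets is fixed, each series is summarized by its
minimum sliding-window Euclidean distance to each shapelet, and those
distances become features for an ordinary classifier. The approach is
attractive in settings such as environmental health, where one wants not
just a prediction (say, whether a day's indoor particulate-matter trace
coincided with rescue-inhaler use) but an interpretable local pattern --
a transient spike, a slow build-up -- that drives it.

The bottleneck is discovery. Exhaustive search over all windows of a fixed
length $L$ examines $(ATL + 1 - L)\,n$ candidates, where $ATL$ is the
average series length and $n$ the number of series
(`brute_force_count()`); at minute resolution over day-long series this
exceeds a million windows per length, and $L$ itself must be tuned.

This package implements an unsupervised alternative: use the continuous
wavelet transform (CWT) to find, at each scale of interest, the time
intervals where a series concentrates energy, and clip exactly those
intervals as candidate shapelets. Candidates inherit their length from the
data, so no window length is pre-specified, and discovery requires no
model fitting.

## The discovery procedure

For a series $X$ and wavelet $\psi$, the transform is discretized as

$$Y(a, b) = a^{-1/2} \sum_t X(t)\, \psi^*\!\left(\frac{t - b}{a}\right),$$

with scale $a$, translation $b$, and zero padding outside the observed
range. The scale is inversely proportional to frequency through the
pseudo-frequency relation $f_a = f_c / a$, where $f_c$ is the wavelet's
central frequency (`pseudo_frequency()`; for the default wavelet
$f_c \approx 0.6$, so scale 32 responds to features roughly 50 samples
across).

Per scale row, the pipeline (`extract_candidates()`) is:

1. **power**: take $|Y(a, b)|$ (modulus);
2. **standardize**: z-score the row (mean 0, sd 1);
3. **dichotomize**: 1 where the standardized power is $\ge \tau$
   (inclusive), 0 below; $\tau = 1$ by default;
4. **run extraction**: keep maximal runs of 1s at least `min_length`
   (default 3) samples long, discarding shorter runs as noise;
5. **clip**: cut each surviving run's interval out of the *original*
   series. The clip, with its source series, start, scale, and class
   label, is one candidate shapelet.

The union over series and scales is the candidate pool. Pools are reduced
to a final shapelet set either by clustering (global alignment kernel
k-means followed by per-cluster center-lines) when candidates form a few
clear shape families, or by a variance filter when they are many and
heterogeneous. Minimum-distance features and a classifier complete the
pipeline (`wtss_classify()`).

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| wavelet | complex Gaussian, order 8 | analysis wavelet of the CWT |
| scales | user-chosen (e.g. 32/64, 256/512) | feature widths to scan, in samples |
| $\tau$ | 1 | threshold on standardized power (sd units) |
| `min_length` | 3 | shortest admissible run, in samples |
| $k$ | 12 | clusters for the kernel k-means reduction |
| `retain` | 20 | anchor-class retain count for the variance filter |
| $\sigma$ | median heuristic | GAK local-kernel bandwidth |
| $\alpha$ | $-30$ | soft-minimum sharpness (learned comparator) |

The wavelet family matters more than is obvious: the modulus of a
*complex* Gaussian wavelet is a single smooth bump, so one localized
transient yields one contiguous high-power run. Real oscillatory wavelets
(Mexican hat, Morlet) split the same transient into lobes and therefore
into several fragmented candidates. That is why the complex Gaussian is
the default; order 8 gives a smooth, well-localized envelope, and orders
1--8 are available. Scales are best chosen by inspecting scalograms of a
few representative series (`write_scalogram_csv()` exports them); dyadic
grids (`dyadic_scales()`) are a convenient starting point.

Raising $\tau$ or `min_length` only ever shrinks the pool (runs can only
shrink or split as $\tau$ rises); this monotonicity is enforced by tests.

## Numerical and design choices

Several points are deliberate decisions where more than one convention is
defensible:

* **Power is $|Y|$, not $|Y|^2$.** The modulus preserves the units of the
  input, keeping thresholded rows interpretable; squared power is
  available behind `power(squared = TRUE)`. Since each row is z-scored
  before thresholding, the choice mainly affects how sharply large peaks
  dominate a row.
* **Standardization is per series and per scale row** by default; a
  dataset-global variant (`standardize = "global"`) is available. Per-row
  standardization makes extraction adaptive to each series' own energy
  profile, which is the behavior needed for heterogeneous sensor panels.
* **Boundary handling is zero padding,** with no cone-of-influence
  masking. Candidates whose run lies within one scale width of either end
  are flagged (`boundary_flag`), not dropped -- at large scales masking
  would discard most of the axis.
* **Runs are half-open, 0-based intervals** `[start, start + length)`;
  the threshold comparison is inclusive ($\ge \tau$).
* **Exact duplicate candidates** (same source, start, length found at
  several scales) are deduplicated; overlapping candidates are *not*
  merged, since no merge rule is uniquely natural.
* **Constant series are skipped at extraction.** The transform of a
  constant series is zero up to floating-point dust; standardizing that
  dust would manufacture spurious runs.
* **Candidates come from training data only** in supervised workflows, so
  no information from evaluation series leaks into the feature
  definitions.
* **Center-lines.** Kernel k-means has no explicit centroids, so each
  cluster is summarized by resampling members linearly to the cluster's
  median length and averaging pointwise. A barycenter under time warping
  would also be defensible; the linear-resample average is transparent,
  deterministic, and adequate for clusters of similar shapes.
* **GAK computations run in the log domain** (C++), so long or dissimilar
  sequences never underflow; the Gram matrix uses the normalized kernel
  $\hat k(x,y) = k(x,y)/\sqrt{k(x,x)k(y,y)}$, and the local kernel is the
  infinitely divisible form $\kappa/(2-\kappa)$ of the Gaussian. The
  bandwidth default is a median-distance heuristic scaled by the root of
  the median sequence length. Empty clusters are re-seeded from the point
  farthest from its center; the best of `n_init` random initializations
  (lowest kernel-space inertia) is kept.
* **Distances are length-normalized** (squared distance divided by $L$
  before the square root) so variable-length shapelets yield comparable
  features; window-level z-normalization is *not* applied, because whole
  series are already scaled consistently (per-series min-max scaling is an
  explicit, optional step, intended for sensor-panel workflows).
* **Test-size rounding** in `split_dataset()` is round-half-up on
  `test_fraction * n` (a 33% holdout of 823 series gives exactly 272).
  Splitting is per-series by default; `group_by` assigns whole groups
  (e.g. all series from one household) to one side, which is the correct
  unit when rows are repeated measurements.
* **The learned-shapelet comparator** uses the standard soft-minimum
  surrogate $\sum_p d_p e^{\alpha d_p} / \sum_p e^{\alpha d_p}$
  ($\alpha < 0$) so the minimum is differentiable; its analytic gradient
  is verified against finite differences in the tests. The loss is a
  multinomial logistic likelihood with an L2 penalty on the linear
  weights only; convergence is declared when the relative loss change
  over a 50-iteration window falls below $10^{-6}$.

## What the generators emulate

`generate_trace_like()` emulates four-class benchmark data in which each
class carries a unique localized template at a jittered position on a
noisy baseline: a rectangular pulse, a ramp with a sharp drop, a smooth
bump, and a late step up *sustained to the end of the series*. The last
template is a level change rather than a pulse on purpose: minimum-distance
features are shift-invariant, so a class defined only by the *position* of
an otherwise identical pulse would be indistinguishable by construction;
what distinguishes the fourth class is its local shape (a rise with no
fall). Defaults -- series length 275, 25 series per class (100 per split),
noise sd 0.1, jitter 30, pattern length 60 -- are fixed study conditions,
not tuning knobs.

`generate_spike_series()` emulates day-long (1440-sample) nonnegative
sensor traces: a noisy baseline plus Gaussian-shaped transient spikes with
Poisson counts. One class ("indoor") is spike-enriched; the other
("outdoor") has proportionally fewer spikes and a slow sinusoidal trend.
A single `labeled_class_effect` parameter interpolates between full
separation (1) and exchangeable classes (0); the null setting is used as a
leakage check -- the whole pipeline must then classify at chance level.
Every planted spike interval is recorded as ground truth, enabling
recovery tests (`recovery_table()`).

Neither generator reproduces the full texture of real sensor data: no
heteroscedastic noise, no diurnal baselines shared across days, no missing
samples, no autocorrelated error. Passing tests on generated data
demonstrates that the machinery is correct and that the method recovers
the structures it is designed for -- not that it will attain any
particular accuracy on a given real dataset.

## Problem sizes used in the checks

The test suite and the acceptance script run the full four-class recipe on
100 training and 100 test series (five independent seeds), spike recovery
on 10 day-long series with 20 planted spikes, and oracle comparisons on
100 randomized small instances per operation. These sizes were chosen so
that each stage is exercised end-to-end with comfortably separable
arithmetic; larger panels run with the same code paths.

## Known limitations

* Scales and the wavelet family must still be chosen by the analyst;
  scalogram inspection is supported but not automated.
* Extraction is unsupervised: a pattern common to all classes produces
  candidates just as a discriminative one does. Reduction and the
  classifier, not extraction, provide the discrimination.
* The variance filter can discard genuinely discriminative low-variance
  candidates; it is a pragmatic device for large heterogeneous pools.
* Distances are Euclidean; no time-warping-based feature distance is
  provided.
* Kernel k-means depends on its random initialization; with `n_init`
  restarts the clustering is stable in practice, but cluster *identity*
  across reruns is not guaranteed.
* Multivariate series and alternative time-frequency decompositions are
  out of scope.

## A worked example

```{r example, eval = FALSE}
gen_tr <- generate_trace_like(n_per_class = 25, seed = 11)
gen_te <- generate_trace_like(n_per_class = 25, seed = 12)
res <- wtss_trace_recipe(gen_tr$dataset, gen_te$dataset, seed = 1)
res$pool_size   # about 200 candidates instead of > 40,000 windows
res$confusion   # rows = predicted, cols = true
res$macro_f1
```

The same pipeline with `reduce = "variance"`, gradient boosted trees, and
min-max scaling is the configuration intended for imbalanced sensor-panel
problems; `feature_importance()` and `partial_dependence()` then connect
the fitted model back to the discovered patterns.
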