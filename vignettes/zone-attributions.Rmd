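---
title: "Zone-based attributions for spectral classifiers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Zone-based attributions for spectral classifiers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zonexplain)
```

## The problem

Classifiers of 1-D vibrational spectra (Raman, FT-IR) consume hundreds of
correlated intensity values. Per-wavenumber attribution methods — classic SHAP
and LIME — struggle here in three ways: the exact Shapley computation scales
as $O(2^F)$ in the number of features $F$; perturbing single wavenumbers
produces spectra no instrument could measure, so the model is probed far off
the data manifold; and the resulting explanations scatter positive and
negative contributions across adjacent, chemically inseparable wavenumbers.
Meanwhile a waterfall plot showing the "top 9" of 584 wavenumbers can leave
most of the prediction inside the grouped remainder.

`zonexplain` addresses all three by changing the unit of explanation: the
wavenumber axis is partitioned into contiguous *zones* bounded by the valleys
between peaks, each zone is perturbed as a group, and attributions are
computed per zone. With 10–25 zones instead of hundreds of wavenumbers,
exact Shapley enumeration becomes feasible, perturbations replace whole bands
(physically meaningful operations), and each attributed unit corresponds to a
chemically interpretable spectral region.

## Zone detection

A zone set $B = \{b_1, \dots, b_n\}$ is an ordered, non-overlapping,
gap-free partition of the grid; each $b_i = [v, w]$ is an interval in
cm$^{-1}$. Boundaries are placed at the valleys between retained peaks.
Extrema are defined through the derivative criterion ($f'(x) = 0$, the sign
of $f''$ giving the type); on sampled, noisy data this is realised as:

1. smooth with a centered moving average (default window 5 points; the
   half-window shrinks symmetrically at the edges, which keeps the operator
   exact on straight segments);
2. take local maxima of the smoothed trace and keep those whose topographic
   prominence exceeds `min_prominence` (default 0.01) times the intensity
   range — prominence relative to the range makes detection invariant to
   uniform intensity scaling, and raising the threshold can only remove
   peaks, never add them;
3. between each pair of consecutive retained peaks, place a boundary at the
   minimum of the smoothed trace. A boundary point belongs to the zone on
   its right; zones narrower than 3 grid points are merged into the
   neighbour whose shared boundary is lower in intensity, so no degenerate
   single-point coalition survives.

The defaults are deliberately mild; neither the window nor the prominence
threshold has a canonical value for FT-Raman data, so both are exposed in
every user-facing entry point. Zones may instead be computed from the
pointwise mean spectrum of a dataset (`global_zones()`, one shared partition
for dataset-level explanations) or supplied by the user from domain
knowledge (`load_user_zones()`; gaps are auto-filled with background zones
so the partition invariant always holds).

## Group perturbations

A perturbed spectrum $z$ keeps a subset of zones from the instance $x$
bit-exactly and replaces the rest. Three generation strategies cover
decreasing data availability: replacement zones can be copied from a
reference spectrum drawn uniformly per sample (*dataset substitution*; the
donor is drawn per sample rather than searched for a best match, which would
cost a full pairwise comparison), copied from a donor after a random
smoothing/sharpening transform (*transform-augmented*, widening the
variation of a small reference set), or synthesised from $x$'s own zone by
such a transform when no reference exists at all (*input-augmented*).
Smoothing is the shrinking-window moving average above; sharpening is
unsharp masking, $x + \lambda (x - \bar x)$. Both act strictly inside the
zone.

Random zone masks are uniform over binary vectors with the all-ones mask
excluded (it carries no information) and the all-zeros mask included (it
anchors the baseline). Every stochastic step requires an explicit seed.

The Shapley explainers need one fixed replacement rule per explanation — the
"exclude a feature" operation, realised as replace by zero, by the pointwise
reference mean, or by the corresponding zone of one seeded reference
spectrum. The default is the reference mean: zero replacement creates
physically implausible cliffs at zone boundaries, which is precisely the
failure mode that motivates grouping.

## Zone Shapley values

With zones as players, the value of a coalition $S$ is the model output on
the spectrum that keeps zones in $S$ from $x$ and replaces the rest. The
Shapley value of zone $i$ is

$$\phi_i = \sum_{S \subseteq B \setminus \{i\}}
  \frac{|S|!\,(n - |S| - 1)!}{n!}
  \left[ f(x_{S \cup \{i\}}) - f(x_S) \right].$$

`exact_zone_shap()` enumerates all $2^n$ coalitions (capped at $n = 20$ by
default), memoizing model calls by coalition bitmask and batching them, so
efficiency, symmetry and dummy hold to numerical precision.
`sampling_zone_shap()` draws $N$ uniform random permutations and credits
each zone with its marginal contribution on its prefix coalition. This
estimator family was chosen over independent subset draws because it is
unbiased, satisfies efficiency *exactly* per draw (the contributions
telescope), and yields per-zone standard errors from the spread of the $N$
marginal contributions. Its RMSE shrinks as $N^{-1/2}$; the default
$N = 5000$ makes the Monte-Carlo error negligible next to typical zone
contributions at 10–25 zones.

The reported `base_value` is the model output on the fully-replaced
spectrum — the explainer's estimate of the expected model output
$E[f(x)]$ under the chosen replacement baseline. This choice (rather than
averaging predictions over a reference set) is what makes the waterfall
identity $\sum_i \phi_i = f(x) - \text{base}$ hold exactly; the reference
average is available separately as `expected_value()`. Explanations are
computed on the probability scale throughout, matching how class
probabilities are read in practice, and the explained class defaults to the
model's argmax on the instance.

## Zone LIME

`zone_lime_explain()` fits a weighted sparse linear surrogate $g$ on binary
zone masks: minimise $\sum_z \pi_x(z)\,(f(z) - g(\text{mask}(z)))^2$ over
the perturbation set, with the proximity kernel
$\pi_x(z) = \exp(-d^2/\sigma^2)$ on the replaced-zone fraction
$d = \#\{\text{mask zeros}\}/n$. The kernel form and default width 0.25 are
implementation choices — any strictly decreasing function of $d$ with
$\pi_x(x) = 1$ qualifies — and both are logged with every fit. Surrogate
complexity is controlled by a hard sparsity cap $K$ (default 10) enforced by
greedy forward selection followed by a weighted least-squares refit on the
selected zones; the weighted $R^2$ of the surrogate against the model is
reported as *fidelity*. The unperturbed instance participates in the fit
with weight 1.

LIME coefficients are local slopes, not additive shares of the prediction:
they do not decompose $f(x) - E[f(x)]$, different mask samples give
different fits, and for that reason the serialized output carries an
explicit non-additivity note and `waterfall_data()` refuses LIME
attributions outright rather than drawing a misleading path.

## Visualisations

Four views are produced from attribution objects. The *waterfall* walks from
the base value to $f(x)$, one row per top-$|\phi|$ zone (ties broken by
ascending zone position, so plots are deterministic), the rest summed into a
remainder row; the additive identity is asserted, not assumed. The
*relevance* plot draws one signed bar per zone over the wavenumber axis.
The *saliency map* spreads each zone's value over its grid points,
normalised by $\max_i |\phi_i|$ into $[-1, 1]$ (an all-zero attribution maps
to zero rather than dividing); it is piecewise constant with breakpoints
exactly at zone boundaries. The *beeswarm summary* aggregates a dataset:
one point per spectrum and zone, ordered by mean $|\phi|$, coloured by the
spectrum's zone-mean intensity min-max normalised per zone across the
dataset (a constant zone maps to colour 0 by convention — constant zones are
legitimate, not an error). The colour scalar is our reading of "feature
value" for a zone; zone mean intensity is the natural grouped analogue of a
wavenumber's intensity.

## The synthetic oil benchmark

No public spectra ship with the package; instead `generate_dataset()`
emulates a bottled-edible-oil study design: 8 oil classes, 7 independent
bottles each (4 train, 3 test), 10 spectra per bottle — 320 training and 240
testing spectra. Each spectrum is a sum of Gaussian bands at nine
fatty-acid positions (760, 972, 1265, 1302, 1440, 1460, 1656, 1745,
2843 cm$^{-1}$), plus a smooth quadratic baseline drift and i.i.d. noise,
max-normalised. Bottle-to-bottle variability is a multiplicative log-normal
amplitude jitter drawn once per bottle (sd 0.05), so spectra within a bottle
are correlated — the structure that makes a bottle-wise split meaningful.

Choices the generator fixes, and why:

* **Gaussian line shapes**, bandwidth $\sigma = 8$ cm$^{-1}$ (FWHM
  $\approx 19$ cm$^{-1}$, typical of FT-Raman oil bands; also keeps the
  1440/1460 doublet resolvable, since two equal Gaussians merge below a
  separation of $2\sigma$). Lorentzian/Voigt shapes are deliberately out of
  scope.
* **Grid 400–3100 cm$^{-1}$ at 2 cm$^{-1}$** (1351 points), mirroring a
  4 cm$^{-1}$-resolution instrument sampled below resolution. Exact
  band-position recovery is checked on a 1 cm$^{-1}$ grid because 1265 is
  odd and cannot lie on an even grid.
* **Class amplitude patterns are stylised**, shaped by lipid chemistry
  (polyunsaturated oils strong at 1265/1656, coconut dominated by saturated
  CH$_2$ bands, seed oils marked at 1460) but not fitted to any measured
  spectra; the generator emulates a study design, not a particular dataset.
* **Noise sd 0.005 and baseline amplitude 0.02** (relative to unit band
  amplitude): a clean but not noiseless FT-Raman regime.

What passing tests on this generator do and do not show: they verify the
*mathematics* of the explainers (axioms, estimator convergence, surrogate
recovery, partition invariants) and the *mechanics* of the pipeline on data
with realistic structure (bands, batches, drift). They do not certify
behaviour on real measurements, which add cosmic-ray spikes, wavenumber
miscalibration, fluorescence backgrounds and non-Gaussian line shapes — the
preprocessing that removes those artefacts is explicitly outside this
package's scope (only grid resampling and the model's own normalisation are
provided).

`stand_in_classifier()` — a multinomial logistic regression on zone-mean
features — plays the role of the opaque model in examples and tests. It
reaches ≈ 90–96 % held-out-bottle accuracy on the default generator
(recomputed, never hard-coded, by `scripts/acceptance.R`), enough to make
explanations meaningful. Any real model is plugged in through the same
two-field contract: a batch prediction function returning class
probabilities, plus ordered class names.

## Numerical and design notes

* Problem sizes in the test-suite are chosen for sharp oracles at interactive
  runtimes: exact enumeration up to 10 zones, $N = 5000$ permutation draws
  when comparing against exact values, 200–250 LIME samples for 5–6 zones.
* Spectra files are written with 17 significant digits so write/read cycles
  are bit-exact; human-facing attribution documents and plot-data exports
  round to 6 significant digits.
* Mismatched grids are always a hard error, never a silent resample: zone
  indices must mean the same thing across a dataset. `resample()` (linear
  interpolation, no extrapolation) is the explicit escape hatch.
* All derived sub-seeds (per-spectrum, per-bottle) are reduced modulo
  `.Machine$integer.max` and every stochastic entry point requires a seed,
  which is echoed into every serialized output, so any run is reproducible
  from its logged configuration alone.
* Known limitations: no Deep/gradient SHAP (the model contract is
  black-box), no Shapley interaction indices, no ridge/elastic-net LIME
  variants, no band deconvolution within zones, no instrument file formats
  (SPC/JCAMP) — spectra travel as wide-format delimited text.
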