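---
title: "Quantifying protein-mediated G-quadruplex unfolding from smFRET traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying protein-mediated G-quadruplex unfolding from smFRET traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 3.5)
```

```{r setup, message = FALSE}
library(gquadfret)
library(dplyr)
library(ggplot2)
```

## The measurement

G-quadruplexes (GQs) are four-stranded DNA structures that helicases and
single-stranded-DNA binding proteins must resolve in vivo. In a
single-molecule FRET (smFRET) assay, a surface-tethered partial-duplex DNA
carries the GQ and a donor/acceptor dye pair; the apparent FRET efficiency
(proximity ratio)

$$E = \frac{I_A}{I_A + I_D}$$

reports the end-to-end compaction of the molecule. A folded GQ is compact
(high $E$), an unfolded or protein-bound molecule is extended (low $E$).
Movies of ~250 molecules per imaging field at 40 ms per frame yield
per-molecule intensity traces; pooling a short window of frames per molecule
across a field gives a steady-state population histogram of $E$.

`gquadfret` implements the quantification chain used to turn such histograms
into binding/unfolding isotherms:

1. **Trace processing** — background subtraction, filtering to single
   molecules, proximity-ratio computation
   (`subtract_background()`, `filter_single_molecules()`, `compute_fret()`);
2. **Histogram analysis** — percent-normalized histograms, subtraction of a
   reference histogram, cumulative-positive-area scoring, thresholded
   integration, Gaussian level identification
   (`fret_histogram()`, `subtract_reference()`, `positive_area()`,
   `threshold_population()`, `fit_fret_gaussians()`);
3. **Isotherm fitting** — weighted Langmuir fits of unfolded-percent versus
   effector concentration (`fit_langmuir()`);
4. **A synthetic trace generator** that emulates the assay's spectroscopic
   state model (`simulate_dataset()`, `simulate_titration()`), so the whole
   chain is validated by parameter recovery without instrument data.

## The spectroscopic state model

Each molecule occupies one of a small set of named states, each a Gaussian
$E$ level. The defaults (`default_states()`) describe partial-duplex human
telomeric GQ constructs with a 12–15 nt 3' overhang:

| state | $E$ | width | class |
|---|---|---|---|
| folded GQ, conformer 1 | 0.64 | 0.07 | folded |
| folded GQ, conformer 2 | 0.78 | 0.05 | folded |
| protein-bound folded GQ | 0.55 | 0.07 | folded |
| unfolded GQ | 0.40 | 0.06 | low |
| protein-bound unfolded DNA | 0.20 | 0.08 | low |
| coiled poly-dT (non-GQ constructs) | 0.85 | 0.05 | folded |

The configured widths are *apparent* level widths — the widths a Gaussian
fit to a measured histogram reports — so they already include photon-noise
broadening. Consequently the generator's additive channel noise
(`noise_sigma`, default 10 counts on a 500 count/frame molecule) models
only residual read noise; making it large would double-count the broadening
that is already in the state widths. Samples from a state Gaussian are not
clipped to $[0, 1]$: proximity-ratio noise legitimately produces values
slightly outside the unit interval, and histograms span $[-0.2, 1.2]$
instead.

In K$^+$ the folded GQ is a broad two-conformer mixture; the relative
abundance of the two conformers is not experimentally resolved and defaults
to 50/50. In Na$^+$ the GQ folds into a single conformation and a single
Gaussian (0.68 ± 0.06) is used.

### From isotherm to occupancies

Steady-state occupancies follow a Langmuir law in the titrated effector
concentration $x$ (protein in nM, or nucleotide in µM):

$$y = \frac{\alpha\, x}{x + K_\mathrm{eq}},$$

where $y$ is the percent of molecules in the low-FRET (unfolded +
protein-bound unfolded) class, $\alpha$ the saturating percentage, and
$K_\mathrm{eq}$ the half-saturation concentration. `occupancy_spec()`
turns an isotherm into a per-state probability vector:

```{r}
spec <- occupancy_spec(isotherm_params(49, 305, units = "nM"))
occupancy_vector(305, spec) # half-saturation: 24.5% in the low class
```

Two conventions here were genuinely open and are package decisions:

* **Low-class split.** The steady-state low-FRET peak near 0.30 is an
  equilibrium mixture of the unfolded (0.40) and protein-bound unfolded
  (0.20) levels; the generator splits the low class 50/50 between them by
  default (configurable), which reproduces the merged peak position.
* **Bound-folded partition.** How much of the *residual folded* class shows
  the protein-bound folded level (~0.55) is not identifiable from the
  isotherm. `bound_folded_fraction` defaults to 0: the isotherm parameters
  of a titration describe the unfolded population only, and any growing
  bound-folded shoulder would leak into the positive-area score — at
  saturation the score would approach 100% instead of $\alpha$, which
  contradicts the cross-check that the score at 1 µM protein
  ($49 \times 1000/1305 \approx 37.5\%$) matches the directly observed
  unfolded population (~40%). A `"saturation"` option
  ($x/(x+K_\mathrm{eq})$, binding-precedes-unfolding) is available for
  forward-modeling experiments that do resolve the bound-folded shoulder.
* **Baseline for relative titrations.** When a nucleotide is titrated at
  fixed protein concentration, the reference state already contains
  unfolded molecules; `baseline_low_percent` adds that baseline and the
  isotherm then describes the *additional* unfolding, exactly how such
  titrations are scored.

## The synthetic trace generator

`simulate_trace()` draws, per molecule: a lognormal brightness
($B \approx 500$ counts/frame, CV 0.2 — wide enough to exercise the
intensity-band filter), a state from the occupancy vector (held for the
whole movie in the static default), per-frame $E$ from the state Gaussian,
and geometric photobleaching times for each dye. Channels are rendered as
$I_A = B E + \mathrm{bg}_A + \varepsilon$,
$I_D = B(1-E) + \mathrm{bg}_D + \varepsilon$. Acceptor bleaching sends $E$
to ~0 (signal moves to the donor channel); donor bleaching sends both
channels to background, because FRET requires an excited donor. Bleach
rates default to $5\times10^{-4}$ (donor) and $10^{-3}$ (acceptor) per
frame so that most 30-frame movies survive while most 1000+-frame movies
bleach. Contaminants — aggregates (two molecules summed) and donor-only
molecules — are generated on request to exercise the filter.

Determinism: every molecule's random stream is seeded from
`(seed, dataset_index, molecule_id)`, so a single trace, a dataset, or a
whole titration is bit-reproducible, independent of simulation order.

A `dynamic_mode` exists in which molecules alternate between the folded and
low classes with exponential dwell times; it is a qualitative tool for
looking at unfolding/refolding dynamics in long traces and is not used by
the steady-state analyses (the histograms this package quantifies are
steady-state by design; dwell-time kinetics are out of scope).

What the generator deliberately does *not* emulate: camera images and spot
detection (the pipeline ingests traces), EMCCD excess noise, spectral
crosstalk and gamma corrections (both generator and analyzer use the raw
proximity ratio, so levels are self-consistent), dye blinking, and
conformational dynamics within the folded class. Passing recovery tests on
this generator therefore validates the *quantification chain*, not
instrument-level artifacts.

```{r}
occ <- occupancy_spec(isotherm_params(49, 305, units = "nM"))
cfg <- simulation_config(occupancy = occ, effector_conc = 1000,
                         n_molecules = 250, n_frames = 30, seed = 11)
ds <- simulate_dataset(cfg)
autoplot(dataset_histogram(ds)) +
  ggtitle("Simulated condition at 1000 nM protein")
```

## Trace processing

`filter_single_molecules()` accepts a trace iff (in order):

1. its mean total intensity lies within ±50% of the dataset median —
   rejects aggregates (~2× brightness) and dim spots. With the lognormal
   CV-0.2 brightness spread this band sits at ~2 sigma, so ~2% of honest
   singles are sacrificed while 2× aggregates sit ~5 sigma out;
2. it shows at most one bleach step (single-frame drop in total intensity
   exceeding half the running pre-drop mean) — a single molecule loses each
   dye at most once;
3. its mean $E$ over usable frames exceeds 0.1 — rejects donor-only
   molecules.

All thresholds are arguments. `compute_fret()` marks frames with total
intensity below a floor (default 100 counts) unusable; the usable window is
the prefix of frames before the first such event, so it ends at the donor
bleach. Background subtraction is `"constant"` (fixed per-channel values)
or `"post_bleach"` (per-molecule mean after the last detected bleach step,
falling back to constant with a warning when no bleach is seen — typical
for short movies).

## Histograms, subtraction, scoring

`fret_histogram()` pools the first `frames_per_molecule` (default 20)
usable frames per molecule — emulating short steady-state movies so bright
long-lived molecules do not dominate — and normalizes to percent: the
histogram totals exactly 100. Default binning is 0.025 over $[-0.2, 1.2]$
(56 bins), which resolves levels 0.1 apart given widths of 0.05–0.08.

`subtract_reference()` subtracts a reference histogram (the zero-effector
state) bin by bin on identical binning; because both inputs total 100%,
the difference has equal positive and negative lobes (asserted to 1e-9).
`positive_area()` sums the whole positive lobe — the percent of molecules
that entered new levels. No smoothing is applied before subtraction, and
no FRET cutoff is imposed by default; an optional `e_cut` restricts the
positive lobe below a threshold for sensitivity analysis.
`threshold_population()` integrates a single histogram below a FRET
threshold (e.g. $E \le 0.40$ for the unfolded population), with pro-rata
handling of the straddling bin to remove edge aliasing.

Two estimator properties worth knowing:

* **Overlap shrinkage.** Where the arriving low-FRET lobe and the departing
  folded lobe overlap, the subtraction cancels mass; with the default level
  table the overlap integral is ~3–4%, so recovered amplitudes run ~4–5%
  low ($\hat\alpha \approx 0.95\,\alpha$) while $K_\mathrm{eq}$ — a ratio
  of responses — is unaffected.
* **Noise positivity.** Summing positive bins of a noisy difference is
  biased upward by $\sim \sum_b \sigma_b/\sqrt{2\pi}$ over near-zero bins.
  Pooling more molecules per histogram shrinks $\sigma_b$ and hence the
  bias; this is one reason the validation runs pool replicate fields
  (below).

`fit_fret_gaussians()` fits one or two Gaussians to bin centers by
Levenberg–Marquardt least squares (initialized by a weighted-median split
of the occupied bins; $\sigma$ bounded to $[0.01, 0.3]$) — used to identify
levels, e.g. the two folded conformers in K$^+$ versus the single Gaussian
in Na$^+$.

## Weighted Langmuir fitting

`fit_langmuir()` minimizes
$\sum_i \left(\frac{y_i - \alpha x_i/(x_i+K_\mathrm{eq})}{\sigma_i}\right)^2$
over $\alpha \in (0, 100]$, $K_\mathrm{eq} > 0$ (Levenberg–Marquardt;
start values $\alpha_0 = \max y$, $K_0$ = first concentration exceeding
half of $\max y$ — robust for saturating and non-saturating series).
Reported 1-sigma errors come from the curvature (inverse weighted
Gauss–Newton Hessian) at the optimum, i.e. they propagate the supplied
$\sigma_i$ without rescaling by residual variance; $\chi^2$ is reported so
dispersion stays visible. The zero-concentration point is the subtraction
reference, not an observation — it is excluded from the residuals by
default (`include_zero = TRUE` keeps it).

Per-point uncertainties from a single synthetic replicate are binomial:
$\sigma_i^2 = 100^2\left[\frac{p_s(1-p_s)}{n_s} +
\frac{p_r(1-p_r)}{n_r}\right]$, with $p_s, p_r$ the measurable low-FRET
fractions (threshold 0.45, between the unfolded and bound-folded levels)
of sample and reference and $n$ their molecule counts. The reference term
matters when the reference itself holds unfolded molecules (nucleotide
titrations at fixed protein); when it does not, this reduces to the
binomial error of the unfolded fraction. For titrations where the effector
*suppresses* unfolding (e.g. ADP at fixed protein), the positive lobe is
the refolded population; `response = "folding"` labels the series
accordingly and the same machinery applies.

## End-to-end example

```{r}
occ <- occupancy_spec(isotherm_params(49, 305, units = "nM"))
cfg <- simulation_config(occupancy = occ, n_molecules = 250,
                         n_frames = 30, seed = 1)
datasets <- simulate_titration(cfg, c(0, 50, 100, 300, 500, 1000, 2000),
                               n_fields = 6)
series <- analyze_titration(datasets, units = "nM")
fit <- fit_langmuir(series)
tidy(fit)
autoplot(fit)
```

## Validation design and problem sizes

The recovery tests configure the generator with published isotherm
parameters, run the full pipeline, and compare the recovered parameters.
Sizes are chosen to make the comparison informative:

* A *single* 250-molecule titration fundamentally cannot pin
  $K_\mathrm{eq}$ tightly: binomial counting noise alone gives
  $\mathrm{sd}(\hat K_\mathrm{eq}) \approx 70$ nM for the
  nucleotide-free design. Real titrations average several movies per
  condition; the validation runs therefore pool 24 replicate 250-molecule
  fields per concentration (12 for the binding fixture) into one condition
  histogram, bringing the recovery scatter to ~15 nM and shrinking the
  noise-positivity bias. The field size itself stays at the physical ~250
  molecules per imaging area.
* Histograms pool 20 frames per molecule from 30-frame movies, the
  steady-state convention; long movies serve trace inspection, not
  histograms.

Degenerate inputs are errors, not silent results: fewer than 3 titration
points, all-zero responses, mismatched histogram binning, histograms with
no usable frames, and non-converging fits (which carry their last iterate
in the error message).

## Limitations

* The proximity ratio is used uncorrected; absolute $E$ values are
  convention-dependent and comparisons should stay within one dye/setup
  convention.
* Subtraction scoring underestimates amplitudes by the lobe-overlap
  fraction (~5% relative here); it is a population *difference* score, not
  a mixture decomposition.
* The generator's static steady-state assumption means kinetic observables
  (dwell times, rates) are out of scope; `dynamic_mode` is qualitative.
* Binomial error bars understate replicate-to-replicate variability of
  real experiments (stage drift, surface chemistry); with real replicates,
  use their standard deviations as `y_err`.
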