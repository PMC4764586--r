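---
title: "Models and methods behind sptmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sptmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sptmap)
```

`sptmap` analyses single-particle trajectories of mRNAs and ribosomes to map
where translation happens in a cell. This vignette explains the models the
package fits, the assumptions behind them, the choices made where the
methodology was genuinely open, and what the synthetic-data generator does
and does not emulate.

## The displacement models

All diffusion statistics start from radial displacements
$r = \lVert p(t+\Delta t) - p(t) \rVert$ at a single lag. For free,
isotropic 2-D diffusion with apparent coefficient $D_\mathrm{app}$ the
displacement CDF is

$$P(r, \Delta t) = 1 - \exp\!\left(-\frac{r^2}{4 D_\mathrm{app} \Delta t}\right),$$

and a population mixing a slow and a fast species follows

$$P(r, \Delta t) = 1 - \left[A\,e^{-r^2/4 D_\mathrm{slow} \Delta t}
  + (1-A)\,e^{-r^2/4 D_\mathrm{fast} \Delta t}\right],$$

with $A$ the slow fraction. The corresponding density of $r$ is Rayleigh,
which is also the per-step emission model of the hidden Markov module.
Coefficients are *apparent* throughout: localization error and motion blur
are not subtracted, matching how such coefficients are usually reported for
camera-limited tracking.

**Fitting.** Both CDF models are fitted by least squares between the model
CDF and the empirical CDF evaluated at 200 evenly spaced quantile points of
the data. A quantile grid (rather than binned histograms or maximum
likelihood) keeps the objective independent of sample size and puts equal
weight on every part of the distribution actually sampled. $D$ is bounded in
$[10^{-4}, 10]$ µm²/s; the two-component fit is parameterized so that
$D_\mathrm{slow} < D_\mathrm{fast}$ holds by construction and is run from
three starts to avoid local minima. With `fix_D` only $A$ is fitted, which
supports deconvolving many experimental conditions against one shared pair
of coefficients — the convention used for comparing treatments. Fits whose
mixture weight lands on the boundary are flagged rather than rejected.

**Single-lag convention.** CDF fits, per-track apparent coefficients and the
local diffusion map all use lag-1 (35 ms) displacements only. Short tracks
(3 frames) dominate these datasets, single-lag displacements are
near-independent, and the spatial maps are defined on a 35 ms timescale;
multi-lag pooling would mix timescales without adding much information.

## MSD, corralling, and the exploration area

`msd_ensemble()` reports, per lag, the mean of squared displacements pooled
over all tracks with overlapping windows; standard errors are computed over
per-track means because tracks, not displacements, are the independent
units. Corralled motion produces an MSD plateau. For a reflecting square
corral of side $L$ the equilibrium plateau has a closed form: positions at
well-separated times are independent Uniform$[0,L]$ per coordinate, so

$$\mathrm{MSD}_\infty = 2 \times 2\,\mathrm{Var}(U[0,L]) = L^2/3.$$

`exploration_area()` estimates the plateau as the mean MSD over the trailing
third of lags and flags the result when the curve is still rising there
(window slope above 10% of the initial slope), so free diffusion cannot
masquerade as confinement.

## Detection and linking

Frames are median-background-subtracted and smoothed with a Gaussian filter
of half-width-at-half-maximum 1.3 px (sd $= 1.3/\sqrt{2\ln 2} \approx
1.104$ px, the exact HWHM conversion). Local maxima above a threshold of 5
robust (MAD) standard deviations are refined by local least-squares 2-D
Gaussian fits; detections closer than twice the filter HWHM merge to the
brighter one. Linking is globally greedy by distance with a 5 px cap, no gap
closing, ties broken by detection index — deterministic and documented,
chosen because the commercial tracker it replaces does not publish its
assignment algorithm. Tracks shorter than 3 frames are dropped on export, so
the minimum exported lifetime at 35 ms frames is 105 ms (lifetimes are
counted as localizations × Δt).

## Compartments and co-movement

No standard recipe exists for delineating focal adhesions from a marker
channel, so `segment_adhesions()` declares its own: Gaussian smoothing, Otsu
threshold, minimum-area filter (no watershed splitting — touching adhesions
stay one component). Tracks are partitioned at track level: any localization
inside the mask dilated by 160 nm (~1.5 px, configurable) makes a track
"adhesion". Group differences are tested with a two-sample
Kolmogorov–Smirnov test on per-track apparent coefficients at α = 0.01.

Co-movement requires at least 3 *consecutive* common frames, every one of
which has the two particles within 320 nm — the stringent reading of a
"within 320 nm for 105 ms" rule. Candidate pairs are found by hashing
detections on a grid of cell size 320 nm, so the search is near-linear in
detections. Matching is many-to-many: one mRNA may pass near several
activated ribosomes.

The colocalization null uses the area-normalized distance distribution:
histogram counts of all cross-channel pair distances divided by annulus
area $\pi(r_\mathrm{out}^2 - r_\mathrm{in}^2)$. Under spatial independence
this density is flat in $r$; a co-moving subpopulation appears as a peak
below ~3 px. Two caveats the test suite makes explicit: (1) annuli truncate
at the field border, so flatness holds only for reference points at least
$r_\mathrm{max}$ inside the support of the other channel — the tests apply
this standard edge correction; (2) permuting frames destroys *temporal*
co-movement but not the territorial overlap of partner tracks (a co-moving
ribosome spends its whole track near one mRNA's path), so frame shuffling
collapses the sharp peak without restoring exact flatness. Strict χ²
flatness is therefore asserted for spatially independent channels.

## The two-state diffusion HMM

`fit_hmm()` implements a pooled hidden Markov model over displacement
magnitudes: $K$ diffusive states with Rayleigh emissions
$p(r \mid D) = \frac{r}{2 D \Delta t} e^{-r^2/4 D \Delta t}$, a row-stochastic
per-frame transition matrix, and parameters shared across all tracks (each
track is an independent sequence). Estimation is Baum–Welch EM with scaled
forward–backward, best of several restarts, converging when the relative
log-likelihood change falls below $10^{-8}$ (cap 500 iterations). States are
reported fast-first (state 1 = $D_1$, state 2 = $D_2$). Emissions use
magnitudes rather than 2-D vectors — equivalent under isotropy and simpler
to validate — and, consistent with the rest of the package, localization
error is not modelled, so state coefficients are apparent.

Model selection uses BIC, $-2\log L + p\ln(n_\mathrm{steps})$ with
$p = K + K(K-1) + (K-1)$, instead of the variational-Bayes evidence of the
method it stands in for. This is a deliberate simplification: on
well-separated states (4-fold coefficient contrast) it reproduces the
1-vs-2-state decision essentially always, but no numerical equivalence to
the Bayesian evidence is claimed. Directed-motion (drift) states are out of
the default model space because the motivating datasets showed no directed
transport; mean state lifetimes are reported as $\Delta t/(1 - T_{kk})$.

Per-step annotation is the Viterbi path; visits are maximal runs of one
state, and visits touching a track's first or last step are marked as
boundary visits so duration histograms can exclude them (those durations are
censored). One bias worth knowing: at 35 ms frames and 4-fold contrast the
Viterbi path suppresses 1–2-step excursions, which inflates mean visit
durations by roughly 25–40% relative to the true label runs. The
transition-matrix lifetime estimator does not share this bias and recovers
simulated lifetimes within 20%; duration histograms are best read as
shape/ordering evidence, not unbiased lifetime estimates.

## The synthetic-data generator

The generator is first-class, tested code, and its defaults are the study
conditions of the analyses: 35 ms frames, 107 nm pixels, fast/slow
coefficients 0.4 and 0.1 µm²/s, geometric (memoryless bleaching)
track-length attrition, Gaussian localization error added to reported
positions (the underlying walk stays Markovian). It emulates:

- free Brownian motion, two-state switching diffusion (exact
  continuous-time discretization $P = e^{Q\Delta t}$, which preserves
  stationary occupancy exactly), reflecting square corrals (fold-reflection
  applied within each step; tracks start at equilibrium, uniform in the
  corral), and tethered particles;
- elliptical adhesion-shaped slow zones with position-dependent step
  variance (tracks reflect at the field border in this scenario so the
  population stays comparable against the static mask);
- dual-channel co-moving pairs: a deterministic
  `round(fraction × n_mrna)` of mRNAs each get a ribosome partner that
  copies the mRNA's reported path plus i.i.d. Gaussian jitter — the minimal
  model that satisfies the co-movement detector's distance criterion by
  construction;
- movie rendering as integrated 2-D Gaussian PSFs with Poisson shot noise,
  16-bit quantization.

It does **not** emulate: directed/motor transport (available only as a test
scenario is out of scope by default), fluorophore blinking kinetics, 3-D
effects of evanescent illumination, camera registration error between
channels (channels are assumed pre-registered; an affine correction hook
exists but is off by default), or anything about real cytoplasmic
heterogeneity beyond the geometries above. Passing tests on synthetic data
therefore demonstrate that the estimators recover the parameters of these
models at realistic sample sizes — not that real cells obey the models.

Track lifetimes are geometric with a nominal mean (no published value exists
for the motivating data; ~6 frames reproduces the reported ~200 ms average).
Free tracks live on an unbounded plane — no periodic wrapping — and only
movie rendering clips to the field, to avoid artificial confinement.

## Problem sizes and numerical choices

The test suite and acceptance script size simulations so each check has the
power it needs and nothing more: $10^5$ displacements for the 2%
one-component recovery bound, $3\times10^4$ for ±0.05 slow-fraction
recovery, ~$2.5\times10^4$ pooled steps for 10%/20% HMM parameter recovery,
500 trajectories × 100 frames for 5% exploration-area recovery. Degenerate
inputs are handled explicitly: zero-diffusion and zero-noise tracks are
legal, empty displacement sets raise errors, boundary-stuck mixture weights
and low-occupancy HMM states are flagged, and an MSD without a plateau is
flagged rather than silently averaged.

## Known limitations

- Linking is greedy, not globally optimal; at high particle density it will
  split or swap tracks earlier than an assignment-problem solver would.
- The CDF deconvolution assumes exactly two exponential components; more
  heterogeneous populations bias $A$.
- The HMM ignores localization error, so at very low $D$ the slow state
  absorbs the noise floor.
- Viterbi visit durations are upward-biased at this frame rate (see above).
- Percent-slowdown summaries compare one-component fits, which are
  themselves compromises on mixed populations; they are comparative, not
  mechanistic, quantities.
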