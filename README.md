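# sptmap

Single-particle tracking (SPT) analysis of mRNA and ribosome mobility in
live cells. `sptmap` is for cell biologists and microscopists who track
single molecules — MS2-labelled mRNAs, sptPALM-labelled ribosomes — and want
to turn thousands of short trajectories into maps of where translation
happens: local diffusion heat maps, focal-adhesion compartment comparisons,
mRNA–ribosome co-movement statistics, and per-step motion-state annotation.

Because raw tracking movies are rarely shareable, the package ships a
first-class synthetic-data module that generates trajectories, dual-channel
co-moving pairs, adhesion-shaped slow zones and rendered TIFF movies with
full ground truth, so every stage of the pipeline is testable end to end.

## What it computes

**Displacement CDF deconvolution.** For radial displacements r at lag Δt,
free 2-D diffusion gives the cumulative distribution

    P(r, Δt) = 1 − exp(−r² / (4 D_app Δt))

and a two-species population gives the mixture

    P(r, Δt) = 1 − [A·exp(−r²/(4 D_slow Δt)) + (1−A)·exp(−r²/(4 D_fast Δt))]

where A is the slow fraction. `fit_cdf_one()` and `fit_cdf_two()` fit these
by least squares on a 200-point quantile grid of the empirical CDF;
`fit_cdf_two(fix_D = c(0.1, 0.4))` deconvolves different conditions against
one shared pair of coefficients.

**MSD and exploration area.** `msd_ensemble()` pools squared displacements
per lag (SEM over tracks); for corralled motion the long-lag plateau is the
exploration area — for a reflecting square corral of side L the equilibrium
value is L²/3 — estimated by `exploration_area()`.

**Spatial maps.** `local_diffusion_map()` grids lag-1 displacements
(20 nm nodes, 80 nm capture radius, ≥5 displacements per node; node value
mean(r²)/4Δt) and `density_map()` bins localizations for PALM-style density
maps.

**Compartments.** `segment_adhesions()` (smooth + Otsu + size filter) and
`partition_tracks()` split trajectories into adhesion vs non-adhesion
classes; `compare_compartments()` reports the percent slowdown
100·(1 − D_adh/D_other), slow-fraction change, lifetime shift and a KS test.

**Co-movement.** `find_comoving()` flags track pairs that stay within
320 nm for ≥3 consecutive frames (105 ms);
`normalized_distance_distribution()` divides distance-histogram counts by
annulus area, so channel independence appears as a flat density and
colocalization as a short-distance peak.

**Motion states.** `fit_hmm()` is a pooled two-state diffusion hidden Markov
model (Rayleigh step emissions, Baum–Welch EM, shared parameters across
tracks), `select_model()` picks K by BIC, `annotate_states()` gives per-step
Viterbi labels, and `duration_histograms()` pools state-visit durations,
optionally excluding boundary-censored visits.

## Worked example

Simulate a two-state switching population (D1 = 0.4, D2 = 0.1 µm²/s) at
35 ms frames, then deconvolve it two ways:

```r
library(sptmap)

cfg <- sim_config(frame_interval = 0.035, pixel_size = 0.107,
                  field_size = c(20, 20), n_frames = 101, seed = 1)
sim <- simulate_tracks(cfg, motion_two_state(D1 = 0.4, D2 = 0.1,
                                             k12 = 2, k21 = 1.4), 300)

d <- collect_displacements(sim$tracks, lag_frames = 1, frame_interval = 0.035)
fit_cdf_one(d)
#> One-component CDF fit: D_app = 0.1787 um^2/s (n = 30000, SS = 0.233)
fit_cdf_two(d, fix_D = c(0.1, 0.4))
#> Two-component CDF fit: A(slow) = 0.570, D_slow = 0.1000, D_fast = 0.4000 um^2/s (n = 30000, SS = 0.000538)

model <- fit_hmm(sim$tracks, K = 2, n_restarts = 2, seed = 2)
tidy(model)
#> # A tibble: 2 × 5
#>   state      D occupancy stay_prob lifetime_s
#>   <int>  <dbl>     <dbl>     <dbl>      <dbl>
#> 1     1 0.405      0.433     0.933      0.526
#> 2     2 0.0993     0.567     0.949      0.680
```

The one-component fit lands between the two true coefficients — the single
exponential cannot describe a mixed population (its residual sum of squares
is ~400× larger than the two-component fit's). The mixture fit recovers the
true coefficients and the occupancy of the slow state, and the HMM
additionally estimates switching kinetics: the stay probabilities imply
mean state lifetimes of about 0.5 s (fast) and 0.7 s (slow), matching the
simulated rates k12 = 2 s⁻¹, k21 = 1.4 s⁻¹. `autoplot()` methods exist for
MSD curves, CDF fits, diffusion/density maps and distance distributions;
`plot_state_tracks()` draws state-coloured trajectories over a compartment
mask. `run_pipeline()` chains all stages from one declarative config and
`make_report()` renders the result as Markdown.

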