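---
title: "From intensity traces to binding rate constants: the smfretkin methods"
author: "smfretkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From intensity traces to binding rate constants: the smfretkin methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The system and the model

`smfretkin` implements the single-molecule FRET (smFRET) analysis chain used
to resolve ligand-driven conformational states of a receptor with two
identical, independent binding sites — the motivating case is glutamate
binding to the two GluN2B ligand-binding domains of an NMDA receptor, read
out as the GluN1 amino-terminal-domain inter-dimer distance. The kinetic
model is a linear three-state chain

    R  <->  RA  <->  RAA

with per-site association rate constant `kon` (1/uM/s) and dissociation
rate constant `koff` (1/s). Site independence fixes the edge rates:

* R -> RA: `2 kon c` (two empty sites), RA -> RAA: `kon c` (one empty site)
* RAA -> RA: `2 koff` (two bound ligands), RA -> R: `koff`

so the scheme has only two free parameters plus the concentration `c`, and
`Kd = koff / kon`. Its equilibrium occupancy is binomial with per-site
occupancy `theta = c / (c + Kd)`: `((1-theta)^2, 2 theta (1-theta),
theta^2)`. A useful analytic consequence: the doubly bound (activated)
fraction `theta^2` reaches half its maximum at `c = Kd / (sqrt(2) - 1)`,
about `2.41 Kd` — a simulation of the ideal scheme therefore cannot (and
should not) reproduce an empirical EC50 measured on real receptors, where
cooperativity and downstream steps compress the dose–response.

Each kinetic state maps 1:1 to a FRET level: R high (~0.52), RA middle
(~0.40), RAA low (~0.28). Everything downstream exploits this singleton
state-to-class mapping.

## What the generator emulates — and what it does not

`simulate_experiment()` produces movies of donor/acceptor intensity traces:

* a Gillespie (exact CTMC) state path per molecule, started from the
  equilibrium distribution at the given concentration;
* per-frame true FRET as the *time-weighted average* of state means within
  each 100-ms frame. This models motion blur: a transition mid-frame leaves
  an intermediate-valued frame, which is what produces the rare apparent
  direct high<->low jumps in idealized data. It must be modeled, not
  idealized away, because the downstream transition-density "void" claim is
  about exactly these events;
* detection distortions inverted from the analysis side: corrected total
  intensity `T` (default 500 a.u.) is split so that `compute_fret()` with
  the same crosstalk (0.105) and gamma (1.1) recovers the true FRET exactly
  at zero noise (`IA = T (E + ct)/(1 + ct)`, `gamma ID = T (1 - E)/(1 +
  ct)`);
* additive Gaussian channel noise. The default `noise_sd = 33.6` a.u. was
  derived once by propagating channel noise through the FRET formula so a
  single-state trace has FRET-domain SD ~0.055, giving the narrow
  single-peak histograms the analysis assumes;
* single-step exponential photobleaching (donor mean 80 s, acceptor mean
  120 s, invented values — the experimental bleach-time distributions are
  not published). After acceptor bleach the rendered FRET is ~0 with the
  donor persisting; after donor bleach both channels fall to background.
  Optional artifact modes (a second half-step acceptor, a drifting total)
  exist solely to exercise the selection filter.

Not emulated: camera physics (EMCCD/sCMOS excess noise, pixelation),
blinking, multi-dye stoichiometries, spot detection, background drift.
Passing tests on this generator therefore show that the *analysis chain* is
correct and unbiased under its own assumptions; they do not certify
robustness to instrument-specific artifacts in real recordings.

Seeds: each trace derives its own seed deterministically from the master
seed and a trace counter, so any subset of traces is reproducible.

## Trace processing and selection

`compute_fret()` applies the gamma correction to the donor channel and then
the standard formula `E = (IA - 0.105 ID) / (ID + IA)` on corrected
intensities; frames with non-positive total are flagged undefined rather
than zeroed. Where gamma enters is not fixed by the formula alone; scaling
the donor before the ratio is the standard detection-efficiency convention,
and the generator uses the same convention so the round trip is exact.

Bleach detection runs recursive exhaustive change-point scans (two-sample
t statistic, minimum segment 5 frames). Donor bleaching is located on the
*total* intensity, which is insensitive to FRET transitions; acceptor
bleaching on the acceptor channel before the donor bleach. A change point
counts as a fluorophore-loss step only if the signal falls below 0.6x its
pre-step level: losing a dye at least halves a channel, while conformational
shifts move at most ~30% of it.

Selection retains traces with exactly one donor-bleach step, at most one
acceptor step (an acceptor that outlives the donor shows none and is kept),
a stable total intensity (CV <= 0.15 over the usable range — the published
criterion says only "stable", so the threshold is a package choice, exposed
as a parameter), and >= 20 s of usable FRET before the first bleach. Every
rejection carries a reason code.

Histograms pool the first 20 s of usable FRET per movie on a fixed grid
(bins of 0.02 from -0.2 to 1.2 — wide enough for noise excursions, fine
enough for >= 6 bins per 0.12 FRET step), normalize per movie, and only then
aggregate across movies (bin-wise mean +/- SEM). Frames after acceptor
bleach never enter histograms; the zero-FRET population is handled in
idealization instead.

## Histogram fitting and dose–response

Gaussian components are fit to the *binned density* by bounded weighted
least squares (`minpack.lm`), mirroring the interactive peak-fitting
workflow the histograms come from — not a sample-based mixture model. Means
are bounded to [0, 1] and SDs to [0.01, 0.2] to prevent component collapse;
components are reported high/middle/low by descending mean. The global fit
shares means *and* SDs across a concentration series (areas free per
histogram): state distributions should not move with concentration, only
their occupancies; sharing SDs is exposed as a switch since the published
description does not pin it down.

The dose–response uses the three-parameter logistic
`f(c) = fmax / (1 + (EC50/c)^h)`. Zero-concentration points cannot sit on a
log axis; the 3-parameter form already forces `f(0) = 0`, which is exactly
the baseline they would constrain, so they are dropped from the abscissa.

Group comparisons use the two-tailed Student t test (pooled variance, or
paired on differences), with P = 1 by convention for degenerate
zero-variance equal-mean input.

## SKM idealization

`skm_idealize()` is full segmental k-means: iterate { Viterbi segmentation
under Gaussian emissions and the current transition matrix; re-estimate
state means, variances, transition probabilities and initial probabilities
from the segmentation } until the labels fix, best of several randomly
perturbed initializations by total path likelihood. Design points:

* transition probabilities are re-estimated from segment counts each
  iteration (an option holds them fixed and uniform); a tiny floor keeps
  log-probabilities finite without measurably perturbing the
  classification-likelihood ascent, which the tests assert is monotone;
* on exact Viterbi ties the path stays in the current state, minimizing
  spurious transitions;
* a state that receives no frames is dropped with a warning and the model
  continues with fewer states;
* traces in a list share one model (pooled re-estimation, per-trace
  segmentation), which is how a per-condition dataset is idealized;
* a dedicated zero-FRET class (initial mean 0) is appended only when the
  input contains post-acceptor-bleach frames. `remove_zero_state()` then
  truncates trailing zero-FRET frames and, for internal zero runs (blinks),
  splits the trace and keeps the longer fragment.

Initial means default to quantiles of the pooled data.

## Dwell times, dead time, and the MIL fit

`extract_dwells()` converts label runs to (state, duration) dwells and
applies the 200-ms dead time by *merging*: any shorter dwell is absorbed
into its preceding dwell (a short first dwell into the following one),
iterating until stable. Merging, rather than dropping, conserves total
idealized time and matches the missed-event logic of interval likelihoods.
First and last dwells are flagged censored.

`dwell_loglik()` exploits the singleton state-to-class mapping: the full
aggregated-state interval likelihood reduces exactly to truncated
exponential dwell densities with branching probabilities. Each observed
dwell of duration `t` in state `i` ending in `j` contributes

    log(lambda_i B_ij) - lambda_i (t - tau)

conditioned on `t >= tau` (the dead time); censored final dwells contribute
the survivor term only. First dwells keep their full term — the residual
life of an exponential is exponential with the same rate. Two dead-time
subtleties matter in practice:

* merging manufactures apparent *direct* high<->low adjacencies (a short
  middle dwell swallowed by its neighbor). Their direct rate is zero under
  the linear scheme, so the naive branch term would be -Inf on essentially
  any real dataset. The branch matrix therefore uses first-order effective
  rates `q_ij + sum_k q_ik (1 - exp(-lambda_k tau)) q_kj / lambda_k`,
  renormalized per state;
* invisible excursions `i -> k -> i` shorter than the dead time extend the
  apparent dwell in `i`. The default `missed_events = "first_order"` lowers
  the apparent exit rate accordingly; `"conditional"` keeps the plain rates
  for closed-form comparisons. Both reduce exactly to `q_ij / lambda_i` at
  zero dead time. On oracle dwell sequences (true state paths,
  frame-discretized and merged) the first-order form recovers all four free
  rates of the reference scheme within ~4%, where plain conditioning is
  10–20% low on the middle-state exit rates.

`fit_rates()` maximizes in log-rate space (positivity without constraints)
with L-BFGS-B on [1e-6, 1e4], five starts perturbed +/- half a decade,
relative tolerance ~1e-9. Standard errors come from the inverse observed
information at the optimum; `Kd = koff/kon` gets a delta-method SE. A rate
at the search boundary is flagged — this is the "very low-probability
transition" signature by which a triangular (direct R<->RAA) scheme fit to
linear-truth data reveals itself, and such fits are reported as
non-converged rather than hidden. `compare_schemes()` tabulates
log-likelihoods, parameter counts and pinned rates across schemes without
aborting on per-scheme failures.

## Numerical choices and degenerate inputs

* Histogram fits: multi-start jitter of 0.05 on means; equal bin weights by
  default (Poisson weights optional).
* Change-point scans guard zero-variance segments (noiseless steps give an
  infinite statistic, flat traces give zero) and clamp tiny negative
  sums-of-squares from cancellation.
* Empty selections, movies without usable frames, all-zero idealized
  traces, and dwell sequences shorter than the dead time all return empty,
  flagged objects instead of erroring mid-pipeline.
* Dose–response fits refuse non-spanning occupancy data (unidentifiable)
  and fewer than four positive concentrations.

## Problem sizes

The shipped tests and the acceptance script run the full chain at 500–750
traces of 60 s per condition (5 movies), which yields roughly 2,000–4,000
dwells after selection and merging and determines Kd to a few percent;
oracle suites use 10,000 Gillespie dwells and 100 random Viterbi
enumeration instances. These sizes are the package's chosen benchmark
scale: large enough that estimator noise is well below the tolerances being
asserted, small enough to run the whole suite in minutes on one core.

## Known limitations

* SKM systematically erodes dwells near the resolution limit (a 2-frame
  excursion is often cheaper to absorb than to pay two transition
  penalties), so fitted rates retain a few-percent downward bias even after
  first-order missed-event correction; the Kd ratio cancels most of it.
  Exact missed-event likelihoods (matrix-exponential style) would go
  further and are out of scope.
* The selection filter assumes single-step bleaching; gradual photophysics
  or strong background drift would need the artifact modes extended.
* The dose–response of the ideal scheme saturates at `fmax = 1` and has no
  cooperativity term; it is a model prediction tool, not a re-fit of
  published dose–response data.
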