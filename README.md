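# smfretkin

Single-molecule FRET (smFRET) trace simulation, idealization and
dwell-time kinetics for ligand-binding receptors with two identical,
independent binding sites.

## The problem

smFRET reports the conformation of one receptor at a time as a noisy FRET
efficiency trace sampled at camera frame rate. For an NMDA-type receptor,
glutamate binding to its two GluN2B ligand-binding domains moves the
amino-terminal-domain dimers apart in two discrete steps, visible as three
FRET levels (high ~0.52, middle ~0.40, low ~0.28) that map 1:1 onto the
kinetic states of a linear two-site binding scheme

    R  ⇌  RA  ⇌  RAA        (resting, one site occupied, both occupied)

with per-site rate constants `kon` (µM⁻¹s⁻¹) and `koff` (s⁻¹). Site
independence fixes the edge rates — R→RA at `2·kon·c`, RA→RAA at `kon·c`,
RAA→RA at `2·koff`, RA→R at `koff` — so equilibrium occupancy is binomial
in the per-site occupancy `θ = c/(c + Kd)`, with `Kd = koff/kon`.

Recovering `kon`, `koff` and `Kd` from camera-limited traces takes a full
chain: FRET calculation with crosstalk/γ corrections, photobleaching
detection and molecule selection, per-movie histograms with across-movie
SEM, Gaussian and Hill dose–response fits, segmental k-means (SKM)
idealization, transition-density plots, dead-time dwell extraction, and
dwell-time maximum-likelihood fitting with missed-event handling.
`smfretkin` implements that chain, plus a forward simulator that generates
donor/acceptor intensity traces with the statistical structure the
analysis assumes (Gillespie state paths, frame-integration blur, 10.5%
crosstalk, γ = 1.1, channel noise, single-step photobleaching), so every
stage can be validated by parameter recovery.

## Worked example

Simulate five movies at 300 nM glutamate with the reference rate constants
(`kon = 1.0 µM⁻¹s⁻¹`, `koff = 0.46 s⁻¹`, so `Kd = 0.46 µM`), then run the
chain and re-estimate the scheme:

```r
library(smfretkin)

kp <- kinetic_params(kon = 1.0, koff = 0.46, conc = 0.3)
ts <- simulate_experiment(kp, n_movies = 5, traces_per_movie = 40,
                          duration = 60, seed = 42)

sel <- select_traces(ts)                    # bleach + stability criteria
length(sel$traces)
#> [1] 50

fit_gaussians(aggregate_histograms(compile_histograms(sel)), k = 3)
#> gauss_fit: 3 component(s), ssr = 0.1141
#>     mean      sd   area   fwhm
#> 1 0.4944 0.06860 0.5341 0.1615
#> 2 0.3827 0.04620 0.3277 0.1088
#> 3 0.2749 0.05117 0.1372 0.1205

set.seed(42)
skm <- skm_idealize(idealization_input(sel), n_states = 3)
skm$state_means                             # the three FRET levels
#> [1] 0.5203468 0.3996191 0.2785113

its <- Filter(function(i) !isTRUE(attr(i, "empty")),
              lapply(skm$traces, remove_zero_state))
dwells <- Filter(function(d) nrow(d) > 1,
                 lapply(its, extract_dwells, dead_time = 0.2))

direct_transition_fraction(transition_density(its))
#> [1] 0.008705114                           # high<->low goes via middle

fit_rates(dwells, scheme_spec("linear", "independent_sites", conc = 0.3),
          dead_time = 0.2)
#> mil_fit (linear, independent_sites): loglik = -1724.98 over 954 dwells
#>  rate  value      se pinned
#>   kon 0.8973 0.04311  FALSE
#>  koff 0.4245 0.02069  FALSE
#> Kd = koff/kon = 0.473 uM (SE 0.03)
```

Fifty molecules survive selection; the three Gaussian components sit at the
configured FRET levels; fewer than 1% of idealized transitions jump
directly between the high and low states (they pass through the
singly-bound intermediate); and the constrained maximum-likelihood fit
returns `Kd = 0.473 µM` against the generator's 0.46 µM from ~950 dwells.
`fit_rates` with `constraint = "free"` drops the 2:1 tying and recovers the
independent-sites structure empirically; `compare_schemes()` shows a
triangular scheme driving its direct R⇌RAA rates to the search boundary —
the signature of a transition that is not in the data.

A configuration-driven runner (`run_pipeline()`, stages `simulate` →
`process` → `histfit` → `doseresponse` → `idealize` → `kinetics`, JSON
report) and a thin CLI (`inst/cli/smfretkin`) wrap the same functions.

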