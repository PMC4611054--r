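---
title: "Mechanistic models of 20S proteasome peptide-hydrolysis dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanistic models of 20S proteasome peptide-hydrolysis dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteodyn)
```

## The scientific problem

In vitro digestions of short fluorogenic peptides (Suc-LLVY-MCA,
Bz-VGR-MCA, Z-LLE-MCA) by purified 20S proteasomes show two features no
Michaelis-Menten (MM) description can produce: the amount of product formed
after several hours *decreases* again at high initial substrate
concentration (substrate inhibition), and the reaction velocity *changes
over time* — for some substrates it grows for the first 90–120 minutes.
Both phenomena are signatures of the proteasome's architecture: the
catalytic sites sit inside a barrel reached through gated antechambers, so
transport into and out of the proteolytic chamber, the finite volume of
that chamber, and regulatory sites that modulate the gate all shape the
observable kinetics.

This package implements a family of nine kinetic models of increasing
mechanistic detail, simulates the fluorogenic-assay protocols, infers
parameters and compares models with ABC-SMC (approximate Bayesian
computation, sequential Monte Carlo), probes rate-limiting steps, and
extends the framework to a two-cleavage-site polypeptide.

## The model family

* **M1** — Michaelis-Menten: `v = vmax * S / (KM + S)`.
* **M2** — a two-site-modifier rate law: substrate and product each bind a
  catalytic and an inhibitory (modifier) site with Hill exponents `na`,
  `ni`; the intermediate complexes are treated in quasi-steady state,
  giving the partition denominator

  `x = 1 + S^na/KaS + S^ni/KiS + P^na/KaP + P^ni/KiP
     + S^(na+ni)/(a*KaS*KiS) + P^(na+ni)/(a*KaP*KiP)
     + S^na P^ni/(a*KaS*KiP) + S^ni P^na/(a*KiS*KaP)`

  and the flux

  `vhydr = na*kp*E0 * (S^na/KaS) * (1 + b*S^ni/(a*KiS) + b*P^ni/(a*KiP)) / x`

  with interaction factor `a` (= `alpha`) and catalytic modulation
  `b` (= `beta`, in (0, 1]: modifier-bound enzyme is at most as active).
  With the modifier site empty this reduces exactly to MM, which the test
  suite exploits as an oracle. In the fast balanced-transport limit of
  the compartmental models (`tau = kon * E0`, all transport rates large)
  the chamber concentration tracks the outer one, the two pools hold
  equal amounts, and the observable kinetics are Michaelis-Menten with an
  effective half-saturation of *twice* the active-site constant -- the
  factor 2 is the two-pool equilibration and the limit tests use it. The leading factor `na` can be switched to
  the number of active-site copies (2) via `lead_factor = "copies"`;
  the default follows the Hill-exponent convention.
* **M3/M4** — M2 plus a saturating positive product feedback on
  active-site binding (M3: `KaS` divided by `1 + eps_fb*P/(K_fb+P)`) or on
  the catalytic rate (M4: `kp` multiplied by the same factor). The
  mechanism of these feedbacks is stated qualitatively in the literature;
  the saturating form here is the simplest bounded choice, and these
  models exist mainly to be rejected by model selection.
* **M5–M9** — compartmentalised transport: substrate binds an outer gate
  site G1 (`kon`/`koff`), enters the chamber (`vin`), can bind the inner
  gate site G2 (`tau`, normalised by `E0`) and exit (`vout`). Influx
  saturates with the chamber load through the heuristic
  `tanh(max(0, E0*C − S − P))`, where `C` is the chamber capacity in
  molecules per proteasome. M5 has no regulation (an optional
  free-diffusion flag replaces gate binding with first-order exchange; it
  is not part of the default selection ladder). M6/M7 add a
  transport-enhancing regulatory site outside/inside the chamber
  (`Ron`/`Roff`, factor `1 + Xenh * occupancy/E0` on both transport
  rates); M8 adds a transport-inhibiting site inside; **M9**, the selected
  topology, combines the enhancer inside the chamber with an inhibitory
  site on the outer surface that consumes `h` peptides per site
  (`Ion*Sout^h`, factor `1/(1 + Yinh * occupancy/I0)`).

Signs of all binding/transport terms are fixed by the conservation laws:
every site class (G1, G2, enhancer, inhibitor) and the total peptide
moiety — counting `h` molecules per occupied inhibitory site — have
exactly zero time derivative. The test suite checks these sums to
machine precision on random states and to `1e-6` relative along
360-minute trajectories of all nine models.

### Units and scales

Concentrations are in uM and time in minutes throughout. The proteasome
concentration `E0` is derived from the assay description (enzyme mass in
ug, reaction volume in ul, molar mass 700 kDa by default) via
`enzyme_concentration_uM()`; 0.125 ug in 100 ul gives about 1.8 nM. The
argument of the capacity `tanh` is treated as dimensionless with an
implicit scale of 1 uM, and clamped at zero so an over-full chamber
cannot produce reverse flux. Site totals (`G1_tot`, `G2_tot`,
`Ereg_tot`, `I0`) default to `E0`: one effective site of each class per
proteasome, matching the `1/E0` normalisation of the inner binding
terms.

## Simulation

`simulate_time_course()` integrates with `deSolve::lsoda` (stiff-capable)
at `rtol = 1e-8`, `atol = 1e-10` by default; the derivatives are
evaluated in compiled C for speed, with the exported R `ode_rhs()` as the
readable reference — the two are held equal by the test suite, and an
independent fixed-step Runge-Kutta oracle reproduces the adaptive result
to 0.1%. States probed slightly negative by the integrator are clamped to
zero inside the rate evaluation (necessary because fractional Hill
exponents are undefined for negative arguments); entries below `-1e-6`
raise an error.

The fluorogenic observable is the *total product moiety*
(`Pout + G1Pout + P + G2P + EregP + h*IP`), identically the cumulative
hydrolysis, because the released fluorophore is detected wherever the
cleaved peptide resides; `where = "outer"` restricts to free outer
product. Initial velocities are least-squares slopes over the 15/30/45/60
minute samples, mirroring standard assay practice.

Protocol-level helpers cover the study designs: `dose_response()`,
`simulate_open_gate_mutant()` (open-gate mutant as a 10-fold increase of
`vin` and `vout`), `simulate_with_rpt()` (gate-opening Rpt peptides as a
constant multiplication of `vin`, default factor 5, reported as a
fold-stimulation series with zero-baseline points returned as `NA`), and
`simulate_cosubstrate()` for two peptide species sharing gates, capacity,
regulatory and active sites. In the co-substrate model the chamber load
seen by species A is volume-weighted, `S_A + P_A + (C_A/C_B)(S_B+P_B)`,
because capacity is inversely proportional to molecular volume; the
active sites are shared competitively through a joint partition
denominator (each species contributes its own occupancy terms, the free
state counted once). How the two species combine at the active site is
not constrained by available data; competitive sharing is this package's
choice and is exercised by reduction tests (one species absent, and a
split dose with `na = ni = h = 1`, both reproduce single-substrate runs).

## Synthetic data

`default_designs()` ships the assay layouts the package emulates: mouse
digestions of 80–480 uM Suc-LLVY-MCA and 160–640 uM Z-LLE-MCA, human
standard-/immuno-proteasome six-point designs from 20 to 640 uM for all
three substrates, an initial-velocity design sampled at 15/30/45/60 min,
and long kinetics to 360 min, each with duplicate replicates.

`fixture_parameters()` provides order-of-magnitude-plausible parameter
sets per substrate and isoform. They are *fixtures*, not experimental
estimates: chosen once so that each substrate class reproduces its
qualitative kinetic regime.

* *Suc-LLVY-MCA*: transport-limited, weak efflux, slow internal enhancer
  (`Ron*load/E0` on the tens-of-minutes scale, `Xenh = 10`), so the
  velocity grows over the first 90–120 min while the chamber fills over
  hours.
* *Z-LLE-MCA*: fast influx with limited efflux fills the chamber within
  minutes; catalysis is slow (`kp = 10 /min`) and strongly
  substrate/product-inhibited (`beta = 0.05`), so hydrolysis — not
  transport — limits the rate; the external inhibitory site (`h = 2`,
  `Yinh = 12`) produces the interior maximum of the dose-response.
* *Bz-VGR-MCA*: intermediate, enhancer-driven, no substrate inhibition in
  the assayed range.

Capacities are hundreds of molecules (200/250/290), decreasing with
molecular volume, the physically sensible scale for peptides of this
size. The immuno-isoform differs from the standard isoform in transport
parameters (gate affinity, influx/efflux, enhancer affinity) and, for the
beta5/beta1-cleaved substrates, in active-site parameters — not for
Bz-VGR-MCA — while `C` is shared (same cavity volume).

Measurement noise is multiplicative log-normal with log-scale standard
deviation `noise_sd` (default 0.05), because fluorescence errors scale
with signal; additive Gaussian noise is available as an option. The
magnitude of real assay noise is not known from the available material;
0.05 is a fixture choice. What the generator does *not* emulate:
fluorescence-unit calibration, photobleaching, plate-edge effects,
pipetting covariance between wells of one replicate series. Tests passing
on these data therefore validate the machinery and its internal
consistency, not instrument-specific error structure.

## Inference: ABC-SMC

`abc_smc()` is a likelihood-free sequential sampler. Population 1 draws
from the prior and accepts all finite-distance particles; each later
population sets its threshold to the 0.3 quantile of the previous
population's distances (adaptive, robust across substrates), resamples
by weight, perturbs, and reweights with the standard prior-over-kernel
importance ratio. The default distance is the root-mean-square difference
of product concentrations over all design cells, each cell normalised by
the maximum of its observed concentration series; the fitting target is
the replicate mean. Identical seeds give bit-identical particle tables.

The default perturbation kernel is a multivariate normal whose
covariance is twice the weighted covariance of the previous population
(per model, on the internal scale — log10 for log-uniform parameters).
The component-wise uniform kernel (half-width 0.5 times the component
range) is kept as `kernel = "uniform"`, but on posteriors of this model
family it mixes poorly: the transport parameters are strongly correlated
(e.g. `vin` with `C` through the influx-saturation term), and an
axis-aligned kernel proposes almost orthogonally to such ridges, so the
acceptance rate collapses once the population begins to contract. The
covariance-adapted kernel follows the ridges and is therefore the
default.

Priors default to log-uniform over four orders of magnitude centred on
the supplied base values (`default_priors()`), with `C` uniform on
[10, 1000] molecules and `beta` clipped at its upper bound 1. Hill
coefficients, the inhibitor stoichiometry `h`, `alpha` and the known
enzyme/site concentrations are fixed, not inferred. The default free
sets follow an identifiability rule of one rate per binding equilibrium:
the product observable constrains site occupancies and net fluxes, not
the individual on/off rates, so `koff` and the regulatory-site kinetics
(`Ron`/`Roff`, `Ion`/`Ioff`) stay fixed while the site strengths `Xenh`
and `Yinh` are inferred. Widening the free set to all fifteen M9
parameters makes the acceptance region a needle no desk-scale particle
budget can find (no draw of 2000 from the full prior comes within six
times the noise floor of the data).

Population 1 can scout: with `n_init` larger than `n_particles` the
sampler simulates `n_init` prior draws and keeps the best-scoring
`n_particles` -- plain rejection ABC with an adaptive first threshold --
so later populations start from every basin the prior supports.

Model selection (`abc_smc_model_select()`) samples the model indicator
jointly with the parameters; the indicator is not perturbed between
populations, so a model's probability shrinks by repeated rejection and
the scheme terminates when one model reaches probability 1 (or a
population cap). The iterative ladder
(`iterative_selection_scheme()`) compares the four non-compartmental
models jointly (prior 1/4 each), advances the winner through pairwise
comparisons (prior 1/2) against M5…M9 in order of increasing complexity,
and finally re-tests the survivor against all other models.

`posterior_compare()` summarises two posteriors per parameter (weighted
median and central 90% interval) and scores the overlap of the two
intervals as intersection length over the shorter interval; overlap
below 0.05 is flagged as evidence for a difference, otherwise the
comparison is read as "no evidence for differences".

## Sensitivity, chamber occupancy, capacity

`rate_limiting_analysis()` re-simulates with one reaction class scaled —
gate affinity (`kon` up, or `koff` down as an option), influx (`vin`),
hydrolysis (`kp`), translocation (`tau`), efflux (`vout`), or gate size
(`vin` and `vout` jointly) — and reports the fold-change of product at
`t_end` (canonical probe: 320 uM substrate, 60 min). The perturbation
factor defaults to 2: small enough to read as a local sensitivity, large
enough to dominate solver noise; it is recorded in the output. Over a
posterior, both weighted means and medians of the fold-change
distribution are reported, and the result is invariant to particle
order.

`chamber_occupancy()` reports molecules inside per proteasome
(`(S+P+G2S+G2P+EregS+EregP)/E0`, bounded by `C` through the influx
saturation), the product fraction of the inner load (`NA` while the
chamber is empty), and the time at which the occupancy first reaches 90%
of its final value. `capacity_consistency()` compares per-substrate
capacity estimates with inverse molecular volumes as pairwise ratios;
the two-decimal convenience column uses decimal round-half-even, so
e.g. 249/200 = 1.245 reports as 1.24.

## The two-cleavage-site polypeptide

A hypothetical 23-residue substrate with cleavage sites after residues 8
and 15 (defaults, configurable) yields the six-species roster S, A, BC,
AB, B, C. Every species is transported with its own gate/transport
parameters but shares the chamber capacity; cleavable species (S at both
sites, BC at site 2, AB at site 1) are hydrolysed with a simplified
shared active-site law — the two-site-modifier denominator with
species-summed occupancies
(`x = 1 + sum(a) + sum(b) + sum(a)*sum(b)/alpha`), cleavable species
contributing catalytic (`KaS`) and inhibitory (`KiS`) occupancy, terminal
products inhibitory occupancy via `KiP`. Per-site relative catalytic
rates allow silencing one site, which reduces the model to
single-cleavage behaviour. The enhancer/inhibitor regulatory sites are
omitted in this extension: the roster's parameterisation covers
transport and the simplified active site, which is what the
cleavage-site-usage question needs; this keeps the sampled parameter
space interpretable.

`cleavage_site_usage()` reports per-site instantaneous cleavage flux,
cumulative counts, the share of total cleavage, and a per-site
normalised usage (flux relative to its first positive value) — the model
analogue of the experimental site-specific cleavage strength. Because
the share normalisation is constrained to sum to one, the *classifier*
(`classify_usage_behavior()`) works on the per-site normalised measure,
fitting a least-squares slope per site with a 5% dead band and labelling
the pattern `flat`, `both_decrease`, `both_increase` or `divergent`.
Both normalisations are exposed because the exact normalisation of the
published usage plots is not defined in the available material.

`search_behaviors()` samples the per-fragment transport parameters from
a log-uniform prior (default two orders of magnitude around the fragment
set's values; the attainability analyses use three) and classifies each
run. All four labels are reachable: retention of a cleavable fragment
inside the chamber feeds its site's flux while crowding the capacity
term throttles fresh substrate influx, so usage drifts over time even
with product re-entry disabled — transport properties alone explain
changing cleavage-site usage, without substrate depletion or re-entry.
The `divergent` class lives on the boundary between globally increasing
and decreasing activity and is correspondingly rare (a few per thousand
draws under the default prior).

## Recovery experiments

Three self-calibration studies ship as functions and back the automated
checks. `selection_experiment_stage1()` simulates Michaelis-Menten data
and runs the joint four-model comparison (prior 1/4 each): the richer
rate laws gain no support, M1 wins. `selection_experiment_m9_vs_m5()`
simulates the full model with a strong internal enhancer and strong
external inhibition (`Xenh = 10`, `Yinh = 12`) and compares it pairwise
against the regulation-free transport model: the simpler model is
favoured in early populations (parsimony) until the threshold crosses
its misfit floor, after which its probability collapses to zero. The
regulation must be strong for this collapse to happen at desk scale --
with weak inhibition the simpler model's floor sits close to the
achievable threshold path and the joint sampler cannot discriminate
within a small particle budget.

`recovery_experiment_m9()` fits M9 to its own noisy six-concentration
dataset. Its generating truth runs in the *capacity-limited* regime
(efflux reduced so the chamber reaches ~90% of its capacity within the
experiment): a container's size is only measurable when it fills, and
with a slowly-filling truth the capacity marginal stays ~±40% wide even
when the sampler is pushed below the data's noise floor. In the
capacity-limited design the time of the velocity bend pins the capacity
to roughly ±10% across seeds, while `vin` is recovered tightly and `kp`
(far from rate-limiting in this regime) is honestly broad.

## Problem sizes

The automated checks run at desk scale, chosen to finish on one CPU
while keeping each property meaningful: conservation on 20 random
parameter/state fixtures per model over 360 minutes; model-selection
recovery with 120–150 particles on three-concentration designs;
parameter recovery for M9 with 200 particles on the six-concentration
design (5% noise); behaviour search over up to 10^4 prior draws. Full
analyses of the same kind on real data would use more particles and
populations; nothing in the implementation is specific to the reduced
sizes.

## Known limitations

* Deterministic ODEs only; no stochastic simulation. At nanomolar enzyme
  and hundreds of molecules per proteasome the mean-field description is
  the intended regime.
* The capacity saturation is heuristic (`tanh` with a 1 uM implicit
  scale), not derived from a packing model; `C` is a scalar.
* The feedback forms of M3/M4 and the co-substrate active-site sharing
  are the package's own closures of qualitatively stated mechanisms.
* ABC-SMC model probabilities depend on prior ranges; the shipped
  defaults (four orders of magnitude) encode weak information, and the
  parsimony behaviour of the selection scheme should be read relative to
  them.
* The polypeptide extension tracks one hypothetical substrate with two
  sites; it is a mechanism probe, not a sequence-level cleavage
  predictor.
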