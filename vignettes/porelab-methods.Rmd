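---
title: "porelab: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{porelab: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(porelab)
```

porelab implements the computational chain used when an engineered protein
nanopore (here, aerolysin-type pores) is characterised both by biased
molecular-dynamics simulation and by single-channel recording. This vignette
explains the underlying models, the tunable parameters and their defaults,
what the synthetic generators do and do not emulate, and the numerical
choices made where the design was genuinely open. It states no empirical
result that the test suite and `scripts/acceptance.R` do not themselves
compute.

## Coordinate conventions

Trajectories carry wrapped coordinates in Å, a periodic box (Lx, Ly, Lz)
and the applied bias in mV (signed; positive bias drives anions from the
cap/cis side toward the stem/trans side). The pore axis is the vertical
line through the protein center of mass; z is measured from the lowest
protein atom ("pore bottom = 0 Å"). Readers never re-reference coordinates;
the geometry operations apply the convention.

## Slice/ring radius profile

For every 1 Å layer along the axis and every selected frame, the local
cavity radius is seeded at 1 Å and grown in 0.5 Å annuli: the annulus
(r, r + 0.5] is accepted while the ratio of water to non-water atoms inside
it exceeds 0.25. Two readings of that ratio are possible and both are
implemented (`ratioMode`): water/(non-water), the default and the literal
reading, and water/(all atoms). On densely watered phantoms they coincide;
the flag exists because on real systems the distinction can matter near a
wall.

Tie rules (`ratioMode = "w_over_p"`): an annulus with water but no
non-water atoms passes (ratio is effectively infinite); an entirely empty
annulus stops the iteration — without this rule the radius would walk
through vacuum outside the protein until the hard ceiling, which is set at
min(Lx, Ly)/2. Layers whose very first annulus is empty are flagged in the
profile metadata rather than repaired.

Because the radius moves on a 0.5 Å grid starting at 1 Å, a single-frame
estimate is accurate to one increment by construction; the test suite
asserts |estimate − truth| ≤ 0.5 Å on cylinder phantoms of radius 3–10 Å
and that the estimate never leaves the grid.

Frame selection defaults to discarding the first quarter of the trajectory
(equilibration) and striding the remainder down to at most 16 frames, which
mirrors how pore diameters are usually averaged over the tail of a
simulation; the profile records mean ± sd over the selected frames. The
sensing-region landmarks default to z = 88.5 (R282), 73.5 (R220), 22.5
(K238) and 10.5 Å (K242) above the pore bottom and are configurable;
`diameterAtRegion()` averages 2·radius over a 3 Å window.

## Charge-displacement currents

The instantaneous current between stored frames is
I = (e / (Δt · L_z)) Σᵢ qᵢ Δzᵢ, summed over ions, with Δzᵢ unwrapped by
minimum image in z (valid while no ion drifts more than L_z/2 per stored
frame; the drift generator checks this before producing data). One
elementary charge per picosecond is 1.602176634 × 10⁵ pA. Per-species sums
give I_K and I_Cl and the total is defined as their sum, so the additivity
invariant holds exactly rather than approximately.

The uncertainty is the standard deviation over 5 equal blocks of the
instantaneous series. Five blocks is a pragmatic stand-in: published
mean ± sd values of simulated currents rarely state the averaging scheme,
and the estimator only has to be honest about its own dispersion, which the
stochastic-phantom tests check (recovery within 3 block-SEs). The analysis
region defaults to the full periodic box, matching periodic
charge-displacement accounting; a z-window option restricts to the membrane
span when desired. Note that absolute simulated currents in this field are
known to overestimate experiment by tens of percent for force-field
reasons, so no absolute-scale agreement with experimental conductance is
asserted anywhere; all current tests are against the package's own
closed-form oracles.

## Ion densities

Densities are computed per 1 Å layer as count/(π r(z)² Δz), counting only
particles within the local cavity radius, sampling frames every 100 ps by
default and reporting mean ± sd across sampled frames. A uniform ideal
solution therefore gives a density independent of the radius profile used
— a volume-normalisation identity the tests exercise — and 1 mol/L
corresponds to 6.022 × 10⁻⁴ particles/Å³.

## Event detection and statistics

Detection rectifies the trace polarity by the sign of the median, so
positive- and negative-bias recordings share one code path. The open-pore
level I0 and baseline sd come from a Gaussian fit of the dominant
histogram mode of the baseline-side samples (robust initialisation by
median/MAD); an event opens when the magnitude drops below I0 − k·σ and
closes on re-crossing. Defaults k = 4 and minimum dwell 0.05 ms (5 samples
at the conventional 100 kHz acquisition) are operational choices — vendor
analysis software hides its own — and are exposed as parameters. Per-event
quantities are the dwell, the mean blockade current and I_res/I0.

Dwell fitting defaults to the MLE for a left-truncated exponential: because
the exponential is memoryless, discarding events shorter than the dead
time shifts the mean by exactly the dead time, so tau = mean(dwell) −
min_dwell. The CI is a seeded percentile bootstrap (1000 resamples). The
histogram method fits A·exp(−t/τ) to binned counts by nonlinear least
squares, matching the traditional "falling exponential" presentation; its
CI uses the nls parameter standard error, since a bootstrap of 1000 nls
refits would be disproportionate for a presentation-oriented method. Both
agree within 10 % on clean exponential samples of n ≥ 1000 (tested).

Capture rate: inter-event intervals (start of event i+1 minus end of event
i) are fitted as an exponential (MLE = mean), giving τ_on and f = 1/τ_on
exactly; the CI is the exact chi-square interval for an exponential mean.

The translocation-vs-bumping classifier regresses ln τ on |V| across at
least three voltages spanning at least 40 mV. A 95 % slope CI entirely
below zero ⇒ translocation (dwell shortens exponentially with driving
force); a CI containing zero with relative τ spread below 25 % ⇒ no
translocation (bumping); anything else ⇒ indeterminate. The 25 % spread
tolerance encodes "dwell unvaried across voltages" while allowing ordinary
estimation noise at a thousand events per voltage.

## Synthetic generators: what they emulate, what they do not

`genChannelStructure()` builds pseudo-atom walls on the surface r(z)
(piecewise-linear knots) and fills the interior with uniformly distributed
"water" particles. The default water number density, 4.0 Å⁻³, is a
sampling resolution, not hydration physics: the radius algorithm probes
0.5 Å annuli of 1 Å layers (volumes of a few Å³), and the phantom must
populate each annulus with high probability for the geometric ground truth
to be meaningful (mean occupancy ≥ ~15 in the smallest annulus at this
density). Liquid water at 0.033 molecules/Å³ would leave most annuli empty
and the empty-annulus stop rule would fire everywhere; on real MD output
the algorithm sees all water atoms across many frames instead.

`genIonTrajectory()` is 1-D drift–diffusion along z (Euler–Maruyama, one
step per stored frame) with lateral diffusion reflected at the wall and
periodic wrap in z. It deliberately preserves exactly the observables the
current and density estimators consume — axial displacement of charge and
layer occupancy — and nothing else: no protein flexibility, no
electrostatic self-consistency, no water polarisation, no attempt to
reproduce absolute conductance from physics. With D = 0 the motion is pure
drift and the estimator must match the closed form
I_s = n_s q_s² μ E e/L_z to floating-point accuracy, which is the sharpest
test in the suite. Mobility may be given per species, e.g. a 3:1 Cl:K
mobility ratio yields an anion selectivity ratio of 0.75 in closed form.

`genCurrentTrace()` superimposes Poisson-arriving rectangular blockades
with exponential dwells on Gaussian baseline noise. Overlapping events are
merged and flagged, because a threshold detector cannot distinguish
overlapped events; consequently the observable dwell distribution is the
M/G/∞ busy period with mean (e^{λτ} − 1)/λ rather than τ. At the dilution
used in the recovery tests (occupancy 5 %) the difference is ~2.5 %, and
the recovery tests compare detection + fit against the realized
ground-truth event table, which is the honest oracle for the observable.
Real recordings differ in ways the generator does not model: 1/f and
instrument noise, filter rise times, sub-states within events, baseline
drift. Passing the synthetic tests therefore demonstrates correctness of
the estimators, not robustness to every artefact of real data.

`genVoltageSeries()` draws per-voltage dwell samples with means either
constant (bumping) or proportional to exp(−|V|/decay) with a 40 mV decay
constant by default, the scale on which recorded dwell–voltage curves in
this system fall by ~e² over an 80–160 mV sweep.

## Problem sizes used by tests and the acceptance script

Chosen as the package's own trade-off between statistical sharpness and
desk-scale runtime: cylinder phantoms of radius 3–10 Å and 40 Å length
(single static frame); drift phantoms with 50 ions/species, D = 0.02
Å²/ps, 10 ps frames — 2 000 frames per seed in the test suite, 50 000 per
seed (5 seeds) in the acceptance script, where the diffusion-noise
closed form puts the pooled standard error near 5 pA on a 100 pA signal;
event recovery on a 200 s synthetic trace at 100 kHz with 25 events/s
(≈5 000 events, tau 2 ms, 50 % depth, noise 2 % of I0); capture-rate
recovery on a 40 s trace at 74.3 events/s; classifier accuracy over 10
series per mode, 5 voltages, 1 000 events per voltage.

## Numerical choices and degenerate inputs

Text formats carry 6 significant digits (PDB coordinates 3 decimals by
format); round-trips are asserted lossless to that precision. Readers
reject rather than repair: missing metadata, non-uniform sampling (>1 ppm),
inconsistent topology, duplicate atom ids and malformed coordinate fields
are errors naming the offending line where possible. Degenerate analysis
inputs (constant histograms, single-frame RMSF, all-dwell-at-dead-time
fits, zero total current in the selectivity ratio) raise flagged errors or
return explicit degeneracy flags instead of silent values. Ties at the
profile minimum are resolved by the midpoint of the tied layers when a
waist position is extracted.

## Known limitations

- The radius algorithm assumes a straight vertical axis; bent pores are
  out of scope.
- Event segmentation is single-level thresholding; multi-level events and
  CUSUM-style deconvolution are out of scope.
- The drift–diffusion generator is not an electrostatics solver; it cannot
  (and is not meant to) predict absolute conductance or its mutant
  dependence from structure.
- RMSF uses equal-weight superposition over pseudo-atoms; mass weighting
  would matter only for heterogeneous real topologies.
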