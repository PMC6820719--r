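# porelab

Analysis toolkit for engineered protein nanopores (aerolysin-type pore-forming
toxins) that are studied by combining biased molecular-dynamics simulation
with single-channel electrophysiology. The package covers the quantitative
chain that links the two worlds:

- **Pore geometry from trajectories** — the slice/ring local radius profile:
  the channel volume is sliced into 1 Å layers along the pore axis (the
  protein center of mass, oriented along the membrane normal, z = 0 at the
  pore bottom); in each layer the local radius starts at 1 Å and grows in
  0.5 Å annuli while the water/non-water atom count ratio in the added
  annulus exceeds 25 %. Mean diameters at the sensing regions (R282, R220 at
  the cap; K238, K242 at the stem) use a 3 Å window. Per-residue RMSF is
  computed after optimal rigid superposition of each frame.
- **Ion transport** — the charge-displacement current estimator
  `I = (e / Δt·L_z) Σᵢ qᵢ Δzᵢ` with minimum-image unwrapping in z, split into
  I_K and I_Cl (I_total = I_K + I_Cl exactly), block-averaged uncertainty;
  z-resolved ion densities inside the cavity defined by the radius profile;
  Gaussian fits of current histograms; the anion selectivity ratio
  |I_Cl|/(|I_Cl|+|I_K|).
- **Event analysis for recordings** — threshold detection of blockade events
  (baseline from the dominant Gaussian mode, event when the current drops
  below I0 − k·σ), falling-exponential dwell-time fits τ (MLE with dead-time
  correction, and histogram fit), capture frequency f = 1/τ_on from
  inter-event intervals, blockade ratio I_res/I0, and a
  translocation-vs-bumping classifier based on whether ln τ decreases
  significantly with |V|.
- **Comparative statistics** — percent change `100·(mut − wt)/wt`, fold
  change `mut/wt`, per-base translocation time, and the diameter–dwell
  correlation (Pearson on a chosen transform plus Spearman).
- **Synthetic generators with closed-form ground truth** — pseudo-atom
  channels with prescribed radius profiles filled with water; 1-D
  drift–diffusion ions under a uniform axial field (expected current
  `I_s = n_s q_s² μ E e / L_z`); two-state current traces with Poisson
  arrivals, exponential dwells and Gaussian noise. Every analysis stage is
  tested against these oracles.

## Worked example

```r
library(porelab)

## a 6 A cylindrical channel phantom, walls + water, one static frame
chan <- channelSpec(data.frame(z = c(0, 40), r = c(6, 6)))
ch   <- genChannelStructure(chan, seed = 1)
prof <- sliceRadiusProfile(ch$trajectory)
range(layers(prof)$radius_mean)
#> [1] 6 6          # every 1 A layer recovers the 6 A radius exactly

## drift-diffusion ions; deterministic drift matches the closed form
spec <- driftDiffusionSpec(nIonsPerSpecies = 50, diffusionCoefficient = 0,
                           mobility = 5e-4, field = 0.5,
                           duration = 1000, frameInterval = 10, seed = 1)
est <- computeSpeciesCurrents(genIonTrajectory(spec, chan))
est
#> CurrentEstimate @ +20 mV: I_total = 100.1 +/- 2.4e-13 pA (I_K = 50.07, I_Cl = 50.07; 101 frames)
analyticDriftCurrent(spec, chan)[["I_total"]]
#> [1] 100.136      # estimator and closed form agree to ~1e-14 relative

## a synthetic recording: 61.5 pA open pore, 50% blockades, tau = 2 ms
g  <- genCurrentTrace(traceSpec(openCurrent = 61.5, noiseSd = 1.23,
                                eventRate = 10, dwellMean = 2e-3,
                                blockadeDepth = 0.5, duration = 10, seed = 4))
ev <- detectEvents(g$trace, kSigma = 5)
fitDwellExponential(ev)
#> DwellFit (mle): tau = 0.001933 s [0.001547, 0.002387], n = 88

## the comparative arithmetic used for mutant-vs-wt reporting
renderChange(percentChange(48.4, 61.5))   # open-pore current, +100 mV
#> [1] "decreased by 21%"
perBaseTime(1815.0, 4)                    # ms per base for a 4-mer
#> [1] 453.75
```

The numbers above are what the code prints: the cylinder phantom radius is
recovered exactly on the 0.5 Å grid, the drift-only current matches the
analytic value to floating-point accuracy, the dwell fit recovers the 2 ms
time constant from a short trace within its confidence interval, and the
percent-change renderer reproduces the conventional "decreased by 21 %"
phrasing from the raw currents.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/porelab.R` (subcommands `pore-profile`, `ion-current`,
`density`, `events`, `report`).

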