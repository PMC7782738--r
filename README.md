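# poregate

Structural and trajectory analysis of voltage-gated ion channels,
centred on one question: is the intracellular activation gate open,
hydrated and conductive — and how has a gating-modifier toxin moved the
voltage sensor?

A constriction at the bundle crossing of the four S6 helices can block
conduction by *dewetting* rather than steric occlusion alone (a
hydrophobic gate), so geometry and hydration must be measured together.
`poregate` provides, for structures (PDB/mmCIF) and MD ensembles
(multi-model PDB, DCD):

- **Canonical pore frame** — per-frame Kabsch superposition on the
  pore-helix Cα atoms, xy-centred on the pore module and z-centred on
  the selectivity-filter (DEKA) Cα centre of mass, so the pore axis is
  z and z = 0 is the filter.
- **Hydration** — axial water profiles in an 8.5 Å cylinder normalized
  to the solvent slice; gate water-count distributions
  (−28 Å < z < −15 Å) with across-replica SEM; wetted/dewetted
  classification (N ≥ 10); ion permeation event detection with
  hysteresis.
- **Gate geometry** — opposing S6-tail distances d₁ (DI–DIII) and d₂
  (DII–DIV) from projected Cα centres of mass; their free-energy
  surface F = −k_B T ln(P/P_max); van der Waals pore-diameter profiles
  (Bondi radii, configurable).
- **Voltage-sensor trapping metrics** — superposed selection RMSD with
  paired-residue accounting; per-residue Cα displacement; gating-charge
  ion-pair census (N–O ≤ 4.0 Å, ENC/INC classification); α vs 3₁₀
  helix assignment; Shrake–Rupley buried interface area with a
  deterministic point set.
- **Functional fits** — Hill concentration–response
  (y = bottom + (top − bottom)/(1 + (EC₅₀/x)^n)) and single-exponential
  kinetics, via Levenberg–Marquardt with deterministic initialisation.
- **Synthetic data** — seeded generators for a four-fold pseudo-channel,
  two-state (dewetted mean 4 / wetted mean 12 waters) Markov gating
  trajectories with bulk water and reflecting ions at 150 mM, two-basin
  gate-distance samples, and dose–response/kinetics datasets, all with
  ground truth returned for validation.

## Worked example

```r
library(poregate)

## two-state gating ensemble with known ground truth
sim <- simulateGatingTrajectory(nFrames = 1200, nReplicas = 6, seed = 1)
counts <- unlist(lapply(sim$ensembles, gateWaterCount))
states <- unlist(sim$states)
mean(counts[states == 0])   # 3.95  -- dewetted-state gate waters
mean(counts[states == 1])   # 11.94 -- wetted-state gate waters
sum(sapply(sim$ensembles, function(e)
  nrow(detectPermeation(e, sim$ionSelection))))   # 0 permeation events

## static gate geometry of the synthetic toxin-bound state model
toxin <- canonicalizeStructure(makeSyntheticGateModel("toxin"),
                               toyCanonicalSpec())
gateDistances(toxin)
#> GateDistanceSeries (replica 1): 1 frames, d1 = 16.60 A, d2 = 16.80 A (means)
gateDiameter(toxin)$diameter
#> [1] 6.6

## concentration-response fit
dose <- simulateDoseResponse(ec50 = 11.4, noiseSd = 0.03, seed = 1)
fitHill(dose)
#> FitResult [hill]: n = 4, RSS = 0.001048
#>   ec50 = 11.7678 +/- 1.898
#>   hillN = 0.981608 +/- 0.1476
#>   top = 1.00016 +/- 0.03621
#>   bottom = 0 (fixed)
```

The gate-distance numbers are the toxin-bound state geometry encoded by
the stand-in generator ((d₁, d₂) = (16.6, 16.8) Å; apo state
(16.1, 16.6) Å with a gate ~1 Å narrower), measured here by the full
canonicalize-project-measure pipeline. The EC₅₀ estimate recovers the
generating value within its standard error.

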