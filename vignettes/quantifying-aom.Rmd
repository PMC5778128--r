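---
title: "Quantifying anaerobic methane oxidation in submarine permafrost"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying anaerobic methane oxidation in submarine permafrost}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(permafrostAOM)
```

## The problem

Submarine permafrost on the Arctic shelves holds large amounts of methane,
trapped during freezing or produced in situ. As the permafrost thaws from
above (warm saline bottom water) and below (geothermal heat), that methane
can be released — unless anaerobic methanotrophic communities consume it on
the way up. Anaerobic oxidation of methane (AOM) leaves a fingerprint in the
residual methane pool: oxidation discriminates against ^13^C, so the methane
that survives becomes isotopically heavier (less negative δ^13^C-CH~4~).
This package turns depth-resolved pore-water geochemistry of permafrost
cores into a quantitative estimate of how much methane was oxidized, and of
what that consumption amounts to when upscaled to the pan-Arctic submarine
permafrost area.

## The isotope mass balance

The core statistic is the open-system carbon isotope mass balance

$$f_{ox} = \frac{\delta_o - \delta_p}{1000\,(\alpha_{ox} - \alpha_{trans})}$$

where $\delta_o$ is the δ^13^C-CH~4~ of an *oxidized* layer, $\delta_p$ that
of a *source* layer below it (methane as produced or trapped), $\alpha_{ox}$
the kinetic fractionation factor of AOM and $\alpha_{trans}$ that of
diffusive transport. $f_{ox}$ is the fraction of methane that was oxidized.
The model assumes an open system at steady state in which the isotope shift
between source and oxidized horizons is generated only by oxidation and
diffusion; it deliberately excludes closed-system Rayleigh distillation,
which would attribute larger shifts to smaller oxidized fractions.

Three choices the analysis makes explicit:

* **Zonation thresholds.** A horizon counts as *oxidized* at
  δ^13^C ≥ −37 ‰ VPDB and as *source* at δ^13^C ≤ −52 ‰; between the two it
  is *intermediate*, without a measurement *unconstrained*. The bounds are
  inclusive so that the endmember values of a core's measured range — which
  are exactly what enters the mass balance — qualify. Both thresholds are
  arguments to every function that uses them.
* **The shift that is used.** `maxIsotopeShift()` takes the *largest*
  $\delta_o - \delta_p$ over all pairs in which the source lies below the
  oxidized layer ("subjacent": oxidized methane sits above the pool it came
  from). Ties are broken towards the smallest depth separation and then the
  shallowest oxidized layer — the most local, least transport-confounded
  signal. Computing the maximum per core (rather than per zone) is one of
  several defensible conventions; it is the one implemented, and it makes
  the estimate an upper envelope of the per-horizon shifts.
* **Scenario screening.** Because $\alpha_{ox}$ is not known in situ, the
  model is evaluated over a registry of six literature scenarios (all with
  $\alpha_{trans} = 1.001$, the soil diffusion value): marine
  sulfate-dependent AOM at its enrichment-culture bounds (1.009, 1.039),
  freshwater sulfate-dependent AOM (1.030), iron- (1.031) and
  nitrate-dependent AOM (1.032), and AOM by extracellular electron transfer
  (1.0174). A scenario whose raw $f_{ox}$ falls outside $[0, \mathrm{cap}]$
  (cap defaults to 1) is physically impossible for the observed shift and is
  flagged `retained = FALSE` rather than dropped silently; negative raw
  fractions (inverted profiles, degraded data) are likewise flagged, never
  errors. With a 35 ‰ shift, for example, only $\alpha_{ox} = 1.039$ yields
  $f_{ox} \le 1$:

```{r}
evaluateScenarios(IsotopeShift(deltaO = -37, deltaP = -72,
                               depthO = 50, depthP = 52))
```

## SMTZ detection

The sulfate–methane transition zone is the interval where downward-diffusing
sulfate and upward-diffusing methane meet. Field studies localize it by
inspection; `detectSmtz()` is a reproducible stand-in: each profile is
normalized to its own maximum, the profiles are treated as linear between
measured depths, and the detector reports the bracketing pair of measured
depths around the shallowest crossing at which sulfate decreases, methane
increases, and sulfate at the interval top is at least `sulfateFloor`
(default 1 mM — below that, opposing gradients are noise, not a transition
zone). The returned interval is therefore never wider than one sampling
step.

## The release and oxidation budget

Methane release from degrading permafrost is modelled as the pore-water
methane inventory liberated by a vertical degradation rate, upscaled to the
submarine permafrost area:

$$R \;[\mathrm{mol\,yr^{-1}}] = v \;[\mathrm{m\,yr^{-1}}] \times A \;[\mathrm{m^2}]
  \times \phi \times C \;[\mathrm{mol\,m^{-3}\,porewater}]$$

and AOM consumption as $R \times f_{ox} \times 12.011\,\mathrm{g\,mol^{-1}} /
10^{12}\,\mathrm{g\,Tg^{-1}}$, in Tg C yr^−1^ (12.011 g mol^−1^ is the molar
mass of the carbon atom in CH~4~, since the budget is a carbon budget).
Defaults: degradation rates of 0.006 m yr^−1^ (C2-like core) and
0.053 m yr^−1^ (BK2-like core), derived in the source literature from
coastal erosion rates and the permafrost table depth and taken here as
direct inputs (no formula is re-derived); area $A = 3 \times 10^{12}$ m²
(3 million km² of submarine permafrost). The pore-water volume fraction
$\phi$ is the one genuinely unconstrained factor: concentrations are
measured per pore-water volume, but the sediment water content used for
upscaling is rarely reported. It therefore defaults to 0.4, is a mandatory
explicit slot of `BudgetInputs`, and is echoed in every report's assumption
ledger — a reader must be able to see it before believing a Tg number.
`budgetGrid()` evaluates the full 3 × 2 grid of concentration level
(lowest/average/highest of the ice-bonded section) by fraction-oxidized
bound, whose corners bracket the budget.

## Headspace and lipid calculators

`dissolvedCH4Concentration()` implements the standard headspace
equilibration partition for frozen sediment immersed in saturated NaCl
brine: ideal-gas moles in the headspace ($xPV_{hs}/RT$) plus
Bunsen-solubility moles in the brine
($\beta V_{brine} (xP/P_0) / V_{m,STP}$), reported per litre pore water
(wet mass × water content at 1.0 g mL^−1^). The Bunsen coefficient defaults
to 0.002 — salting-out in saturated brine makes methane solubility nearly
negligible, which is why the brine is used — but it is a parameter, echoed
in batch output, not an asserted literature constant. Constants:
R = 8.314 J mol^−1^ K^−1^, V~m,STP~ = 22.414 L mol^−1^, P₀ = 101.325 kPa;
no non-ideal gas or temperature-dependent solubility corrections are
applied.

The lipid module computes the BIT index (branched vs. isoprenoid
tetraethers; ≈1 means terrestrial organic matter), the methane index
(isoprenoid GDGT-1..3 against crenarchaeol and its isomer; →1 where AOM
archaea dominate the tetraether pool, as at an SMTZ) and the plain
archaeal:bacterial ether-lipid quotient. Which compounds make up the
archaeal and bacterial sums varies between laboratories, so the sums are
caller-supplied.

## The synthetic-core generator

`generateCore()` builds profiles with *known* ground truth by running the
isotope model forwards: pick a source signature $\delta_p$, a true fraction
$f_{ox}$ and a generating scenario, and place the implied
$\delta_o = \delta_p + 1000(\alpha_{ox}-\alpha_{trans})f_{ox}$ at the
oxidized crest. Two presets emulate the study conditions the package is
built around:

* `c2_like` — 118 horizons to 58.5 mbsf at 0.5 m spacing, ice-bonded below
  34.5 m, SMTZ at 50–53 mbsf, low background methane (12 µM) with a 990 µM
  Gaussian peak at 52 mbsf (ice-bonded mean ≈ 50 µM), sulfate declining from
  a 24 mM surface plateau, $\delta_p = -72$ ‰ and $f_{ox} = 35/38$ under the
  marine high scenario so the noiseless isotope extremes are −72 and −37 ‰.
* `bk2_like` — 80 horizons to 47.4 mbsf at 0.6 m spacing, thaw front at
  24.6 m with the SMTZ at the permafrost table (24.0–24.6 mbsf), frozen
  section methane 384 µM (8 × the C2 average), sulfate 6 mM above the front,
  $\delta_p = -71$ ‰ and complete oxidation ($f_{ox}=1$, $\delta_o=-33$ ‰)
  above the thaw front.

Profile shapes are deliberate stand-ins: logistic sulfate decline and
methane rise centred on the SMTZ midpoint (so their max-normalized curves
cross at the midpoint when neither profile has a dominating peak), a
Gaussian methane peak, and linear δ^13^C ramps of 2.5 ‰ m^−1^ towards the
oxidized crest and 3 ‰ m^−1^ towards the source trough. The ramps matter
statistically: they isolate the extreme horizons by ~1.5–1.8 ‰ from their
neighbours, so under measurement noise the maximum-shift estimator almost
always picks the true crest/trough pair and stays essentially unbiased —
with flat plateaus instead of ramps, the maximum of many equal-mean noisy
values would be systematically inflated. Noise is additive Gaussian on
δ^13^C (default 0.5 ‰, a typical IRMS replicate precision) and
multiplicative log-normal on concentrations (default 5 %, keeping them
positive); a single RNG stream is fully determined by the integer seed,
which is recorded in the truth object.

What the generator does **not** emulate: non-monotone sulfate profiles
(the real C2 core has a deep local sulfate maximum; the generator's
monotone logistic places the opposing-gradient structure at the configured
SMTZ instead), electron-acceptor fluctuations in partially thawed layers,
transport-driven smoothing of δ^13^C, and any microbial community
structure. Passing the recovery tests therefore shows that the estimator
chain is correct and well-calibrated *for profiles whose extremes are real
signal*, not that field profiles satisfy that assumption.

## Numerical and design choices

* Duplicate depths are rejected, not averaged — replicate handling is an
  upstream concern; row order is restored by sorting, so permuting input
  rows never changes a result.
* The maximum-shift search is exact (all ordered pairs), with the
  deterministic tie-break above; profiles of tens to low hundreds of
  horizons are far below any performance concern.
* `evaluateScenarios()` reports both the raw fraction (which may exceed 1
  or be negative) and the value capped to [0, 1]; printed "100 %" results
  correspond to the cap, and the retention rule uses the raw value only.
* Year-length conversions, where they arise, use 365.25 days; carbon molar
  mass is 12.011 g mol^−1^.
* The parameter-recovery simulation used in the test suite runs 200
  replicates of the `bk2_like` preset with 1 ‰ isotope noise — small enough
  to run in seconds, large enough that the Monte-Carlo error on the mean
  estimated fraction (~0.003) is well below the 0.02 acceptance band.

## Known limitations

The per-core oxidized-fraction ranges and Tg-budgets published for the real
study cores rest on per-sample isotope pairs, concentrations and water
contents that were never published; they cannot be regenerated from the
printed extremes and the six α values alone, and this package does not
attempt to — it reports whatever the supplied profile yields, with every
assumption echoed. The isotope mass balance is an open-system model; where
transport is advective or the system closed, the estimates are biased in
ways the model cannot see. SMTZ detection assumes a single transition; cores
with stacked SMTZs return only the shallowest.
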