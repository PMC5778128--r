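# permafrostAOM

Quantifying anaerobic oxidation of methane (AOM) in thawing submarine
permafrost from pore-water geochemistry.

Submarine permafrost on the Arctic shelves is a potentially large methane
source, but anaerobic methanotrophic communities can consume much of the
methane before it escapes. Oxidation enriches the residual methane in
^13C, so depth profiles of δ¹³C-CH₄ record how much was consumed. This
package implements the full quantification chain for geochemists working
with permafrost (or other subsurface) cores:

1. **Zonation** — classify horizons into *oxidized* (δ¹³C ≥ −37 ‰ VPDB),
   *source* (δ¹³C ≤ −52 ‰), *intermediate* and *unconstrained* layers, and
   locate the sulfate–methane transition zone (SMTZ) from opposing
   sulfate/methane gradients.
2. **Isotope mass balance** — extract the maximal isotope shift
   δ_o − δ_p between an oxidized layer and a subjacent source layer and
   convert it to the fraction of methane oxidized under the open-system
   model

   f_ox = (δ_o − δ_p) / (1000 · (α_ox − α_trans)),

   evaluated over a registry of six literature fractionation scenarios
   (α_ox ∈ {1.009, 1.0174, 1.030, 1.031, 1.032, 1.039}, α_trans = 1.001).
   Scenarios implying f_ox > 1 (or < 0) are physically impossible for the
   observed shift and are flagged, not silently dropped.
3. **Budget** — propagate the retained fractions through a
   permafrost-degradation methane-release model (degradation rate × area ×
   pore-water fraction × concentration) upscaled to the 3 million km² of
   submarine permafrost, in mol CH₄ yr⁻¹ and Tg C yr⁻¹.
4. **Auxiliaries** — a headspace-equilibration calculator for dissolved
   methane per litre pore water, GDGT lipid biomarker indices (BIT, methane
   index, archaeal:bacterial ether ratio), and a seeded synthetic-core
   generator whose profiles have known ground truth (the exact inverse of
   the estimator), so the whole chain is testable without field data.

See the methods vignette (`vignettes/quantifying-aom.Rmd`) for the model
assumptions, parameter choices and limitations.

## Worked example

Simulate a core emulating a deeply inundated shelf core (118 horizons,
ice-bonded below 34.5 mbsf, a 990 µM methane peak at 52 mbsf, realistic
measurement noise), then run the full analysis with a budget:

```r
library(permafrostAOM)

sim <- generateCore(syntheticCoreParams("c2_like", seed = 42))
rep <- runAnalysis(sim$profile,
                   budget = BudgetInputs(0.006, 0.0002, 0.050, 0.99,
                                         fOxMin = 0, fOxMax = 1))
rep
#> AomReport for core 'synthetic-c2_like'
#>   zonation: intermediate=104, oxidized=1, source=13
#>   SMTZ interval 51.00-51.50 mbsf (SO4 18.30 mM at top, CH4 590.3 uM at bottom)
#>   IsotopeShift: 34.36 permil (delta_o = -36.40 at 50.00 mbsf, delta_p = -70.76 at 58.00 mbsf)
#>   scenarios: 1 retained / 5 rejected; retained f_ox 0.904-0.904
#>   budget: oxidized carbon 1.564e-05-0.07741 Tg C yr-1
```

Reading the output: the detected SMTZ brackets the thaw-driven
sulfate/methane crossing at ~51 mbsf; the largest isotope shift is 34.4 ‰
(an oxidized horizon at −36.4 ‰ above a source horizon at −70.8 ‰); under
the six fractionation scenarios only marine sulfate-AOM at α_ox = 1.039
yields a physically possible fraction (f_ox = 0.904, i.e. ~90 % of the
methane oxidized — the generator's true value was 35/38 ≈ 0.921); the other
five scenarios imply f_ox > 1 and are rejected. The budget brackets AOM
consumption between 1.6 × 10⁻⁵ and 0.077 Tg C yr⁻¹ across the concentration
and f_ox grid. The per-scenario table is in `rep@estimates`:

```r
rep@estimates[, c("scenario", "alpha_ox", "f_raw", "retained")]
#>            scenario alpha_ox  f_raw retained
#> 1  S-AOM-marine-low    1.009 4.2946    FALSE
#> 2 S-AOM-marine-high    1.039 0.9041     TRUE
#> 3  S-AOM-freshwater    1.030 1.1847    FALSE
#> 4            Fe-AOM    1.031 1.1452    FALSE
#> 5             N-AOM    1.032 1.1083    FALSE
#> 6           EEL-AOM    1.017 2.0949    FALSE
```

`writeReport(rep, "out/")` serializes the report (with the full assumption
ledger: thresholds, retention cap, pore-water fraction, scenario registry)
to JSON and CSV. Profiles themselves are read and written with
`readCoreProfile()` / `writeCoreProfile()` in a single canonical CSV
dialect (`depth_mbsf,ch4_uM,d13c_ch4_permil,so4_mM,no3_uM,mn_uM,fe_uM,state`).

A thin command-line wrapper over the same functions is installed at
`inst/scripts/aom-pipeline.R` (`analyze` and `simulate` subcommands).

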