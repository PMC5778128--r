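## physical constants of the headspace equilibration model
.gasConstant <- 8.314      # J mol-1 K-1
.molarVolumeSTP <- 22.414  # L mol-1
.pressureSTP <- 101.325    # kPa
.porewaterDensity <- 1.0   # g mL-1, mass -> volume conversion of pore water

#' Dissolved methane per litre pore water from a headspace measurement
#'
#' Computes the total methane in a sealed serum vial (frozen sediment
#' immersed in saturated NaCl brine) from the headspace gas-chromatography
#' mole fraction, and reports it relative to the sediment's pore-water
#' volume, regardless of whether that water was present as ice or water.
#' Total moles are the ideal-gas headspace term
#' \eqn{x P V_{hs} / (R T)} plus the dissolved term via the Bunsen
#' solubility coefficient,
#' \eqn{\beta V_{brine} (x P / P_0) / V_{m,STP}}.
#' The headspace volume is the vial volume minus brine and sediment-solids
#' volume; pore-water volume is `sedimentMassWet x waterContent / 1.0 g/mL`.
#'
#' @param vialVolume serum-vial volume, mL.
#' @param brineVolume added brine volume, mL.
#' @param sedimentMassWet wet sediment mass, g.
#' @param waterContent mass fraction of water in wet sediment, \[0, 1).
#' @param ch4MoleFraction methane mole fraction in the headspace, \[0, 1\].
#' @param pressureKPa headspace pressure, kPa.
#' @param temperatureK equilibration temperature, K.
#' @param bunsen Bunsen coefficient (volume CH4 at STP per volume brine per
#'   atm CH4 partial pressure). Default 0.002: salting-out in saturated NaCl
#'   brine makes methane solubility nearly negligible; always override when
#'   a measured value is available. Echoed by [headspaceBatch()].
#' @param sedimentDensity sediment solids density, g mL-1 (default 2.0).
#' @return dissolved methane, umol per litre pore water. Vectorized over all
#'   sample arguments.
#' @examples
#' # headspace-only partition (bunsen = 0): 4.087 umol in 1 mL pore water
#' dissolvedCH4Concentration(20, 8.5, 3, 1 / 3, 0.01, 101.325, 298.15,
#'                           bunsen = 0, sedimentDensity = 2)
#' @export
dissolvedCH4Concentration <- function(vialVolume, brineVolume,
                                      sedimentMassWet, waterContent,
                                      ch4MoleFraction, pressureKPa,
                                      temperatureK, bunsen = 0.002,
                                      sedimentDensity = 2.0) {
  n <- max(lengths(list(vialVolume, brineVolume, sedimentMassWet,
                        waterContent, ch4MoleFraction, pressureKPa,
                        temperatureK, bunsen)))
  args <- lapply(list(vialVolume = vialVolume, brineVolume = brineVolume,
                      sedimentMassWet = sedimentMassWet,
                      waterContent = waterContent,
                      ch4MoleFraction = ch4MoleFraction,
                      pressureKPa = pressureKPa, temperatureK = temperatureK,
                      bunsen = bunsen), rep_len, n)
  with(args, {
    if (any(vialVolume <= 0 | brineVolume <= 0 | sedimentMassWet <= 0 |
            pressureKPa <= 0 | temperatureK <= 0))
      stop("volumes, masses, pressure and temperature must be positive")
    if (any(ch4MoleFraction < 0 | ch4MoleFraction > 1))
      stop("ch4MoleFraction must lie in [0, 1]")
    if (any(bunsen < 0)) stop("bunsen coefficient must be non-negative")
    if (any(waterContent <= 0 | waterContent >= 1))
      stop("undefined basis: waterContent must lie in (0, 1)")
    sedimentVolume <- sedimentMassWet / sedimentDensity          # mL
    headspaceVolume <- vialVolume - brineVolume - sedimentVolume # mL
    if (any(headspaceVolume <= 0))
      stop("geometry error: headspace volume must be positive")
    # ideal-gas headspace term, mol: x * P[Pa] * V[m3] / (R * T)
    headspaceMol <- ch4MoleFraction * (pressureKPa * 1000) *
      (headspaceVolume * 1e-6) / (.gasConstant * temperatureK)
    # Bunsen dissolved term, mol: beta * V_brine[L] * (x P / P0) / Vm
    dissolvedMol <- bunsen * (brineVolume / 1000) *
      (ch4MoleFraction * pressureKPa / .pressureSTP) / .molarVolumeSTP
    porewaterVolumeL <- sedimentMassWet * waterContent /
      .porewaterDensity / 1000
    (headspaceMol + dissolvedMol) * 1e6 / porewaterVolumeL
  })
}

#' Batch headspace computation over a sample table
#'
#' Applies [dissolvedCH4Concentration()] to each row of a sample table (the
#' same field names as the function arguments, in snake_case) and appends
#' the result plus an echo of the solubility and density assumptions.
#'
#' @param samples data.frame with columns `vial_volume_ml`,
#'   `brine_volume_ml`, `sediment_mass_wet_g`, `water_content`,
#'   `ch4_mole_fraction`, `pressure_kpa`, `temperature_k` and optionally
#'   `bunsen`.
#' @param bunsen,sedimentDensity defaults for rows without their own values.
#' @return the input with added columns `ch4_uM_porewater`, `bunsen_used`,
#'   `sediment_density_used`.
#' @export
headspaceBatch <- function(samples, bunsen = 0.002, sedimentDensity = 2.0) {
  need <- c("vial_volume_ml", "brine_volume_ml", "sediment_mass_wet_g",
            "water_content", "ch4_mole_fraction", "pressure_kpa",
            "temperature_k")
  missing <- setdiff(need, names(samples))
  if (length(missing))
    stop("sample table lacks column(s): ", paste(missing, collapse = ", "))
  b <- if ("bunsen" %in% names(samples)) {
    ifelse(is.na(samples$bunsen), bunsen, samples$bunsen)
  } else rep(bunsen, nrow(samples))
  samples$ch4_uM_porewater <- dissolvedCH4Concentration(
    samples$vial_volume_ml, samples$brine_volume_ml,
    samples$sediment_mass_wet_g, samples$water_content,
    samples$ch4_mole_fraction, samples$pressure_kpa, samples$temperature_k,
    bunsen = b, sedimentDensity = sedimentDensity)
  samples$bunsen_used <- b
  samples$sediment_density_used <- sedimentDensity
  samples
}
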