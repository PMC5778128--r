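## carbon molar mass: mass of C in CH4, since the budget reports Tg C
.carbonMolarMass <- 12.011   # g mol-1
.gramsPerTg <- 1e12

#' Methane release rate from degrading submarine permafrost
#'
#' Release of pore-water methane caused by vertical permafrost degradation,
#' upscaled over the submarine permafrost area:
#' `degradationRate (m/yr) x area (m2) x porewaterVolumeFraction x
#' concentration (mol CH4 / m3 pore water)`, in mol CH4 yr-1. The release
#' precedes oxidation and is independent of the fraction-oxidized bounds.
#'
#' @param inputs a [BudgetInputs-class].
#' @param level which concentration level to use: `"low"`, `"mean"` or
#'   `"high"` (lowest, average and highest methane concentration of the
#'   ice-bonded permafrost).
#' @return mol CH4 yr-1.
#' @examples
#' b <- BudgetInputs(0.053, 0.384, 0.384, 0.384, fOxMin = 1, fOxMax = 1)
#' methaneReleaseRate(b, "mean")   # 2.44224e10 mol/yr
#' @export
methaneReleaseRate <- function(inputs, level = c("mean", "low", "high")) {
  stopifnot(is(inputs, "BudgetInputs"))
  validObject(inputs)
  level <- match.arg(level)
  conc <- switch(level, low = inputs@ch4Low, mean = inputs@ch4Mean,
                 high = inputs@ch4High)
  inputs@degradationRate * inputs@area * inputs@porewaterVolumeFraction * conc
}

#' Oxidized-carbon consumption in Tg C per year
#'
#' Converts a methane release rate and a fraction oxidized into the mass of
#' methane-carbon consumed by AOM: `release x fOx x 12.011 g/mol / 1e12
#' g/Tg`.
#'
#' @param release methane release, mol CH4 yr-1 (non-negative).
#' @param fOx fraction oxidized in \[0, 1\].
#' @return Tg C yr-1.
#' @examples
#' oxidizedCarbon(2.44224e10, 1)   # 0.29334 Tg C / yr
#' @export
oxidizedCarbon <- function(release, fOx) {
  if (any(!is.finite(release)) || any(release < 0))
    stop("release must be finite and non-negative")
  if (any(!is.finite(fOx)) || any(fOx < 0) || any(fOx > 1))
    stop("fOx must lie in [0, 1]")
  release * fOx * .carbonMolarMass / .gramsPerTg
}

#' Budget grid over concentration levels and fraction-oxidized bounds
#'
#' Evaluates the oxidized-carbon budget on the full 3 x 2 grid of methane
#' concentration level (low/mean/high of the ice-bonded section) by
#' fraction-oxidized bound (retained minimum / maximum), the same scheme the
#' regional extrapolation uses to bracket AOM consumption. The overall
#' minimum and maximum are attached as attributes `"min"` and `"max"`.
#'
#' @param inputs a [BudgetInputs-class].
#' @return data.frame with columns `level`, `f_bound`, `f_ox`,
#'   `release_mol_yr`, `oxidized_tg_c_yr`.
#' @examples
#' b <- BudgetInputs(0.053, 0.1, 0.384, 0.5, fOxMin = 0.79, fOxMax = 1)
#' g <- budgetGrid(b)
#' attr(g, "min"); attr(g, "max")
#' @export
budgetGrid <- function(inputs) {
  stopifnot(is(inputs, "BudgetInputs"))
  validObject(inputs)
  grid <- expand.grid(level = c("low", "mean", "high"),
                      f_bound = c("min", "max"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$f_ox <- ifelse(grid$f_bound == "min", inputs@fOxMin, inputs@fOxMax)
  grid$release_mol_yr <- vapply(grid$level, function(lv)
    methaneReleaseRate(inputs, lv), numeric(1))
  grid$oxidized_tg_c_yr <- oxidizedCarbon(grid$release_mol_yr, grid$f_ox)
  attr(grid, "min") <- min(grid$oxidized_tg_c_yr)
  attr(grid, "max") <- max(grid$oxidized_tg_c_yr)
  grid
}

#' Read budget inputs from a YAML configuration
#'
#' Keys mirror the [BudgetInputs()] arguments in snake_case:
#' `degradation_rate_m_yr`, `area_m2`, `porewater_volume_fraction`,
#' `ch4_low_mol_m3`, `ch4_mean_mol_m3`, `ch4_high_mol_m3`, `f_ox_min`,
#' `f_ox_max`.
#'
#' @param path YAML file path.
#' @return a validated [BudgetInputs-class].
#' @export
readBudgetConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("degradation_rate_m_yr", "ch4_low_mol_m3", "ch4_mean_mol_m3",
            "ch4_high_mol_m3", "f_ox_min", "f_ox_max")
  missing <- need[!vapply(need, function(k) !is.null(cfg[[k]]), logical(1))]
  if (length(missing))
    stop("budget config lacks field(s): ", paste(missing, collapse = ", "))
  BudgetInputs(
    degradationRate = cfg$degradation_rate_m_yr,
    ch4Low = cfg$ch4_low_mol_m3, ch4Mean = cfg$ch4_mean_mol_m3,
    ch4High = cfg$ch4_high_mol_m3,
    fOxMin = cfg$f_ox_min, fOxMax = cfg$f_ox_max,
    area = if (is.null(cfg$area_m2)) 3e12 else cfg$area_m2,
    porewaterVolumeFraction = if (is.null(cfg$porewater_volume_fraction)) 0.4
                              else cfg$porewater_volume_fraction)
}
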