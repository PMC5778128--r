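#' Run the full profile -> zonation -> fractionation -> budget analysis
#'
#' Executes the analysis chain in fixed order on one core profile: horizon
#' zonation by delta13C thresholds, SMTZ detection, extraction of the
#' maximal isotope shift, per-scenario fraction-oxidized estimates with the
#' physical retention rule, and (when budget inputs are supplied and at
#' least one scenario is retained) the upscaled oxidized-carbon budget grid.
#' A profile with no qualifying oxidized/source pair yields a report whose
#' fraction-oxidized section is marked not computable, never an error.
#' All configuration problems are collected and reported together.
#'
#' @param profile a [CoreProfile-class] (or a path accepted by
#'   [readCoreProfile()]).
#' @param scenarios list of [FractionationScenario-class] objects; default
#'   the built-in registry [defaultScenarios()].
#' @param oxThreshold,sourceThreshold zonation thresholds, permil VPDB.
#' @param sulfateFloor mM, see [detectSmtz()].
#' @param cap retention cap on the raw fraction, see [evaluateScenarios()].
#' @param budget optional [BudgetInputs-class] whose `fOxMin`/`fOxMax` are
#'   replaced by the retained capped-fraction range before the grid is
#'   evaluated.
#' @return an [AomReport-class]. The assumption ledger (thresholds, cap,
#'   sulfate floor, scenario registry, pore-water fraction when a budget is
#'   run) is always present in the report.
#' @examples
#' sim <- generateCore(syntheticCoreParams("c2_like", seed = 1,
#'                                         noiseSdDelta = 0, noiseSdConc = 0))
#' runAnalysis(sim$profile)
#' @export
runAnalysis <- function(profile, scenarios = defaultScenarios(),
                        oxThreshold = -37, sourceThreshold = -52,
                        sulfateFloor = 1.0, cap = 1.0, budget = NULL) {
  if (is.character(profile)) profile <- readCoreProfile(profile)
  problems <- character()
  if (!is(profile, "CoreProfile"))
    problems <- c(problems, "profile must be a CoreProfile or a file path")
  if (!length(scenarios) ||
      !all(vapply(scenarios, is, logical(1), "FractionationScenario")))
    problems <- c(problems, "scenarios must be a non-empty list of FractionationScenario")
  if (!is.numeric(oxThreshold) || !is.numeric(sourceThreshold) ||
      !(oxThreshold > sourceThreshold))
    problems <- c(problems, "thresholds must satisfy oxThreshold > sourceThreshold")
  if (!is.numeric(cap) || length(cap) != 1L || cap <= 0)
    problems <- c(problems, "cap must be a single positive number")
  if (!is.null(budget) && !is(budget, "BudgetInputs"))
    problems <- c(problems, "budget must be NULL or a BudgetInputs object")
  if (length(problems))
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "))
  validObject(profile)

  zonation <- classifyHorizons(profile, oxThreshold, sourceThreshold)
  smtz <- tryCatch(detectSmtz(profile, sulfateFloor),
                   error = function(e) NULL)
  shift <- maxIsotopeShift(profile, oxThreshold, sourceThreshold)

  estimates <- NULL
  fOxRange <- c(NA_real_, NA_real_)
  budgetResult <- NULL
  if (!is.null(shift)) {
    estimates <- evaluateScenarios(shift, scenarios, cap)
    retained <- estimates[estimates$retained, , drop = FALSE]
    if (nrow(retained)) {
      fOxRange <- range(retained$f_capped)
      if (!is.null(budget)) {
        budgetUsed <- BudgetInputs(
          degradationRate = budget@degradationRate,
          ch4Low = budget@ch4Low, ch4Mean = budget@ch4Mean,
          ch4High = budget@ch4High,
          fOxMin = fOxRange[1], fOxMax = fOxRange[2],
          area = budget@area,
          porewaterVolumeFraction = budget@porewaterVolumeFraction)
        budgetResult <- budgetGrid(budgetUsed)
      }
    }
  }

  assumptions <- list(
    ox_threshold_permil = oxThreshold,
    source_threshold_permil = sourceThreshold,
    sulfate_floor_mM = sulfateFloor,
    retention_cap = cap,
    scenario_registry = vapply(scenarios, scenarioName, character(1)),
    porewater_volume_fraction = if (is.null(budget)) NA_real_
                                else budget@porewaterVolumeFraction,
    area_m2 = if (is.null(budget)) NA_real_ else budget@area,
    carbon_molar_mass_g_mol = .carbonMolarMass)

  new("AomReport", coreId = coreId(profile), zonation = zonation,
      smtz = smtz, shift = shift, estimates = estimates,
      fOxRange = fOxRange, budget = budgetResult,
      assumptions = assumptions,
      version = as.character(utils::packageVersion("permafrostAOM")))
}

#' Write an AomReport to disk
#'
#' Emits `report.json` (stable key order, every number traceable to one
#' operation's output, assumption ledger included) and `zonation.csv`
#' (`depth_mbsf,label`) into a directory.
#'
#' @param report an [AomReport-class].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
writeReport <- function(report, dir) {
  stopifnot(is(report, "AomReport"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  payload <- list(
    core_id = report@coreId,
    version = report@version,
    assumptions = report@assumptions,
    zonation = report@zonation,
    smtz = if (is.null(report@smtz)) NULL else list(
      top_mbsf = report@smtz@topMbsf, bottom_mbsf = report@smtz@bottomMbsf,
      sulfate_at_top_mM = report@smtz@sulfateAtTop,
      methane_at_bottom_uM = report@smtz@methaneAtBottom),
    isotope_shift = if (is.null(report@shift)) "not_computable" else list(
      delta_o_permil = report@shift@deltaO,
      delta_p_permil = report@shift@deltaP,
      depth_o_mbsf = report@shift@depthO,
      depth_p_mbsf = report@shift@depthP,
      shift_permil = report@shift@shift),
    scenario_estimates = report@estimates,
    f_ox_retained_range = if (anyNA(report@fOxRange)) "not_computable"
                          else report@fOxRange,
    budget = report@budget)
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  write.csv(report@zonation, file.path(dir, "zonation.csv"),
            row.names = FALSE, quote = FALSE)
  invisible(dir)
}
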