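#' @import methods
#' @importFrom stats rnorm setNames
#' @importFrom utils read.csv write.csv
NULL

## canonical pore-water profile dialect: one header row, comma-separated,
## empty string = missing value
.profileColumns <- c("depth_mbsf", "ch4_uM", "d13c_ch4_permil", "so4_mM",
                     "no3_uM", "mn_uM", "fe_uM", "state")
.analyteColumns <- c("ch4_uM", "d13c_ch4_permil", "so4_mM", "no3_uM",
                     "mn_uM", "fe_uM")
.frozenStates <- c("ice_bonded", "unfrozen", "partially_thawed", "unknown")

setClassUnion("DFOrNULL", c("data.frame", "NULL"))

#' CoreProfile: depth-resolved pore-water geochemistry of one sediment core
#'
#' Holds the ordered pore-water records of a single submarine permafrost
#' core: depth (metres below seafloor, positive downward), dissolved methane
#' (\eqn{\mu}mol per litre pore water), \eqn{\delta^{13}}C-CH4 (permil VPDB),
#' sulfate (mM), nitrate/manganese/iron (\eqn{\mu}M, total ions) and the
#' frozen state of each horizon.
#'
#' @slot coreId single string identifying the core.
#' @slot inundationAge years since marine inundation (NA when unknown).
#' @slot records data.frame with the canonical profile columns, strictly
#'   increasing in `depth_mbsf`.
#' @slot provenance free-text metadata.
#' @export
setClass("CoreProfile",
         representation(coreId = "character",
                        inundationAge = "numeric",
                        records = "data.frame",
                        provenance = "character"))

setValidity("CoreProfile", function(object) {
  msgs <- character()
  rec <- object@records
  if (length(object@coreId) != 1L || is.na(object@coreId))
    msgs <- c(msgs, "coreId must be a single non-NA string")
  missing_cols <- setdiff(.profileColumns, names(rec))
  if (length(missing_cols))
    return(paste("records lack required columns:",
                 paste(missing_cols, collapse = ", ")))
  if (nrow(rec) < 1L)
    msgs <- c(msgs, "profile must contain at least one record")
  d <- rec$depth_mbsf
  if (anyNA(d) || any(d < 0))
    msgs <- c(msgs, "depth_mbsf must be non-negative and non-missing")
  if (anyDuplicated(d)) {
    dup <- unique(d[duplicated(d)])
    msgs <- c(msgs, paste("duplicate depths:", paste(dup, collapse = ", ")))
  } else if (is.unsorted(d, strictly = TRUE)) {
    msgs <- c(msgs, "records must be strictly increasing in depth_mbsf")
  }
  for (col in c("ch4_uM", "so4_mM", "no3_uM", "mn_uM", "fe_uM")) {
    v <- rec[[col]]
    if (any(v < 0, na.rm = TRUE))
      msgs <- c(msgs, paste0("negative concentration in column ", col))
  }
  d13 <- rec$d13c_ch4_permil
  if (any(d13 < -120 | d13 > 20, na.rm = TRUE))
    msgs <- c(msgs, "d13c_ch4_permil outside [-120, 20] permil VPDB")
  if (!all(rec$state %in% .frozenStates))
    msgs <- c(msgs, paste("state must be one of:",
                          paste(.frozenStates, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' Construct a CoreProfile
#'
#' Rows are sorted by depth; analyte columns absent from `records` are filled
#' with `NA`, and a missing `state` column defaults to `"unknown"`. Duplicate
#' depths and negative concentrations are rejected.
#'
#' @param records data.frame with at least a `depth_mbsf` column; recognised
#'   analyte columns are `ch4_uM`, `d13c_ch4_permil`, `so4_mM`, `no3_uM`,
#'   `mn_uM`, `fe_uM`, plus a `state` column with values among
#'   `ice_bonded`, `unfrozen`, `partially_thawed`, `unknown`.
#' @param coreId core identifier.
#' @param inundationAge years since inundation (optional).
#' @param provenance free-text metadata (optional).
#' @return a validated [CoreProfile-class] object.
#' @examples
#' p <- CoreProfile(data.frame(depth_mbsf = c(2, 1), ch4_uM = c(20, 10)))
#' records(p)$depth_mbsf   # sorted ascending
#' @export
CoreProfile <- function(records, coreId = "core", inundationAge = NA_real_,
                        provenance = character()) {
  stopifnot(is.data.frame(records))
  if (!"depth_mbsf" %in% names(records))
    stop("records must contain a 'depth_mbsf' column")
  if (nrow(records) < 1L)
    stop("profile must contain at least one record")
  rec <- records
  for (col in .analyteColumns)
    if (!col %in% names(rec)) rec[[col]] <- NA_real_
  if (!"state" %in% names(rec)) rec$state <- "unknown"
  rec$state[is.na(rec$state)] <- "unknown"
  for (col in c("depth_mbsf", .analyteColumns))
    rec[[col]] <- as.numeric(rec[[col]])
  rec$state <- as.character(rec$state)
  rec <- rec[order(rec$depth_mbsf), .profileColumns, drop = FALSE]
  rownames(rec) <- NULL
  new("CoreProfile", coreId = as.character(coreId),
      inundationAge = as.numeric(inundationAge), records = rec,
      provenance = as.character(provenance))
}

#' @describeIn CoreProfile accessor for the record table.
#' @param x a `CoreProfile`.
#' @export
setGeneric("records", function(x) standardGeneric("records"))
#' @export
setMethod("records", "CoreProfile", function(x) x@records)

#' @describeIn CoreProfile accessor for the core identifier.
#' @export
setGeneric("coreId", function(x) standardGeneric("coreId"))
#' @export
setMethod("coreId", "CoreProfile", function(x) x@coreId)

#' @describeIn CoreProfile number of horizons in the profile.
#' @export
setMethod("length", "CoreProfile", function(x) nrow(x@records))

setMethod("show", "CoreProfile", function(object) {
  rec <- object@records
  cat("CoreProfile '", object@coreId, "': ", nrow(rec), " horizons, ",
      sprintf("%.1f-%.1f mbsf\n", min(rec$depth_mbsf), max(rec$depth_mbsf)),
      sep = "")
  n_d13 <- sum(!is.na(rec$d13c_ch4_permil))
  cat("  d13C-CH4 measured at ", n_d13, " horizons; frozen states: ",
      paste(names(table(rec$state)), table(rec$state),
            sep = "=", collapse = ", "), "\n", sep = "")
  if (!is.na(object@inundationAge))
    cat("  inundation age: ", object@inundationAge, " yr\n", sep = "")
})

#' FractionationScenario: a named pair of isotope fractionation factors
#'
#' One AOM fractionation scenario: the kinetic fractionation factor of
#' anaerobic methane oxidation (`alphaOx`) paired with the transport
#' (diffusion) fractionation factor (`alphaTrans`), labelled by the terminal
#' electron acceptor the literature value refers to.
#'
#' @slot name short scenario name.
#' @slot alphaOx oxidation fractionation factor (> 1).
#' @slot alphaTrans transport fractionation factor (>= 1, != alphaOx).
#' @slot electronAcceptor one of `sulfate_marine`, `sulfate_freshwater`,
#'   `iron`, `nitrate`, `EET`, `other`.
#' @slot sourceNote free-text provenance of the alpha value.
#' @export
setClass("FractionationScenario",
         representation(name = "character", alphaOx = "numeric",
                        alphaTrans = "numeric", electronAcceptor = "character",
                        sourceNote = "character"))

.electronAcceptors <- c("sulfate_marine", "sulfate_freshwater", "iron",
                        "nitrate", "EET", "other")

setValidity("FractionationScenario", function(object) {
  msgs <- character()
  if (length(object@alphaOx) != 1L || !is.finite(object@alphaOx) ||
      object@alphaOx <= 1)
    msgs <- c(msgs, "alphaOx must be a single finite value > 1")
  if (length(object@alphaTrans) != 1L || !is.finite(object@alphaTrans) ||
      object@alphaTrans < 1)
    msgs <- c(msgs, "alphaTrans must be a single finite value >= 1")
  if (length(object@alphaOx) == 1L && length(object@alphaTrans) == 1L &&
      isTRUE(object@alphaOx == object@alphaTrans))
    msgs <- c(msgs, "alphaOx must differ from alphaTrans")
  if (!object@electronAcceptor %in% .electronAcceptors)
    msgs <- c(msgs, paste("electronAcceptor must be one of:",
                          paste(.electronAcceptors, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' Construct a FractionationScenario
#'
#' @param name scenario name.
#' @param alphaOx oxidation fractionation factor (> 1).
#' @param alphaTrans transport fractionation factor (default 1.001, the soil
#'   diffusion value used for all built-in scenarios).
#' @param electronAcceptor electron-acceptor label.
#' @param sourceNote optional provenance note.
#' @return a validated [FractionationScenario-class].
#' @examples
#' FractionationScenario("S-AOM-marine-high", 1.039,
#'                       electronAcceptor = "sulfate_marine")
#' @export
FractionationScenario <- function(name, alphaOx, alphaTrans = 1.001,
                                  electronAcceptor = "other",
                                  sourceNote = character()) {
  new("FractionationScenario", name = as.character(name),
      alphaOx = as.numeric(alphaOx), alphaTrans = as.numeric(alphaTrans),
      electronAcceptor = as.character(electronAcceptor),
      sourceNote = as.character(sourceNote))
}

#' @describeIn FractionationScenario accessor for the oxidation factor.
#' @param x a `FractionationScenario`.
#' @export
setGeneric("alphaOx", function(x) standardGeneric("alphaOx"))
#' @export
setMethod("alphaOx", "FractionationScenario", function(x) x@alphaOx)

#' @describeIn FractionationScenario accessor for the transport factor.
#' @export
setGeneric("alphaTrans", function(x) standardGeneric("alphaTrans"))
#' @export
setMethod("alphaTrans", "FractionationScenario", function(x) x@alphaTrans)

#' @describeIn FractionationScenario accessor for the scenario name.
#' @export
setGeneric("scenarioName", function(x) standardGeneric("scenarioName"))
#' @export
setMethod("scenarioName", "FractionationScenario", function(x) x@name)

setMethod("show", "FractionationScenario", function(object) {
  cat(sprintf("FractionationScenario '%s' (%s): alpha_ox = %.4f, alpha_trans = %.4f\n",
              object@name, object@electronAcceptor, object@alphaOx,
              object@alphaTrans))
})

#' IsotopeShift: the oxidized/source delta13C pair driving the mass balance
#'
#' The pair of \eqn{\delta^{13}}C-CH4 values entering the open-system isotope
#' mass balance: `deltaO` from an oxidized horizon and `deltaP` from a source
#' horizon lying below it, with their difference `shift` in permil.
#'
#' @slot deltaO permil VPDB in the oxidized layer.
#' @slot deltaP permil VPDB in the subjacent source layer.
#' @slot depthO depth (mbsf) of the oxidized layer.
#' @slot depthP depth (mbsf) of the source layer (`depthP > depthO`).
#' @slot shift `deltaO - deltaP` (permil).
#' @export
setClass("IsotopeShift",
         representation(deltaO = "numeric", deltaP = "numeric",
                        depthO = "numeric", depthP = "numeric",
                        shift = "numeric"))

setValidity("IsotopeShift", function(object) {
  msgs <- character()
  for (s in c("deltaO", "deltaP", "depthO", "depthP", "shift"))
    if (length(slot(object, s)) != 1L || !is.finite(slot(object, s)))
      msgs <- c(msgs, paste(s, "must be a single finite number"))
  if (!length(msgs)) {
    if (object@depthP <= object@depthO)
      msgs <- c(msgs, "source layer must lie below the oxidized layer (depthP > depthO)")
    if (abs(object@shift - (object@deltaO - object@deltaP)) > 1e-9)
      msgs <- c(msgs, "shift must equal deltaO - deltaP")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an IsotopeShift
#'
#' @param deltaO,deltaP permil VPDB of the oxidized and source layers.
#' @param depthO,depthP their depths (mbsf); `depthP` must exceed `depthO`.
#' @return a validated [IsotopeShift-class].
#' @examples
#' IsotopeShift(deltaO = -37, deltaP = -72, depthO = 50, depthP = 52)
#' @export
IsotopeShift <- function(deltaO, deltaP, depthO, depthP) {
  new("IsotopeShift", deltaO = as.numeric(deltaO), deltaP = as.numeric(deltaP),
      depthO = as.numeric(depthO), depthP = as.numeric(depthP),
      shift = as.numeric(deltaO) - as.numeric(deltaP))
}

#' @describeIn IsotopeShift the isotope shift deltaO - deltaP in permil.
#' @param x an `IsotopeShift`.
#' @export
setGeneric("isotopeShift", function(x) standardGeneric("isotopeShift"))
#' @export
setMethod("isotopeShift", "IsotopeShift", function(x) x@shift)

setMethod("show", "IsotopeShift", function(object) {
  cat(sprintf("IsotopeShift: %.2f permil (delta_o = %.2f at %.2f mbsf, delta_p = %.2f at %.2f mbsf)\n",
              object@shift, object@deltaO, object@depthO, object@deltaP,
              object@depthP))
})

#' SmtzInterval: a detected sulfate-methane transition zone
#'
#' Depth interval bracketing the crossing of the max-normalized sulfate and
#' methane profiles, where sulfate decreases and methane increases downward.
#'
#' @slot topMbsf,bottomMbsf interval bounds (m, `top < bottom`).
#' @slot sulfateAtTop sulfate (mM) at the interval top.
#' @slot methaneAtBottom methane (uM) at the interval bottom.
#' @export
setClass("SmtzInterval",
         representation(topMbsf = "numeric", bottomMbsf = "numeric",
                        sulfateAtTop = "numeric", methaneAtBottom = "numeric"))

setValidity("SmtzInterval", function(object) {
  if (object@topMbsf >= object@bottomMbsf)
    "topMbsf must be shallower than bottomMbsf"
  else TRUE
})

setMethod("show", "SmtzInterval", function(object) {
  cat(sprintf("SMTZ interval %.2f-%.2f mbsf (SO4 %.2f mM at top, CH4 %.1f uM at bottom)\n",
              object@topMbsf, object@bottomMbsf, object@sulfateAtTop,
              object@methaneAtBottom))
})

setClassUnion("SmtzOrNULL", c("SmtzInterval", "NULL"))
setClassUnion("ShiftOrNULL", c("IsotopeShift", "NULL"))

#' BudgetInputs: parameters of the permafrost-degradation methane budget
#'
#' Inputs of the upscaled methane-release and oxidized-carbon budget:
#' a vertical permafrost degradation rate, the submarine permafrost area, the
#' pore-water volume fraction of the sediment, three methane concentration
#' levels (low/mean/high of the ice-bonded section, mol CH4 per m3 pore
#' water) and the retained fraction-oxidized bounds.
#'
#' @slot degradationRate m yr-1 (0.006 for a C2-like core, 0.053 BK2-like).
#' @slot area m2 (default 3e12 = 3 million km2 of submarine permafrost).
#' @slot porewaterVolumeFraction dimensionless in (0, 1]; an explicit
#'   assumption, echoed in every report.
#' @slot ch4Low,ch4Mean,ch4High mol CH4 per m3 pore water, `low <= mean <= high`.
#' @slot fOxMin,fOxMax retained fraction-oxidized bounds in \[0, 1\].
#' @export
setClass("BudgetInputs",
         representation(degradationRate = "numeric", area = "numeric",
                        porewaterVolumeFraction = "numeric",
                        ch4Low = "numeric", ch4Mean = "numeric",
                        ch4High = "numeric", fOxMin = "numeric",
                        fOxMax = "numeric"))

setValidity("BudgetInputs", function(object) {
  msgs <- character()
  pos <- c("degradationRate", "area", "porewaterVolumeFraction",
           "ch4Low", "ch4Mean", "ch4High")
  for (s in pos) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msgs <- c(msgs, paste(s, "must be a single positive finite number"))
  }
  if (!length(msgs)) {
    if (object@porewaterVolumeFraction > 1)
      msgs <- c(msgs, "porewaterVolumeFraction must lie in (0, 1]")
    if (!(object@ch4Low <= object@ch4Mean && object@ch4Mean <= object@ch4High))
      msgs <- c(msgs, "require ch4Low <= ch4Mean <= ch4High")
    for (s in c("fOxMin", "fOxMax")) {
      v <- slot(object, s)
      if (length(v) != 1L || !is.finite(v) || v < 0 || v > 1)
        msgs <- c(msgs, paste(s, "must lie in [0, 1]"))
    }
    if (!length(msgs) && object@fOxMin > object@fOxMax)
      msgs <- c(msgs, "fOxMin must not exceed fOxMax")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct BudgetInputs
#'
#' @param degradationRate vertical degradation rate, m yr-1.
#' @param ch4Low,ch4Mean,ch4High methane concentration levels, mol m-3 pore
#'   water (1 uM = 1e-3 mol m-3).
#' @param fOxMin,fOxMax fraction-oxidized bounds in \[0, 1\].
#' @param area submarine permafrost area, m2.
#' @param porewaterVolumeFraction sediment pore-water volume fraction.
#' @return a validated [BudgetInputs-class].
#' @examples
#' BudgetInputs(0.053, ch4Low = 0.377, ch4Mean = 0.384, ch4High = 0.384,
#'              fOxMin = 0.79, fOxMax = 1)
#' @export
BudgetInputs <- function(degradationRate, ch4Low, ch4Mean, ch4High,
                         fOxMin, fOxMax, area = 3e12,
                         porewaterVolumeFraction = 0.4) {
  new("BudgetInputs", degradationRate = as.numeric(degradationRate),
      area = as.numeric(area),
      porewaterVolumeFraction = as.numeric(porewaterVolumeFraction),
      ch4Low = as.numeric(ch4Low), ch4Mean = as.numeric(ch4Mean),
      ch4High = as.numeric(ch4High), fOxMin = as.numeric(fOxMin),
      fOxMax = as.numeric(fOxMax))
}

setMethod("show", "BudgetInputs", function(object) {
  cat(sprintf("BudgetInputs: %.4f m/yr over %.3g m2, porewater fraction %.2f\n",
              object@degradationRate, object@area,
              object@porewaterVolumeFraction))
  cat(sprintf("  CH4 low/mean/high: %.4g/%.4g/%.4g mol m-3; f_ox in [%.3f, %.3f]\n",
              object@ch4Low, object@ch4Mean, object@ch4High,
              object@fOxMin, object@fOxMax))
})

#' AomReport: the assembled result of one profile analysis
#'
#' Produced by [runAnalysis()]: horizon zonation, the detected SMTZ (or
#' NULL), the maximal isotope shift (or NULL), the per-scenario oxidation
#' estimates with retention flags, the retained fraction-oxidized range, the
#' optional budget grid, and the assumption ledger echoing every tunable
#' constant that influenced a number.
#'
#' @slot coreId analysed core.
#' @slot zonation data.frame `depth_mbsf, label`.
#' @slot smtz [SmtzInterval-class] or NULL.
#' @slot shift [IsotopeShift-class] or NULL when no qualifying pair exists.
#' @slot estimates data.frame of per-scenario oxidation estimates (or NULL).
#' @slot fOxRange numeric length-2 `c(min, max)` over retained scenarios
#'   (capped fractions; `NA` when not computable).
#' @slot budget data.frame budget grid or NULL.
#' @slot assumptions named list of thresholds and constants used.
#' @slot version package version string.
#' @export
setClass("AomReport",
         representation(coreId = "character", zonation = "data.frame",
                        smtz = "SmtzOrNULL", shift = "ShiftOrNULL",
                        estimates = "DFOrNULL", fOxRange = "numeric",
                        budget = "DFOrNULL", assumptions = "list",
                        version = "character"))

setMethod("show", "AomReport", function(object) {
  cat("AomReport for core '", object@coreId, "'\n", sep = "")
  tab <- table(object@zonation$label)
  cat("  zonation: ", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n", sep = "")
  if (is.null(object@smtz)) cat("  SMTZ: none detected\n") else {
    cat("  ")
    show(object@smtz)
  }
  if (is.null(object@shift)) {
    cat("  isotope shift: not computable (no oxidized/source pair)\n")
  } else {
    cat("  ")
    show(object@shift)
    ret <- object@estimates[object@estimates$retained, , drop = FALSE]
    cat(sprintf("  scenarios: %d retained / %d rejected; retained f_ox %.3f-%.3f\n",
                nrow(ret), nrow(object@estimates) - nrow(ret),
                object@fOxRange[1], object@fOxRange[2]))
  }
  if (!is.null(object@budget))
    cat(sprintf("  budget: oxidized carbon %.4g-%.4g Tg C yr-1\n",
                min(object@budget$oxidized_tg_c_yr),
                max(object@budget$oxidized_tg_c_yr)))
})
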