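#' SyntheticCoreParams: parameters of the synthetic-core generator
#'
#' Describes a synthetic submarine permafrost core with known ground truth:
#' the depth grid, the SMTZ and ice-bonded intervals, the source-methane
#' isotope signature `deltaPTrue`, the true fraction oxidized `fOxTrue`
#' under `scenarioTrue` (the oxidized-layer signature follows by the forward
#' isotope mass balance), the methane and sulfate profile shapes, noise
#' levels and the RNG seed. Use [syntheticCoreParams()] to build one from a
#' preset.
#'
#' @slot preset `"c2_like"`, `"bk2_like"` or `"custom"`.
#' @slot nHorizons number of evenly spaced horizons.
#' @slot depthRange,smtzInterval,ibpInterval depth intervals, m.
#' @slot deltaPTrue source delta13C, permil VPDB.
#' @slot fOxTrue true fraction oxidized in \[0, 1\].
#' @slot scenarioTrue the generating [FractionationScenario-class].
#' @slot ch4Background deep plateau methane, uM pore water.
#' @slot ch4Peak either `numeric(0)` (no peak) or `c(value_uM, depth_m)`.
#' @slot ch4PeakSd Gaussian peak width, m.
#' @slot sulfateSurface,sulfateDeep sulfate plateau values, mM.
#' @slot oxRampSlope,srcRampSlope delta13C gradients (permil per m) towards
#'   the oxidized crest and the source trough.
#' @slot oxSpan,srcSpan delta13C spans (permil) of the oxidized ramp and of
#'   the source zone above its trough.
#' @slot degradationRate m yr-1, used for the true budget.
#' @slot inundationAge years, profile metadata.
#' @slot noiseSdDelta additive Gaussian sd on delta13C, permil.
#' @slot noiseSdConc multiplicative log-normal sdlog on concentrations.
#' @slot seed integer RNG seed.
#' @export
setClass("SyntheticCoreParams",
         representation(preset = "character", nHorizons = "numeric",
                        depthRange = "numeric", smtzInterval = "numeric",
                        ibpInterval = "numeric", deltaPTrue = "numeric",
                        fOxTrue = "numeric",
                        scenarioTrue = "FractionationScenario",
                        ch4Background = "numeric", ch4Peak = "numeric",
                        ch4PeakSd = "numeric", sulfateSurface = "numeric",
                        sulfateDeep = "numeric", oxRampSlope = "numeric",
                        srcRampSlope = "numeric", oxSpan = "numeric",
                        srcSpan = "numeric", degradationRate = "numeric",
                        inundationAge = "numeric", noiseSdDelta = "numeric",
                        noiseSdConc = "numeric", seed = "numeric"))

setValidity("SyntheticCoreParams", function(object) {
  msgs <- character()
  dr <- object@depthRange
  if (length(dr) != 2L || dr[1] >= dr[2])
    msgs <- c(msgs, "depthRange must be an increasing length-2 interval")
  for (s in c("smtzInterval", "ibpInterval")) {
    iv <- slot(object, s)
    if (length(iv) != 2L || iv[1] >= iv[2])
      msgs <- c(msgs, paste(s, "must be an increasing length-2 interval"))
    else if (length(dr) == 2L && (iv[1] < dr[1] || iv[2] > dr[2]))
      msgs <- c(msgs, paste(s, "must lie within depthRange"))
  }
  if (object@fOxTrue < 0 || object@fOxTrue > 1)
    msgs <- c(msgs, "fOxTrue must lie in [0, 1]")
  if (object@noiseSdDelta < 0 || object@noiseSdConc < 0)
    msgs <- c(msgs, "noise levels must be non-negative")
  if (object@nHorizons < 4)
    msgs <- c(msgs, "nHorizons must be at least 4")
  if (!length(object@ch4Peak) %in% c(0L, 2L))
    msgs <- c(msgs, "ch4Peak must be numeric(0) or c(value_uM, depth_m)")
  if (length(object@ch4Peak) == 2L && length(dr) == 2L &&
      (object@ch4Peak[2] < dr[1] || object@ch4Peak[2] > dr[2]))
    msgs <- c(msgs, "ch4Peak depth must lie within depthRange")
  if (length(msgs)) msgs else TRUE
})

#' Build synthetic-core parameters from a preset
#'
#' Two presets emulate the printed qualitative structure of the study cores.
#' `"c2_like"`: 118 horizons to 58.5 mbsf, ice-bonded below 34.5 m, SMTZ at
#' 50-53 mbsf, low background methane with a 990 uM peak at 52 mbsf, source
#' signature -72 permil and a true oxidized fraction of 35/38 under the
#' marine high S-AOM scenario, so the noiseless isotope extremes are -72 and
#' -37 permil. `"bk2_like"`: 80 horizons to 47.4 mbsf, ice-bonded permafrost
#' below the thaw front at 24.6 mbsf, an SMTZ at the permafrost table
#' (24.0-24.6 mbsf) with opposing sulfate/methane gradients, methane 8x the
#' C2 average in the frozen section, source signature -71 permil and
#' complete oxidation (`fOxTrue = 1`) above the thaw front. Any slot can be
#' overridden by name; `preset = "custom"` starts from the c2-like defaults.
#'
#' @param preset `"c2_like"`, `"bk2_like"` or `"custom"`.
#' @param seed integer RNG seed.
#' @param ... named slot overrides (e.g. `fOxTrue = 0.8`,
#'   `noiseSdDelta = 1`).
#' @return a validated [SyntheticCoreParams-class].
#' @examples
#' syntheticCoreParams("bk2_like", seed = 1, noiseSdDelta = 1)
#' @export
syntheticCoreParams <- function(preset = c("c2_like", "bk2_like", "custom"),
                                seed = 1L, ...) {
  preset <- match.arg(preset)
  base <- list(
    preset = preset, nHorizons = 118, depthRange = c(0, 58.5),
    smtzInterval = c(50, 53), ibpInterval = c(34.5, 58.5),
    deltaPTrue = -72, fOxTrue = 35 / 38,
    scenarioTrue = defaultScenarios()[["S-AOM-marine-high"]],
    ch4Background = 12, ch4Peak = c(990, 52), ch4PeakSd = 0.5,
    sulfateSurface = 24, sulfateDeep = 0.1,
    oxRampSlope = 2.5, srcRampSlope = 3, oxSpan = 11, srcSpan = 17,
    degradationRate = 0.006, inundationAge = 2500,
    noiseSdDelta = 0.5, noiseSdConc = 0.05, seed = seed)
  if (preset == "bk2_like") {
    base[c("nHorizons", "depthRange", "smtzInterval", "ibpInterval",
           "deltaPTrue", "fOxTrue", "ch4Background", "ch4Peak",
           "sulfateSurface", "sulfateDeep", "degradationRate",
           "inundationAge")] <-
      list(80, c(0, 47.4), c(24.0, 24.6), c(24.6, 47.4),
           -71, 1.0, 384, numeric(0), 6, 0.08, 0.053, 540)
  }
  override <- list(...)
  unknown <- setdiff(names(override), names(base))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  base[names(override)] <- override
  do.call(new, c(list(Class = "SyntheticCoreParams"), base))
}

#' SyntheticTruth: ground truth of a generated core
#'
#' @slot fOxTrue generating fraction oxidized.
#' @slot deltaOExpected oxidized-layer delta13C implied by the forward mass
#'   balance (equals `deltaPTrue + 1000 (alpha_ox - alpha_trans) fOxTrue`).
#' @slot deltaPTrue source delta13C.
#' @slot smtzInterval true SMTZ interval, m.
#' @slot budgetTrue budget grid under the true parameters (noiseless
#'   ice-bonded concentrations, both f bounds at `fOxTrue`).
#' @slot seed RNG seed the core was generated with.
#' @export
setClass("SyntheticTruth",
         representation(fOxTrue = "numeric", deltaOExpected = "numeric",
                        deltaPTrue = "numeric", smtzInterval = "numeric",
                        budgetTrue = "data.frame", seed = "numeric"))

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf("SyntheticTruth: f_ox = %.4f (delta_o = %.2f, delta_p = %.2f), SMTZ %.1f-%.1f mbsf, seed %d\n",
              object@fOxTrue, object@deltaOExpected, object@deltaPTrue,
              object@smtzInterval[1], object@smtzInterval[2],
              as.integer(object@seed)))
})

## noiseless profile shapes ---------------------------------------------

.logistic <- function(x) 1 / (1 + exp(-x))

.syntheticCh4 <- function(d, params) {
  zt <- params@smtzInterval[1]; zb <- params@smtzInterval[2]
  mid <- (zt + zb) / 2
  w <- (zb - zt) / 8
  above <- 0.02 * params@ch4Background
  base <- above + (params@ch4Background - above) * .logistic((d - mid) / w)
  if (length(params@ch4Peak) == 2L) {
    pv <- params@ch4Peak[1]; pd <- params@ch4Peak[2]
    baseAtPeak <- above + (params@ch4Background - above) *
      .logistic((pd - mid) / w)
    amp <- pv - baseAtPeak
    base <- base + amp * exp(-(d - pd)^2 / (2 * params@ch4PeakSd^2))
  }
  base
}

.syntheticSulfate <- function(d, params) {
  zt <- params@smtzInterval[1]; zb <- params@smtzInterval[2]
  mid <- (zt + zb) / 2
  w <- (zb - zt) / 8
  params@sulfateDeep + (params@sulfateSurface - params@sulfateDeep) *
    .logistic(-(d - mid) / w)
}

.syntheticDelta <- function(d, params) {
  zt <- params@smtzInterval[1]; zb <- params@smtzInterval[2]
  dmax <- max(d)
  deltaO <- forwardDelta(params@fOxTrue, params@deltaPTrue,
                         params@scenarioTrue)
  crest <- max(d[d <= zt])
  ceiling <- params@deltaPTrue + params@srcSpan
  srcProfile <- function(x)
    pmax(params@deltaPTrue,
         pmin(ceiling, params@deltaPTrue + params@srcRampSlope * (dmax - x)))
  out <- numeric(length(d))
  upper <- d <= crest
  out[upper] <- pmax(deltaO - params@oxRampSlope * (crest - d[upper]),
                     deltaO - params@oxSpan)
  lower <- d > zb
  out[lower] <- srcProfile(d[lower])
  inner <- !upper & !lower
  if (any(inner)) {
    t <- (d[inner] - crest) / (zb - crest)
    out[inner] <- deltaO + t * (srcProfile(zb) - deltaO)
  }
  out
}

#' Generate a synthetic core with known ground truth
#'
#' Builds a [CoreProfile-class] on an even depth grid as the exact inverse
#' of the fraction-oxidized estimator: delta13C rises to the forward-model
#' crest value at the top of the SMTZ (most oxidized right above the
#' methane source) and falls to `deltaPTrue` at the deepest horizon (most
#' depleted at depth); methane climbs logistically across the SMTZ to its
#' deep plateau (plus an optional Gaussian peak) while sulfate declines
#' logistically across the same interval, guaranteeing opposing gradients.
#' Gaussian noise (permil) is added to delta13C and multiplicative
#' log-normal noise to concentrations; with both noise levels at zero the
#' pipeline recovers `fOxTrue`, the SMTZ and the true budget exactly.
#' Output is fully determined by `params@seed`.
#'
#' @param params a [SyntheticCoreParams-class].
#' @return list with elements `profile` ([CoreProfile-class]) and `truth`
#'   ([SyntheticTruth-class]).
#' @examples
#' sim <- generateCore(syntheticCoreParams("c2_like", seed = 7))
#' sim$truth
#' @export
generateCore <- function(params) {
  stopifnot(is(params, "SyntheticCoreParams"))
  validObject(params)
  set.seed(as.integer(params@seed))
  d <- seq(params@depthRange[1], params@depthRange[2],
           length.out = params@nHorizons)
  if (!any(d <= params@smtzInterval[1]))
    stop("no horizon at or above the SMTZ top")
  ch4 <- .syntheticCh4(d, params)
  so4 <- .syntheticSulfate(d, params)
  d13 <- .syntheticDelta(d, params)
  ## minor electron acceptors: mild depth decay, emulation only
  no3 <- 4 * exp(-d / 25) + 0.3
  mn <- 2 * exp(-d / 30) + 0.2
  fe <- 8 * exp(-d / 30) + 0.5
  n <- length(d)
  d13n <- d13 + rnorm(n, 0, params@noiseSdDelta)
  concNoise <- function(x) x * exp(rnorm(n, 0, params@noiseSdConc))
  rec <- data.frame(
    depth_mbsf = d, ch4_uM = concNoise(ch4),
    d13c_ch4_permil = pmax(-120, pmin(20, d13n)),
    so4_mM = concNoise(so4), no3_uM = concNoise(no3),
    mn_uM = concNoise(mn), fe_uM = concNoise(fe),
    state = ifelse(d >= params@ibpInterval[1] & d <= params@ibpInterval[2],
                   "ice_bonded", "unfrozen"))
  profile <- CoreProfile(rec, coreId = paste0("synthetic-", params@preset),
                         inundationAge = params@inundationAge,
                         provenance = sprintf("synthetic core, seed %d",
                                              as.integer(params@seed)))
  ibp <- d >= params@ibpInterval[1] & d <= params@ibpInterval[2]
  ibpCh4 <- ch4[ibp] * 1e-3   # uM -> mol m-3, noiseless truth
  budgetTrue <- budgetGrid(BudgetInputs(
    degradationRate = params@degradationRate,
    ch4Low = min(ibpCh4), ch4Mean = mean(ibpCh4), ch4High = max(ibpCh4),
    fOxMin = params@fOxTrue, fOxMax = params@fOxTrue))
  truth <- new("SyntheticTruth", fOxTrue = params@fOxTrue,
               deltaOExpected = forwardDelta(params@fOxTrue,
                                             params@deltaPTrue,
                                             params@scenarioTrue),
               deltaPTrue = params@deltaPTrue,
               smtzInterval = params@smtzInterval,
               budgetTrue = budgetTrue, seed = params@seed)
  list(profile = profile, truth = truth)
}
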