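#' GDGT lipid biomarker indices
#'
#' Index calculators for glycerol dialkyl glycerol tetraether (GDGT)
#' membrane lipids measured in sediment extracts. All three are scale
#' invariant (abundances may be in any common response unit) and vectorized
#' over samples.
#'
#' `bitIndex` is the branched vs. isoprenoid tetraether index,
#' `(br I + br II + br III) / (br I + br II + br III + crenarchaeol)`;
#' values near 1 indicate terrestrial organic-matter dominance.
#'
#' `methaneIndex` is
#' `(GDGT-1 + GDGT-2 + GDGT-3) / (GDGT-1 + GDGT-2 + GDGT-3 + crenarchaeol +
#' crenarchaeol isomer)`; values approaching 1 indicate tetraether pools
#' dominated by AOM archaea, as at a sulfate-methane transition zone.
#'
#' `archaealBacterialRatio` is the plain quotient of the summed archaeal
#' over the summed bacterial ether lipids; values above 1 mark archaeal
#' dominance.
#'
#' @param brI,brII,brIII branched GDGT abundances (>= 0).
#' @param gdgt1,gdgt2,gdgt3 isoprenoid GDGT-1..3 abundances (>= 0).
#' @param crenarchaeol,crenIsomer crenarchaeol and its regioisomer (>= 0).
#' @param archaealEtherSum,bacterialEtherSum summed archaeal and bacterial
#'   ether lipid abundances (>= 0; bacterial sum must be positive).
#' @return a fraction in \[0, 1\] (`bitIndex`, `methaneIndex`) or a
#'   non-negative ratio (`archaealBacterialRatio`).
#' @examples
#' bitIndex(1, 1, 1, crenarchaeol = 1)                 # 0.75
#' methaneIndex(1, 1, 1, crenarchaeol = 1, crenIsomer = 1)  # 0.6
#' archaealBacterialRatio(3, 2)                        # 1.5
#' @name lipidIndices
NULL

.checkNonNegative <- function(...) {
  vals <- list(...)
  nm <- names(vals)
  for (k in seq_along(vals)) {
    if (any(!is.finite(vals[[k]])) || any(vals[[k]] < 0))
      stop("abundance '", nm[k], "' must be finite and non-negative")
  }
}

#' @rdname lipidIndices
#' @export
bitIndex <- function(brI, brII, brIII, crenarchaeol) {
  .checkNonNegative(brI = brI, brII = brII, brIII = brIII,
                    crenarchaeol = crenarchaeol)
  branched <- brI + brII + brIII
  denom <- branched + crenarchaeol
  if (any(denom == 0))
    stop("undefined index: all branched GDGTs and crenarchaeol are zero")
  branched / denom
}

#' @rdname lipidIndices
#' @export
methaneIndex <- function(gdgt1, gdgt2, gdgt3, crenarchaeol, crenIsomer) {
  .checkNonNegative(gdgt1 = gdgt1, gdgt2 = gdgt2, gdgt3 = gdgt3,
                    crenarchaeol = crenarchaeol, crenIsomer = crenIsomer)
  iso <- gdgt1 + gdgt2 + gdgt3
  denom <- iso + crenarchaeol + crenIsomer
  if (any(denom == 0))
    stop("undefined index: all five GDGT terms are zero")
  iso / denom
}

#' @rdname lipidIndices
#' @export
archaealBacterialRatio <- function(archaealEtherSum, bacterialEtherSum) {
  .checkNonNegative(archaealEtherSum = archaealEtherSum,
                    bacterialEtherSum = bacterialEtherSum)
  if (any(bacterialEtherSum == 0))
    stop("undefined ratio: bacterial ether sum is zero")
  archaealEtherSum / bacterialEtherSum
}

#' Lipid indices for a table of GDGT measurements
#'
#' Row-wise application of [bitIndex()], [methaneIndex()] and
#' [archaealBacterialRatio()] to a measurement table with columns `br_I`,
#' `br_II`, `br_III`, `gdgt_1`, `gdgt_2`, `gdgt_3`, `crenarchaeol`,
#' `cren_isomer`, `archaeal_ether_sum`, `bacterial_ether_sum`.
#'
#' @param measurements data.frame of GDGT abundances.
#' @return the input with added columns `bit`, `mi`,
#'   `archaeal_bacterial_ratio`.
#' @export
lipidIndexTable <- function(measurements) {
  need <- c("br_I", "br_II", "br_III", "gdgt_1", "gdgt_2", "gdgt_3",
            "crenarchaeol", "cren_isomer", "archaeal_ether_sum",
            "bacterial_ether_sum")
  missing <- setdiff(need, names(measurements))
  if (length(missing))
    stop("measurement table lacks column(s): ",
         paste(missing, collapse = ", "))
  m <- measurements
  m$bit <- bitIndex(m$br_I, m$br_II, m$br_III, m$crenarchaeol)
  m$mi <- methaneIndex(m$gdgt_1, m$gdgt_2, m$gdgt_3, m$crenarchaeol,
                       m$cren_isomer)
  m$archaeal_bacterial_ratio <- archaealBacterialRatio(
    m$archaeal_ether_sum, m$bacterial_ether_sum)
  m
}
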