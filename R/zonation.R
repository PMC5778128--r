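#' Classify core horizons by their delta13C-CH4 signature
#'
#' Partitions every horizon of a profile into one of four zonation labels
#' based on the stable carbon isotope signature of methane: `oxidized`
#' (residual methane enriched in 13C by anaerobic oxidation,
#' \eqn{\delta^{13}C \ge} `oxThreshold`), `source` (methane as produced or
#' trapped, \eqn{\delta^{13}C \le} `sourceThreshold`), `intermediate`
#' (between the thresholds) and `unconstrained` (no isotope measurement).
#' Both thresholds are inclusive so the printed endmember values of a core's
#' isotope range qualify for the mass balance.
#'
#' @param profile a [CoreProfile-class].
#' @param oxThreshold permil VPDB; default -37, the oxidized-layer threshold.
#' @param sourceThreshold permil VPDB; default -52, the source-layer
#'   threshold. Must be below `oxThreshold`.
#' @return data.frame with columns `depth_mbsf` and `label`, one row per
#'   horizon in depth order.
#' @examples
#' p <- CoreProfile(data.frame(depth_mbsf = 1:3,
#'                             d13c_ch4_permil = c(-35, -45, -70)))
#' classifyHorizons(p)
#' @export
classifyHorizons <- function(profile, oxThreshold = -37,
                             sourceThreshold = -52) {
  stopifnot(is(profile, "CoreProfile"))
  if (!(oxThreshold > sourceThreshold))
    stop("oxThreshold must exceed sourceThreshold")
  d13 <- profile@records$d13c_ch4_permil
  label <- ifelse(is.na(d13), "unconstrained",
                  ifelse(d13 >= oxThreshold, "oxidized",
                         ifelse(d13 <= sourceThreshold, "source",
                                "intermediate")))
  data.frame(depth_mbsf = profile@records$depth_mbsf, label = label,
             stringsAsFactors = FALSE)
}

#' Maximal isotope shift between an oxidized layer and a subjacent source
#'
#' Scans all ordered horizon pairs (oxidized layer above a source layer) and
#' returns the pair maximizing \eqn{\delta_o - \delta_p}, the largest change
#' in stable isotope signature, which drives the fraction-oxidized mass
#' balance. Ties are broken by the smallest depth separation, then by the
#' shallowest oxidized layer (the most local, least transport-confounded
#' signal).
#'
#' @inheritParams classifyHorizons
#' @return an [IsotopeShift-class], or `NULL` when no oxidized horizon lies
#'   above a source horizon.
#' @examples
#' p <- CoreProfile(data.frame(depth_mbsf = c(50, 52),
#'                             d13c_ch4_permil = c(-37, -72)))
#' isotopeShift(maxIsotopeShift(p))   # 35 permil
#' @export
maxIsotopeShift <- function(profile, oxThreshold = -37,
                            sourceThreshold = -52) {
  z <- classifyHorizons(profile, oxThreshold, sourceThreshold)
  rec <- profile@records
  ox <- which(z$label == "oxidized")
  src <- which(z$label == "source")
  if (!length(ox) || !length(src)) return(NULL)
  best <- NULL
  for (i in ox) {
    j <- src[rec$depth_mbsf[src] > rec$depth_mbsf[i]]
    if (!length(j)) next
    sh <- rec$d13c_ch4_permil[i] - rec$d13c_ch4_permil[j]
    sep <- rec$depth_mbsf[j] - rec$depth_mbsf[i]
    for (k in seq_along(j)) {
      cand <- c(shift = sh[k], sep = sep[k], depthO = rec$depth_mbsf[i],
                i = i, j = j[k])
      if (is.null(best) ||
          cand["shift"] > best["shift"] + 1e-12 ||
          (abs(cand["shift"] - best["shift"]) <= 1e-12 &&
           (cand["sep"] < best["sep"] - 1e-12 ||
            (abs(cand["sep"] - best["sep"]) <= 1e-12 &&
             cand["depthO"] < best["depthO"]))))
        best <- cand
    }
  }
  if (is.null(best)) return(NULL)
  i <- best[["i"]]; j <- best[["j"]]
  IsotopeShift(deltaO = rec$d13c_ch4_permil[i],
               deltaP = rec$d13c_ch4_permil[j],
               depthO = rec$depth_mbsf[i], depthP = rec$depth_mbsf[j])
}

#' Detect a sulfate-methane transition zone
#'
#' Localizes the SMTZ as the depth interval bracketing the crossing of the
#' sulfate and methane profiles after each is normalized to its own maximum,
#' requiring opposing gradients across the interval (sulfate decreasing,
#' methane increasing with depth) and sulfate at the interval top of at
#' least `sulfateFloor`. Between measured depths the profiles are treated as
#' linear; the bracketing pair of measured depths is returned. The shallowest
#' qualifying crossing is reported.
#'
#' @param profile a [CoreProfile-class] with at least 3 horizons where both
#'   sulfate and methane were measured.
#' @param sulfateFloor mM; minimum sulfate at the interval top (default 1).
#' @return an [SmtzInterval-class], or `NULL` when no qualifying crossing
#'   exists.
#' @export
detectSmtz <- function(profile, sulfateFloor = 1.0) {
  stopifnot(is(profile, "CoreProfile"))
  rec <- profile@records
  ok <- !is.na(rec$so4_mM) & !is.na(rec$ch4_uM)
  if (sum(ok) < 3L)
    stop("insufficient data: need >= 3 horizons with both sulfate and methane")
  d <- rec$depth_mbsf[ok]
  su <- rec$so4_mM[ok]
  ch <- rec$ch4_uM[ok]
  if (max(su) <= 0 || max(ch) <= 0) return(NULL)
  sn <- su / max(su)
  cn <- ch / max(ch)
  for (k in seq_len(length(d) - 1L)) {
    opposing <- su[k + 1L] < su[k] && ch[k + 1L] > ch[k]
    crossing <- sn[k] >= cn[k] && sn[k + 1L] < cn[k + 1L]
    if (opposing && crossing && su[k] >= sulfateFloor)
      return(new("SmtzInterval", topMbsf = d[k], bottomMbsf = d[k + 1L],
                 sulfateAtTop = su[k], methaneAtBottom = ch[k + 1L]))
  }
  NULL
}
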