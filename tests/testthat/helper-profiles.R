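# quick profile builder for tests
makeProfile <- function(depth, d13c = NA_real_, ch4 = NA_real_,
                        so4 = NA_real_, ...) {
  CoreProfile(data.frame(depth_mbsf = depth, d13c_ch4_permil = d13c,
                         ch4_uM = ch4, so4_mM = so4, ...))
}

# independent brute-force oracle for the maximal isotope shift: exhaustive
# double loop over all ordered horizon pairs
bruteForceMaxShift <- function(profile, oxThreshold = -37,
                               sourceThreshold = -52) {
  rec <- records(profile)
  best <- NULL
  n <- nrow(rec)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    di <- rec$d13c_ch4_permil[i]; dj <- rec$d13c_ch4_permil[j]
    if (is.na(di) || is.na(dj)) next
    if (di < oxThreshold || dj > sourceThreshold) next
    if (rec$depth_mbsf[j] <= rec$depth_mbsf[i]) next
    s <- di - dj
    if (is.null(best) || s > best) best <- s
  }
  best
}
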