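# Spectrum-peptide match score: the sum of matched normalized peak
# intensities.  Deterministic, non-negative and monotone in the tolerance,
# which the downstream 80% candidate-retention rule and protein-feedback
# weighting rely on.

#' Score a theoretical ion list against a processed spectrum
#'
#' Each theoretical ion may match only its nearest experimental peak within a
#' ppm window (tie between two equidistant peaks: the lower m/z wins), and
#' each peak may be claimed by at most one ion; contested peaks go to the ion
#' with the smallest m/z distance (then lower ion m/z).  The score is the sum
#' of the normalized intensities of the matched peaks.
#'
#' @param ps A `processed_spectrum`.
#' @param ions Theoretical ion m/z values (numeric vector) or a data.frame
#'   with an `mz` column as produced by [fragment_with_site_mass()].
#' @param tol_ppm Match tolerance in ppm of the theoretical m/z.
#' @return List with `score`, `matched_ions`, `total_ions`.
#' @export
match_score <- function(ps, ions, tol_ppm = 20) {
  stopifnot(tol_ppm > 0)
  ion_mz <- if (is.data.frame(ions)) ions$mz else as.numeric(ions)
  total <- length(ion_mz)
  if (total == 0L || length(ps$mz) == 0L) {
    return(list(score = 0, matched_ions = 0L, total_ions = total))
  }
  pm <- ps$mz
  np <- length(pm)
  right <- findInterval(ion_mz, pm) + 1L          # first peak with mz >= ion
  left <- right - 1L
  d_left <- ifelse(left >= 1L, ion_mz - pm[pmax(left, 1L)], Inf)
  d_right <- ifelse(right <= np, pm[pmin(right, np)] - ion_mz, Inf)
  use_left <- d_left <= d_right                   # tie -> lower m/z peak
  peak <- ifelse(use_left, left, right)
  dist <- ifelse(use_left, d_left, d_right)
  ok <- which(is.finite(dist) & dist <= tol_ppm * 1e-6 * ion_mz)
  if (!length(ok)) {
    return(list(score = 0, matched_ions = 0L, total_ions = total))
  }
  ord <- ok[order(dist[ok], ion_mz[ok], ok, method = "radix")]
  taken <- logical(np)
  score <- 0
  matched <- 0L
  for (j in ord) {
    p <- peak[j]
    if (!taken[p]) {
      taken[p] <- TRUE
      score <- score + ps$intensity[p]
      matched <- matched + 1L
    }
  }
  list(score = score, matched_ions = matched, total_ions = total)
}
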