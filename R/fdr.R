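# Target-decoy FDR for cross-link spectrum matches.  A TD match contains one
# random peptide and a DD match two, so the decoy count double-counts unless
# corrected: the estimator is max(0, TD - DD) / TT over each score prefix
# (the xProphet-style accounting for cross-links).  FDR is computed on the
# spectral combined score, not the feedback score: feedback chooses which
# candidate represents a spectrum, while the spectral evidence ranks spectra,
# which keeps the null calibration free of circular feedback weights.

#' Assign q-values to cross-link spectrum matches
#'
#' Sorts by combined score (descending), computes the prefix FDR estimate
#' `max(0, TD - DD) / max(1, TT)`, and converts it to q-values by taking the
#' running minimum from the bottom rank upward.
#'
#' @param csms data.frame of CSMs with `combined_score` and `decoy_class`.
#' @return The same data.frame with a `q_value` column, original row order.
#' @export
assign_qvalues <- function(csms) {
  if (nrow(csms) == 0L) {
    csms$q_value <- numeric()
    return(csms)
  }
  tie_key <- if ("spectrum_id" %in% names(csms)) csms$spectrum_id else
    seq_len(nrow(csms))
  ord <- order(-csms$combined_score, tie_key, method = "radix")
  cls <- csms$decoy_class[ord]
  tt <- cumsum(cls == "TT")
  td <- cumsum(cls == "TD")
  dd <- cumsum(cls == "DD")
  fdr_hat <- pmax(0, td - dd) / pmax(1, tt)
  q <- rev(cummin(rev(fdr_hat)))
  csms$q_value <- NA_real_
  csms$q_value[ord] <- q
  csms
}

#' Report target-target CSMs at an FDR level
#'
#' @param csms data.frame with assigned `q_value`.
#' @param alpha FDR level (default 0.05).
#' @return Subset of target-target CSMs with `q_value <= alpha`; decoy-
#'   containing matches are never reported.
#' @export
filter_at_fdr <- function(csms, alpha = 0.05) {
  stopifnot(!is.null(csms$q_value))
  out <- csms[csms$decoy_class == "TT" & csms$q_value <= alpha, ,
              drop = FALSE]
  rownames(out) <- NULL
  out
}
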