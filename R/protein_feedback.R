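# The protein-feedback stage: confident first hits accumulate weight on their
# parent proteins, and each spectrum's cached candidates are then re-ranked by
# that protein-level evidence.  Peptides sharing a protein ("sibling"
# peptides) appear across many spectra, so a candidate from a well-supported
# protein is more plausible than an isolated one even when the spectral
# evidence alone cannot separate them.

#' Retain candidates scoring at least a fraction of the top one
#'
#' Keeps candidate pairs whose combined score is at least
#' `retain_ratio * top score`; the top candidate is always kept.
#'
#' @param r A `spectrum_result` (sorted descending by combined score).
#' @param retain_ratio Fraction of the top score required (default 0.8).
#' @return A filtered `spectrum_result`.
#' @export
filter_candidates <- function(r, retain_ratio = 0.8) {
  stopifnot(retain_ratio > 0, retain_ratio <= 1)
  cand <- r$candidates
  if (nrow(cand) > 1L) {
    keep <- cand$combined_score >= retain_ratio * cand$combined_score[1L]
    keep[1L] <- TRUE
    r$candidates <- cand[keep, , drop = FALSE]
    rownames(r$candidates) <- NULL
  }
  r
}

#' Collect confident first hits across all spectra
#'
#' Takes the rank-1 candidate of every non-empty spectrum, estimates q-values
#' over those first hits with the cross-link target-decoy estimator, and
#' returns the target-target hits at or above the score cutoff where the
#' estimated FDR is at most `firsthit_fdr`.  Decoy-containing (TD/DD) first
#' hits are never returned: they only serve the cutoff estimate.
#'
#' @param results List of `spectrum_result` objects (empty ones are skipped).
#' @param firsthit_fdr FDR level defining the data-driven score cutoff.
#' @return data.frame of accepted first hits (one row per spectrum), possibly
#'   empty.
#' @export
collect_first_hits <- function(results, firsthit_fdr = 0.10) {
  stopifnot(firsthit_fdr > 0, firsthit_fdr <= 1)
  nonempty <- Filter(function(r) nrow(r$candidates) > 0L, results)
  if (!length(nonempty)) return(empty_candidates())
  first <- do.call(rbind, lapply(nonempty, function(r) {
    row <- r$candidates[1L, , drop = FALSE]
    row$spectrum_id <- r$spectrum_id
    row
  }))
  rownames(first) <- NULL
  first <- assign_qvalues(first)
  hits <- first[first$q_value <= firsthit_fdr & first$decoy_class == "TT", ,
                drop = FALSE]
  if (nrow(hits) == 0L) {
    warning("no first hit passes the ", firsthit_fdr,
            " FDR cutoff; protein feedback will be a no-op")
  }
  rownames(hits) <- NULL
  hits
}

#' Accumulate protein scores from confident first hits
#'
#' Each accepted first hit credits the individual site score of each of its
#' two peptides to every parent protein of that peptide (shared peptides
#' credit all parents).  Only target proteins accumulate weight (TD/DD hits
#' are excluded upstream); at lookup time a decoy protein reads back its
#' target mirror's weight (see [protein_score()]), which keeps target/decoy
#' competition symmetric during re-ranking and hence keeps the target-decoy
#' FDR estimate honest.
#'
#' @param hits data.frame from [collect_first_hits()].
#' @return Named numeric vector of protein weights (class
#'   `protein_score_db`); absent accessions read as 0 via [protein_score()].
#' @export
build_protein_scores <- function(hits) {
  prot <- c(unlist(hits$alpha_proteins, use.names = FALSE),
            unlist(hits$beta_proteins, use.names = FALSE))
  w <- c(rep(hits$alpha_score, lengths(hits$alpha_proteins)),
         rep(hits$beta_score, lengths(hits$beta_proteins)))
  if (!length(prot)) {
    return(structure(numeric(), class = "protein_score_db"))
  }
  db <- vapply(split(w, prot), sum, 0)
  structure(db, class = "protein_score_db")
}

#' Look up the feedback weight of a peptide's parent proteins
#'
#' A decoy accession (`REV_` prefix) reads back the weight of its target
#' mirror.  Decoys are built by reversing target proteins, so the mirrored
#' weight keeps re-ranking competition between a target candidate and an
#' equally (un)supported decoy candidate symmetric; without it, feedback
#' would steer every ambiguous spectrum onto a target pair, deflate the TD
#' count, and make the downstream target-decoy FDR estimate anti-conservative.
#'
#' @param db A `protein_score_db`.
#' @param proteins Character vector of accessions.
#' @return The maximum accumulated weight over the parents (0 if none known).
#' @export
protein_score <- function(db, proteins) {
  if (!length(db) || !length(proteins)) return(0)
  w <- db[sub("^REV_", "", proteins)]
  w[is.na(w)] <- 0
  max(w)
}

#' Re-rank a spectrum's candidates by protein feedback
#'
#' The feedback score of a candidate pair is
#' `log(1 + PS(alpha)) + log(1 + PS(beta))` where `PS` is the maximum parent
#' protein weight of the peptide ([protein_score()]).  Candidates are
#' re-ranked by `combined_score + feedback_score`: the protein-level evidence
#' adjusts the spectral evidence rather than replacing it, so a candidate
#' from a well-supported protein overtakes the top hit only when the spectral
#' margin is small — exactly the ambiguous, fragmentation-starved case the
#' mechanism targets.  With an empty database all feedback terms are 0 and
#' the original top pair wins (identity property).  Ties break toward higher
#' combined score, then alpha/beta sequence.
#'
#' @param r A (filtered) `spectrum_result`.
#' @param db A `protein_score_db`.
#' @return One-row data.frame: the winning candidate annotated with
#'   `spectrum_id` and `feedback_score` (the log-weight term), or NULL for an
#'   empty result.
#' @export
rerank_candidates <- function(r, db) {
  cand <- r$candidates
  if (nrow(cand) == 0L) return(NULL)
  fs <- vapply(seq_len(nrow(cand)), function(i) {
    log1p(protein_score(db, cand$alpha_proteins[[i]])) +
      log1p(protein_score(db, cand$beta_proteins[[i]]))
  }, 0)
  best <- order(-(cand$combined_score + fs), -cand$combined_score,
                cand$alpha_seq, cand$beta_seq, method = "radix")[1L]
  out <- cand[best, , drop = FALSE]
  out$feedback_score <- fs[best]
  out$spectrum_id <- r$spectrum_id
  rownames(out) <- NULL
  out
}
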