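# Per-spectrum candidate enumeration: score every mass-eligible peptide once
# (the partner rides as an opaque mass offset, so a peptide's score does not
# depend on which partner it later pairs with), then sweep the mass-sorted
# score table for peptide pairs satisfying the precursor mass constraint and
# keep the top-N by combined score.

#' Score all eligible peptides against a spectrum (non-cleavable linker)
#'
#' For every indexed peptide light enough to leave room for a partner, the
#' site-localized offset is `delta = neutral_mass - mono_mass(p)` (partner
#' plus intact linker); the best-scoring link site is kept per peptide.
#'
#' @param ps A `processed_spectrum`.
#' @param index A `peptide_index`.
#' @param linker A `linker_spec` (non-cleavable).
#' @param ms2_tol_ppm Fragment match tolerance (ppm).
#' @param min_peptide_mass Smallest partner mass that must remain (Da);
#'   defaults to the index lower mass bound.
#' @param max_frag_charge Fragment charges searched.
#' @return data.frame of peptide-site scores, mass-sorted, one row per
#'   eligible peptide: `pep` (index row), `sequence`, `mono_mass`, `site`,
#'   `score`, `matched`, `stub`, `is_decoy`, `proteins`.  Attribute `n_eval`
#'   counts (site, delta) evaluations for work accounting.
#' @export
score_peptides_noncleavable <- function(ps, index, linker, ms2_tol_ppm = 20,
                                        min_peptide_mass = NULL,
                                        max_frag_charge = 2L) {
  linker <- get_linker(linker)
  if (linker$cleavable) stop("linker is cleavable; use the cleavable mode")
  if (is.null(min_peptide_mass)) min_peptide_mass <- index$mass_range[1L]
  bound <- ps$neutral_mass - linker$intact_mass - min_peptide_mass
  k <- findInterval(bound, index$peptides$mono_mass)
  if (k < 1L) return(empty_site_scores())
  deltas <- ps$neutral_mass - index$peptides$mono_mass[seq_len(k)]
  .score_prefix(ps, index, k, deltas, NULL, ms2_tol_ppm, max_frag_charge)
}

#' Score all eligible peptides against a spectrum (MS-cleavable linker)
#'
#' Each peptide is scored under both the short and long stub; the best
#' (site, stub) combination is kept, ties resolved toward the short stub.
#'
#' @inheritParams score_peptides_noncleavable
#' @param linker A cleavable `linker_spec`.
#' @return As [score_peptides_noncleavable()], with `stub` set to
#'   `"short"`/`"long"`.
#' @export
score_peptides_cleavable <- function(ps, index, linker, ms2_tol_ppm = 20,
                                     min_peptide_mass = NULL,
                                     max_frag_charge = 2L) {
  linker <- get_linker(linker)
  if (!linker$cleavable) stop("linker is not cleavable")
  if (is.null(min_peptide_mass)) min_peptide_mass <- index$mass_range[1L]
  bound <- ps$neutral_mass - linker$intact_mass - min_peptide_mass
  k <- findInterval(bound, index$peptides$mono_mass)
  if (k < 1L) return(empty_site_scores())
  d1 <- rep(linker$stub_short, k)
  d2 <- rep(linker$stub_long, k)
  .score_prefix(ps, index, k, d1, d2, ms2_tol_ppm, max_frag_charge)
}

empty_site_scores <- function() {
  data.frame(pep = integer(), sequence = character(), mono_mass = numeric(),
             site = integer(), score = numeric(), matched = integer(),
             stub = character(), is_decoy = logical(),
             proteins = I(list()), stringsAsFactors = FALSE)
}

.score_prefix <- function(ps, index, k, delta1, delta2, tol_ppm, max_charge) {
  res_end <- index$pep_off[k + 1L]
  site_end <- index$site_off[k + 1L]
  m <- .score_sites_kernel(
    ps$mz, ps$intensity,
    index$res_flat[seq_len(res_end)], index$pep_off[seq_len(k + 1L)],
    index$site_flat[seq_len(site_end)], index$site_off[seq_len(k + 1L)],
    delta1, if (is.null(delta2)) numeric() else delta2,
    tol_ppm, as.integer(max_charge), MASS_PROTON, MASS_WATER)
  pep <- index$peptides[seq_len(k), ]
  out <- data.frame(
    pep = seq_len(k), sequence = pep$sequence, mono_mass = pep$mono_mass,
    site = as.integer(m[, 2L]), score = m[, 1L],
    matched = as.integer(m[, 4L]),
    stub = if (is.null(delta2)) NA_character_ else
      c("short", "long")[m[, 3L]],
    is_decoy = pep$is_decoy, stringsAsFactors = FALSE)
  out$proteins <- pep$proteins
  n_sites <- index$site_off[2L:(k + 1L)] - index$site_off[seq_len(k)]
  attr(out, "n_eval") <- sum(n_sites) * (if (is.null(delta2)) 1L else 2L)
  out
}

#' Detect cleavable-linker signature doublets
#'
#' Scans for peak pairs separated by (long - short)/z for assumed charges 1
#' and 2.  Each pair yields a hypothesis for one constituent peptide's neutral
#' mass, `z * (mz_low - proton) - short`, with the summed normalized intensity
#' of the two peaks as evidence.
#'
#' @param ps A `processed_spectrum`.
#' @param linker A cleavable `linker_spec`.
#' @param tol_ppm Doublet spacing tolerance in ppm (of the heavier peak).
#' @return data.frame with `mass`, `evidence`, `charge` (possibly 0 rows).
#' @export
detect_doublets <- function(ps, linker, tol_ppm = 20) {
  linker <- get_linker(linker)
  if (!linker$cleavable) stop("doublet search requires a cleavable linker")
  spacing0 <- linker$stub_long - linker$stub_short
  mz <- ps$mz
  out <- list()
  for (z in 1:2) {
    spacing <- spacing0 / z
    target <- mz + spacing
    tol <- tol_ppm * 1e-6 * target
    from <- findInterval(target - tol, mz, left.open = TRUE) + 1L
    to <- findInterval(target + tol, mz)
    has <- which(from <= to)
    for (i in has) {
      js <- from[i]:to[i]
      out[[length(out) + 1L]] <- data.frame(
        mass = z * (mz[i] - MASS_PROTON) - linker$stub_short,
        evidence = ps$intensity[i] + ps$intensity[js],
        charge = z)
    }
  }
  if (!length(out)) {
    return(data.frame(mass = numeric(), evidence = numeric(),
                      charge = integer()))
  }
  res <- do.call(rbind, out)
  res[res$mass > 0, , drop = FALSE]
}

#' Rank candidate cross-linked pairs for one spectrum
#'
#' Enumerates all unordered peptide pairs whose summed mass matches the
#' precursor-derived target `T = neutral_mass - intact linker` within the MS1
#' tolerance (ppm of the observed neutral mass), ranks them by combined score
#' and returns the top `N`.  Homodimers (a peptide paired with a second copy
#' of itself) are allowed by default.  In cleavable mode, a candidate gains
#' `doublet_bonus * evidence` for every signature-doublet hypothesis matching
#' either peptide's mass.  Alpha is the higher-scoring peptide of a pair
#' (score ties: lexicographically smaller sequence).
#'
#' @param scores Site-score table from one of the `score_peptides_*`
#'   functions (must be sorted ascending by `mono_mass`).
#' @param ps The `processed_spectrum`.
#' @param linker The `linker_spec` used for scoring.
#' @param N Number of candidate pairs cached.
#' @param ms1_tol_ppm Precursor tolerance (ppm of the observed neutral mass).
#' @param ms2_tol_ppm Tolerance for matching doublet hypotheses to peptide
#'   masses (ppm).
#' @param doublet_bonus Weight of doublet evidence (0 disables).
#' @param doublets Optional [detect_doublets()] table.
#' @param homodimers Allow self-pairs.
#' @return A `spectrum_result`: list with `spectrum_id`, `neutral_mass`, and
#'   `candidates` (data.frame sorted by combined score desc, then alpha and
#'   beta sequence).
#' @export
top_pairs <- function(scores, ps, linker, N = 20L, ms1_tol_ppm = 10,
                      ms2_tol_ppm = 20, doublet_bonus = 1,
                      doublets = NULL, homodimers = TRUE) {
  linker <- get_linker(linker)
  empty <- structure(list(spectrum_id = ps$spectrum_id,
                          neutral_mass = ps$neutral_mass,
                          candidates = empty_candidates()),
                     class = "spectrum_result")
  n <- nrow(scores)
  if (n < 1L) return(empty)
  m <- scores$mono_mass
  if (is.unsorted(m)) stop("score table must be sorted by mono_mass")
  target <- ps$neutral_mass - linker$intact_mass
  tol_da <- ms1_tol_ppm * 1e-6 * ps$neutral_mass

  lo <- findInterval(target - m - tol_da, m, left.open = TRUE) + 1L
  hi <- findInterval(target - m + tol_da, m)
  lo <- pmax(lo, seq_len(n))                     # unordered: j >= i
  valid <- which(lo <= hi)
  if (!length(valid)) return(empty)
  i_idx <- rep(valid, hi[valid] - lo[valid] + 1L)
  j_idx <- unlist(lapply(valid, function(i) lo[i]:hi[i]), use.names = FALSE)
  keep <- abs(m[i_idx] + m[j_idx] - target) <= tol_da
  if (!homodimers) keep <- keep & i_idx != j_idx
  i_idx <- i_idx[keep]; j_idx <- j_idx[keep]
  if (!length(i_idx)) return(empty)

  bonus <- numeric(length(i_idx))
  if (linker$cleavable && doublet_bonus > 0 && !is.null(doublets) &&
      nrow(doublets)) {
    hyp <- doublets[order(doublets$mass), , drop = FALSE]
    ev_for <- function(mass) {
      tol <- ms2_tol_ppm * 1e-6 * mass
      a <- findInterval(mass - tol, hyp$mass, left.open = TRUE) + 1L
      b <- findInterval(mass + tol, hyp$mass)
      if (a > b) 0 else sum(hyp$evidence[a:b])
    }
    ev <- vapply(unique(c(i_idx, j_idx)), function(i) ev_for(m[i]), 0)
    names(ev) <- as.character(unique(c(i_idx, j_idx)))
    bonus <- doublet_bonus *
      (ev[as.character(i_idx)] + ev[as.character(j_idx)])
  }

  s_i <- scores$score[i_idx]; s_j <- scores$score[j_idx]
  seq_i <- scores$sequence[i_idx]; seq_j <- scores$sequence[j_idx]
  # alpha = higher score; ties -> lexicographically smaller sequence
  a_first <- s_i > s_j | (s_i == s_j & seq_i <= seq_j)
  ai <- ifelse(a_first, i_idx, j_idx)
  bi <- ifelse(a_first, j_idx, i_idx)

  cand <- data.frame(
    alpha_seq = scores$sequence[ai], alpha_site = scores$site[ai],
    alpha_score = scores$score[ai], alpha_mass = scores$mono_mass[ai],
    alpha_is_decoy = scores$is_decoy[ai], alpha_stub = scores$stub[ai],
    beta_seq = scores$sequence[bi], beta_site = scores$site[bi],
    beta_score = scores$score[bi], beta_mass = scores$mono_mass[bi],
    beta_is_decoy = scores$is_decoy[bi], beta_stub = scores$stub[bi],
    doublet_evidence = unname(bonus),
    stringsAsFactors = FALSE)
  cand$alpha_proteins <- scores$proteins[ai]
  cand$beta_proteins <- scores$proteins[bi]
  cand$combined_score <- cand$alpha_score + cand$beta_score +
    cand$doublet_evidence
  cand$mass_error_ppm <- (cand$alpha_mass + cand$beta_mass +
                            linker$intact_mass - ps$neutral_mass) /
    ps$neutral_mass * 1e6
  cand$decoy_class <- ifelse(
    cand$alpha_is_decoy & cand$beta_is_decoy, "DD",
    ifelse(!cand$alpha_is_decoy & !cand$beta_is_decoy, "TT", "TD"))

  ord <- order(-cand$combined_score, cand$alpha_seq, cand$beta_seq,
               method = "radix")
  cand <- cand[head(ord, N), , drop = FALSE]
  rownames(cand) <- NULL
  structure(list(spectrum_id = ps$spectrum_id,
                 neutral_mass = ps$neutral_mass, candidates = cand),
            class = "spectrum_result")
}

empty_candidates <- function() {
  df <- data.frame(
    alpha_seq = character(), alpha_site = integer(), alpha_score = numeric(),
    alpha_mass = numeric(), alpha_is_decoy = logical(),
    alpha_stub = character(),
    beta_seq = character(), beta_site = integer(), beta_score = numeric(),
    beta_mass = numeric(), beta_is_decoy = logical(), beta_stub = character(),
    doublet_evidence = numeric(), stringsAsFactors = FALSE)
  df$alpha_proteins <- list()
  df$beta_proteins <- list()
  df$combined_score <- numeric()
  df$mass_error_ppm <- numeric()
  df$decoy_class <- character()
  df
}
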