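# Pipeline orchestration: configuration, the expensive per-spectrum candidate
# search, the feedback + FDR finishing stages, and result serialization.
# The candidate stage and the finishing stage are exposed separately so the
# same cached candidates can be finished with and without feedback.

#' Search configuration
#'
#' @param fasta_path Protein database (targets only; decoys are generated).
#' @param mgf_path MS/MS spectra (MGF).
#' @param mode `"noncleavable"` or `"cleavable"` search.
#' @param linker Linker name (see [builtin_linkers()]) or a `linker_spec`;
#'   must agree with `mode`.
#' @param ms1_tol_ppm Precursor (pair mass) tolerance, ppm.
#' @param ms2_tol_ppm Fragment tolerance, ppm.
#' @param top_n Candidate pairs cached per spectrum.
#' @param retain_ratio Candidate filter: fraction of the top combined score.
#' @param firsthit_fdr FDR level of the data-driven first-hit cutoff feeding
#'   the protein score database.
#' @param final_fdr Reported CSM FDR level.
#' @param feedback_enabled Apply protein-feedback re-ranking.
#' @param max_missed,min_len,max_len,pep_mass_range,allow_cterm_k,cys_cam
#'   Digestion/indexing parameters (see [digest()] and [build_index()]).
#' @param top_k,window Spectrum preprocessing (see [preprocess_spectrum()]).
#' @param min_charge Minimum precursor charge read from the MGF.
#' @param doublet_bonus Weight of signature-doublet evidence (cleavable).
#' @param homodimers Allow self-pairs.
#' @param output_path Optional TSV path written by [run_search()].
#' @return Object of class `search_config`.
#' @export
search_config <- function(fasta_path, mgf_path,
                          mode = c("noncleavable", "cleavable"),
                          linker = NULL, ms1_tol_ppm = 10, ms2_tol_ppm = 20,
                          top_n = 20L, retain_ratio = 0.8,
                          firsthit_fdr = 0.10, final_fdr = 0.05,
                          feedback_enabled = TRUE,
                          max_missed = 2L, min_len = 5L, max_len = 50L,
                          pep_mass_range = c(500, 6000),
                          allow_cterm_k = TRUE, cys_cam = TRUE,
                          top_k = 10L, window = 100, min_charge = 3L,
                          doublet_bonus = 1, homodimers = TRUE,
                          output_path = NULL) {
  mode <- match.arg(mode)
  if (is.null(linker)) linker <- if (mode == "cleavable") "DSSO" else "DSS"
  linker <- get_linker(linker)
  if (linker$cleavable != (mode == "cleavable")) {
    stop("linker '", linker$name, "' does not match mode '", mode, "'")
  }
  stopifnot(ms1_tol_ppm > 0, ms2_tol_ppm > 0, top_n >= 1L,
            retain_ratio > 0, retain_ratio <= 1)
  structure(list(fasta_path = fasta_path, mgf_path = mgf_path, mode = mode,
                 linker = linker, ms1_tol_ppm = ms1_tol_ppm,
                 ms2_tol_ppm = ms2_tol_ppm, top_n = as.integer(top_n),
                 retain_ratio = retain_ratio, firsthit_fdr = firsthit_fdr,
                 final_fdr = final_fdr, feedback_enabled = feedback_enabled,
                 max_missed = max_missed, min_len = min_len,
                 max_len = max_len, pep_mass_range = pep_mass_range,
                 allow_cterm_k = allow_cterm_k, cys_cam = cys_cam,
                 top_k = top_k, window = window, min_charge = min_charge,
                 doublet_bonus = doublet_bonus, homodimers = homodimers,
                 output_path = output_path),
            class = "search_config")
}

#' Run the candidate search stage
#'
#' Reads and digests the database (targets plus reversed decoys), reads the
#' spectra, and caches the top-N candidate pairs of every spectrum.
#'
#' @param cfg A `search_config`.
#' @param verbose Log stage progress to stderr.
#' @return List with `results` (list of `spectrum_result`), `index`,
#'   `n_spectra`, and `cfg`.
#' @export
collect_candidates <- function(cfg, verbose = FALSE) {
  say <- function(...) if (verbose) message("[xlinkr] ", ...)
  say("reading FASTA: ", cfg$fasta_path)
  proteins <- generate_decoys(read_fasta(cfg$fasta_path))
  say(nrow(proteins), " proteins incl. decoys; digesting")
  peptides <- digest_proteins(proteins, max_missed = cfg$max_missed,
                              min_len = cfg$min_len, max_len = cfg$max_len,
                              linker_residues = cfg$linker$reactive_residues,
                              allow_cterm_k = cfg$allow_cterm_k,
                              cys_cam = cfg$cys_cam)
  index <- build_index(peptides, mass_range = cfg$pep_mass_range,
                       cys_cam = cfg$cys_cam)
  say(nrow(index$peptides), " indexed peptides")
  spectra <- read_mgf(cfg$mgf_path, min_charge = cfg$min_charge)
  say(length(spectra), " spectra; searching (mode: ", cfg$mode, ", linker: ",
      cfg$linker$name, ")")

  results <- vector("list", length(spectra))
  for (i in seq_along(spectra)) {
    ps <- preprocess_spectrum(spectra[[i]], top_k = cfg$top_k,
                              window = cfg$window)
    if (cfg$mode == "noncleavable") {
      scores <- score_peptides_noncleavable(ps, index, cfg$linker,
                                            ms2_tol_ppm = cfg$ms2_tol_ppm)
      doublets <- NULL
    } else {
      scores <- score_peptides_cleavable(ps, index, cfg$linker,
                                         ms2_tol_ppm = cfg$ms2_tol_ppm)
      doublets <- detect_doublets(ps, cfg$linker, tol_ppm = cfg$ms2_tol_ppm)
    }
    results[[i]] <- top_pairs(scores, ps, cfg$linker, N = cfg$top_n,
                              ms1_tol_ppm = cfg$ms1_tol_ppm,
                              ms2_tol_ppm = cfg$ms2_tol_ppm,
                              doublet_bonus = cfg$doublet_bonus,
                              doublets = doublets,
                              homodimers = cfg$homodimers)
  }
  say(sum(vapply(results, function(r) nrow(r$candidates) > 0L, NA)),
      " spectra with candidate pairs")
  list(results = results, index = index, n_spectra = length(spectra),
       cfg = cfg)
}

#' Run the feedback and FDR stages on cached candidates
#'
#' @param cands Output of [collect_candidates()].
#' @param feedback_enabled Apply protein-feedback re-ranking; when `FALSE`
#'   the rank-1 candidate of each spectrum proceeds directly to FDR.
#' @param db_override Optional `protein_score_db` used instead of the one
#'   built from first hits (for diagnostics; an all-zero database reproduces
#'   the no-feedback ranking exactly).
#' @param verbose Log stage progress.
#' @return List with `csms` (all CSMs with q-values), `accepted` (target-
#'   target CSMs at the configured FDR), `protein_db`, and `report` (named
#'   stage counts).
#' @export
finish_search <- function(cands, feedback_enabled = cands$cfg$feedback_enabled,
                          db_override = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message("[xlinkr] ", ...)
  cfg <- cands$cfg
  results <- Filter(function(r) nrow(r$candidates) > 0L, cands$results)
  n_candidates <- sum(vapply(results, function(r) nrow(r$candidates), 0L))
  filtered <- lapply(results, filter_candidates,
                     retain_ratio = cfg$retain_ratio)
  n_filtered <- sum(vapply(filtered, function(r) nrow(r$candidates), 0L))

  if (feedback_enabled || !is.null(db_override)) {
    if (is.null(db_override)) {
      hits <- collect_first_hits(filtered, firsthit_fdr = cfg$firsthit_fdr)
      db <- build_protein_scores(hits)
      n_hits <- nrow(hits)
    } else {
      db <- db_override
      n_hits <- NA_integer_
    }
    say(length(db), " proteins in the feedback score database")
    csms <- do.call(rbind, lapply(filtered, rerank_candidates, db = db))
  } else {
    db <- structure(numeric(), class = "protein_score_db")
    n_hits <- 0L
    csms <- do.call(rbind, lapply(filtered, function(r) {
      out <- r$candidates[1L, , drop = FALSE]
      out$feedback_score <- 0
      out$spectrum_id <- r$spectrum_id
      out
    }))
  }
  rownames(csms) <- NULL
  csms <- assign_qvalues(csms)
  accepted <- filter_at_fdr(csms, alpha = cfg$final_fdr)
  say(nrow(accepted), " CSMs accepted at ", cfg$final_fdr, " FDR")
  report <- c(spectra_searched = cands$n_spectra,
              spectra_with_candidates = length(results),
              candidates_cached = n_candidates,
              candidates_after_filter = n_filtered,
              first_hits_in_db = n_hits,
              proteins_with_weight = length(db),
              csms_total = nrow(csms),
              csms_accepted = nrow(accepted))
  list(csms = csms, accepted = accepted, protein_db = db, report = report)
}

#' Run the full cross-link search pipeline
#'
#' read FASTA -> decoys -> digest -> index -> per-spectrum candidate search ->
#' 80% candidate filter -> confident first hits -> protein score database ->
#' feedback re-rank -> target-decoy q-values -> FDR filter -> TSV.
#'
#' @param cfg A `search_config`.
#' @param verbose Log stage progress and counts to stderr.
#' @return As [finish_search()], plus `cfg`; if `cfg$output_path` is set the
#'   accepted CSMs are written there as TSV.
#' @export
run_search <- function(cfg, verbose = FALSE) {
  cands <- collect_candidates(cfg, verbose = verbose)
  out <- finish_search(cands, feedback_enabled = cfg$feedback_enabled,
                       verbose = verbose)
  out$cfg <- cfg
  if (!is.null(cfg$output_path)) {
    write_results(out$accepted, cfg$output_path)
    if (verbose) message("[xlinkr] wrote ", cfg$output_path)
  }
  out
}

#' Write reported CSMs as a 12-column TSV
#'
#' Sites are printed 1-based (0-based internally); parent proteins are
#' semicolon-joined.  Fixed numeric formatting makes identical runs produce
#' byte-identical files.
#'
#' @param csms data.frame of CSMs with q-values.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_results <- function(csms, path) {
  cols <- c("spectrum_id", "alpha_peptide", "alpha_site", "alpha_proteins",
            "beta_peptide", "beta_site", "beta_proteins", "combined_score",
            "feedback_score", "mass_error_ppm", "decoy_class", "q_value")
  if (nrow(csms) == 0L) {
    writeLines(paste(cols, collapse = "\t"), path)
    return(invisible(path))
  }
  join <- function(l) vapply(l, paste, "", collapse = ";")
  out <- data.frame(
    spectrum_id = csms$spectrum_id,
    alpha_peptide = csms$alpha_seq,
    alpha_site = csms$alpha_site + 1L,
    alpha_proteins = join(csms$alpha_proteins),
    beta_peptide = csms$beta_seq,
    beta_site = csms$beta_site + 1L,
    beta_proteins = join(csms$beta_proteins),
    combined_score = sprintf("%.6f", csms$combined_score),
    feedback_score = sprintf("%.6f", csms$feedback_score),
    mass_error_ppm = sprintf("%.4f", csms$mass_error_ppm),
    decoy_class = csms$decoy_class,
    q_value = sprintf("%.6g", csms$q_value),
    stringsAsFactors = FALSE)
  names(out) <- cols
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
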