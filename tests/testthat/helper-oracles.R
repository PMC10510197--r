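# Independent oracles and small fixture builders used across the suite.

# Residue monoisotopic masses, typed independently from a published table,
# used only for cross-checking the package's mass arithmetic.
ORACLE_AA <- c(
  A = 71.037114, R = 156.101111, N = 114.042927, D = 115.026943,
  C = 103.009185, E = 129.042593, Q = 128.058578, G = 57.021464,
  H = 137.058912, I = 113.084064, L = 113.084064, K = 128.094963,
  M = 131.040485, F = 147.068414, P = 97.052764, S = 87.032028,
  T = 101.047678, W = 186.079313, Y = 163.063329, V = 99.068414)
ORACLE_WATER <- 18.0105646837
ORACLE_PROTON <- 1.00727646677
ORACLE_CAM <- 57.021464

oracle_peptide_mass <- function(seq, cys_cam = TRUE) {
  aa <- strsplit(seq, "")[[1]]
  m <- sum(ORACLE_AA[aa]) + ORACLE_WATER
  if (cys_cam) m <- m + ORACLE_CAM * sum(aa == "C")
  unname(m)
}

# Minimal processed-spectrum constructor for scorer tests.
make_ps <- function(mz, intensity = rep(1, length(mz)), neutral_mass = 3000,
                    id = "test") {
  o <- order(mz)
  structure(list(spectrum_id = id, neutral_mass = neutral_mass, charge = 3L,
                 precursor_mz = (neutral_mass + 3 * ORACLE_PROTON) / 3,
                 mz = mz[o], intensity = intensity[o]),
            class = "processed_spectrum")
}

# Exhaustive optimal one-to-one assignment between ions and in-tolerance
# peaks, maximizing the summed matched intensity.  Ions may use any peak
# within tolerance (not only the nearest), so this upper-bounds the greedy
# nearest-peak rule the scorer specifies.
oracle_best_assignment <- function(ion_mz, peak_mz, peak_int, tol_ppm) {
  compat <- lapply(ion_mz, function(v)
    which(abs(peak_mz - v) <= tol_ppm * 1e-6 * v))
  n <- length(ion_mz)
  best <- 0
  rec <- function(i, used, acc) {
    if (i > n) {
      best <<- max(best, acc)
      return()
    }
    rec(i + 1, used, acc)  # leave ion i unmatched
    for (p in compat[[i]]) {
      if (!(p %in% used)) rec(i + 1, c(used, p), acc + peak_int[p])
    }
  }
  rec(1L, integer(), 0)
  best
}

# Brute-force all-pairs ranking oracle for top_pairs (no doublet bonus).
oracle_top_pairs <- function(scores, ps, linker, N, ms1_tol_ppm,
                             homodimers = TRUE) {
  linker <- get_linker(linker)
  target <- ps$neutral_mass - linker$intact_mass
  tol <- ms1_tol_ppm * 1e-6 * ps$neutral_mass
  n <- nrow(scores)
  sums <- outer(scores$mono_mass, scores$mono_mass, "+")
  idx <- which(abs(sums - target) <= tol, arr.ind = TRUE)
  idx <- idx[idx[, 1] <= idx[, 2], , drop = FALSE]
  if (!homodimers) idx <- idx[idx[, 1] != idx[, 2], , drop = FALSE]
  if (nrow(idx) == 0L) {
    return(data.frame(alpha_seq = character(), beta_seq = character(),
                      combined_score = numeric()))
  }
  i <- idx[, 1]; j <- idx[, 2]
  s_i <- scores$score[i]; s_j <- scores$score[j]
  a_first <- s_i > s_j | (s_i == s_j & scores$sequence[i] <= scores$sequence[j])
  ai <- ifelse(a_first, i, j); bi <- ifelse(a_first, j, i)
  out <- data.frame(alpha_seq = scores$sequence[ai],
                    alpha_site = scores$site[ai],
                    alpha_score = scores$score[ai],
                    beta_seq = scores$sequence[bi],
                    beta_site = scores$site[bi],
                    beta_score = scores$score[bi],
                    combined_score = s_i + s_j,
                    stringsAsFactors = FALSE)
  ord <- order(-out$combined_score, out$alpha_seq, out$beta_seq,
               method = "radix")
  out <- out[head(ord, N), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Random score table (mass-sorted) emulating score_peptides_* output.
random_score_table <- function(n, mass_range = c(500, 2500)) {
  seqs <- unique(replicate(n, paste(sample(names(ORACLE_AA), 8, TRUE),
                                    collapse = "")))
  n <- length(seqs)
  m <- sort(runif(n, mass_range[1], mass_range[2]))
  df <- data.frame(pep = seq_len(n), sequence = seqs, mono_mass = m,
                   site = sample(0:5, n, TRUE),
                   score = round(runif(n, 0, 10), 3),
                   matched = 0L, stub = NA_character_,
                   is_decoy = sample(c(TRUE, FALSE), n, TRUE),
                   stringsAsFactors = FALSE)
  df$proteins <- as.list(paste0("P", seq_len(n)))
  df
}

# Tiny deterministic fixture for end-to-end tests.
small_fixture <- function(dir, seed = 7, n_xl = 40L, n_null = 15L,
                          n_proteins = 15L, ...) {
  cfg <- sim_config(n_proteins = n_proteins, protein_len = c(150L, 250L),
                    n_xl_spectra = n_xl, n_null_spectra = n_null,
                    seed = seed, ...)
  generate_fixture(cfg, dir)
}
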