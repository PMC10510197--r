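# Synthetic XL-MS fixture generator.  It emulates the statistical structure
# the feedback mechanism targets: cross-linked precursors whose heavier
# peptide fragments well while the lighter one is starved of ions in a
# spectrum-dependent way, plus null spectra drawn from peptides absent from
# the searched database.
#
# Fragmentation model: each peptide of a pair gets a per-spectrum
# fragmentation efficiency drawn from a Beta distribution with mean p_frag_*
# and concentration 1.5, and its theoretical ions are then retained i.i.d. at
# that rate.  The marginal per-ion detection probability equals p_frag_*, but
# the spectrum-level correlation reproduces the real co-fragmentation
# phenomenon where some spectra contain essentially no fragments of the
# lighter peptide.  Lighter-peptide fragments are also drawn ~5x weaker.

BETA_CONCENTRATION <- 1.5
INT_SCALE_HEAVY <- 1000
INT_SCALE_LIGHT <- 200
INT_SCALE_NOISE <- 150
INT_SCALE_DOUBLET <- 800

#' Simulation configuration
#'
#' @param n_proteins Number of target proteins.
#' @param protein_len Length range (residues), inclusive.
#' @param n_xl_spectra Cross-linked spectra with ground truth.
#' @param n_null_spectra Spectra generated from a foreign proteome absent
#'   from the searched database.
#' @param p_frag_light,p_frag_heavy Marginal per-ion detection probability for
#'   the lighter / heavier peptide of each pair.
#' @param noise_peaks Uniform random noise peaks per spectrum.
#' @param ppm_error_sd Gaussian m/z error (ppm) on fragments and precursors.
#' @param seed RNG seed; the whole fixture is deterministic given it.
#' @param mode `"noncleavable"` or `"cleavable"` fragmentation.
#' @param linker Linker name or `linker_spec` (must match `mode`).
#' @param doublet_prob Probability that a peptide's signature doublet appears
#'   (cleavable mode only).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 50L, protein_len = c(200L, 400L),
                       n_xl_spectra = 300L, n_null_spectra = 100L,
                       p_frag_light = 0.3, p_frag_heavy = 0.9,
                       noise_peaks = 60L, ppm_error_sd = 5, seed = 42L,
                       mode = c("noncleavable", "cleavable"),
                       linker = NULL, doublet_prob = 0.8) {
  mode <- match.arg(mode)
  if (is.null(linker)) linker <- if (mode == "cleavable") "DSSO" else "DSS"
  linker <- get_linker(linker)
  stopifnot(p_frag_light >= 0, p_frag_light <= 1,
            p_frag_heavy >= 0, p_frag_heavy <= 1,
            (mode == "cleavable") == linker$cleavable)
  structure(list(n_proteins = n_proteins, protein_len = protein_len,
                 n_xl_spectra = n_xl_spectra,
                 n_null_spectra = n_null_spectra,
                 p_frag_light = p_frag_light, p_frag_heavy = p_frag_heavy,
                 noise_peaks = noise_peaks, ppm_error_sd = ppm_error_sd,
                 seed = seed, mode = mode, linker = linker,
                 doublet_prob = doublet_prob),
            class = "sim_config")
}

# Amino-acid sampling frequencies: roughly proteome-like, with K and R both
# boosted to 8% so tryptic and cross-link sites are plentiful.
AA_FREQ <- c(A = 7.4, C = 1.4, D = 5.2, E = 6.2, F = 3.9, G = 7.0, H = 2.3,
             I = 5.8, K = 8.0, L = 9.0, M = 2.3, N = 4.1, P = 4.6, Q = 3.8,
             R = 8.0, S = 6.4, T = 5.2, V = 6.6, W = 1.1, Y = 2.9)

.gen_proteins <- function(n, len_range, prefix = "SYN") {
  p <- AA_FREQ / sum(AA_FREQ)
  seqs <- character(n)
  for (i in seq_len(n)) {
    repeat {
      len <- sample(len_range[1L]:len_range[2L], 1L)
      s <- paste(sample(names(p), len, replace = TRUE, prob = p),
                 collapse = "")
      if (grepl("K", s, fixed = TRUE)) break  # need at least one link site
    }
    seqs[i] <- s
  }
  data.frame(accession = sprintf("%s_P%03d", prefix, seq_len(n)),
             sequence = seqs, is_decoy = FALSE, stringsAsFactors = FALSE)
}

#' Generate a random proteome
#'
#' Residues are drawn i.i.d. with K and R frequencies near 8%; every protein
#' is guaranteed at least one K.  Deterministic under `cfg$seed`.
#'
#' @param cfg A `sim_config`.
#' @return data.frame of target proteins (`accession`, `sequence`,
#'   `is_decoy`).
#' @export
generate_proteome <- function(cfg) {
  stopifnot(cfg$n_proteins > 0L)
  set.seed(cfg$seed)
  .gen_proteins(cfg$n_proteins, cfg$protein_len)
}

#' Write proteins to a FASTA file
#'
#' @param proteins data.frame with `accession` and `sequence`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  writeLines(paste0(">", proteins$accession, "\n", proteins$sequence), path)
  invisible(path)
}

.frag_efficiency <- function(p) {
  if (p <= 0) return(0)
  if (p >= 1) return(1)
  rbeta(1L, BETA_CONCENTRATION * p, BETA_CONCENTRATION * (1 - p))
}

.sim_peptide_ions <- function(sequence, site, delta, p_frag, int_scale,
                              ppm_sd) {
  ions <- fragment_with_site_mass(sequence, site, delta, max_frag_charge = 2L)
  eff <- .frag_efficiency(p_frag)
  keep <- runif(nrow(ions)) < eff
  mz <- ions$mz[keep]
  n <- length(mz)
  if (!n) return(cbind(mz = numeric(), intensity = numeric()))
  cbind(mz = mz * (1 + rnorm(n, 0, ppm_sd) * 1e-6),
        intensity = rlnorm(n, log(int_scale), 0.8))
}

#' Simulate one cross-linked MS/MS spectrum
#'
#' Generates theoretical b/y ions of both peptides under the configured
#' chemistry (non-cleavable: the partner plus intact linker as a site
#' offset; cleavable: short-stub ions plus, with probability
#' `cfg$doublet_prob` per peptide, the intact-peptide signature doublet),
#' thins them by the imbalanced per-spectrum fragmentation model, perturbs
#' m/z by Gaussian ppm error, adds log-normal intensities and uniform noise
#' peaks, and forms the precursor at charge 3-5.  Uses the current RNG
#' stream; seed management belongs to the caller.
#'
#' @param alpha,beta Lists with `sequence`, `site` (0-based), `protein`.
#' @param cfg A `sim_config`.
#' @param spectrum_id TITLE for the MGF block.
#' @return List with `spectrum` (a `spectrum` object) and `truth` (one-row
#'   data.frame ground-truth record).
#' @export
simulate_crosslinked_spectrum <- function(alpha, beta, cfg, spectrum_id) {
  linker <- cfg$linker
  ma <- peptide_mass(alpha$sequence)
  mb <- peptide_mass(beta$sequence)
  heavy_first <- ma >= mb
  p_a <- if (heavy_first) cfg$p_frag_heavy else cfg$p_frag_light
  p_b <- if (heavy_first) cfg$p_frag_light else cfg$p_frag_heavy
  sc_a <- if (heavy_first) INT_SCALE_HEAVY else INT_SCALE_LIGHT
  sc_b <- if (heavy_first) INT_SCALE_LIGHT else INT_SCALE_HEAVY

  if (cfg$mode == "noncleavable") {
    delta_a <- mb + linker$intact_mass
    delta_b <- ma + linker$intact_mass
  } else {
    delta_a <- linker$stub_short
    delta_b <- linker$stub_short
  }
  pk <- rbind(
    .sim_peptide_ions(alpha$sequence, alpha$site, delta_a, p_a, sc_a,
                      cfg$ppm_error_sd),
    .sim_peptide_ions(beta$sequence, beta$site, delta_b, p_b, sc_b,
                      cfg$ppm_error_sd))

  if (cfg$mode == "cleavable") {
    for (m in c(ma, mb)) {
      if (runif(1L) < cfg$doublet_prob) {
        dmz <- c(m + linker$stub_short + MASS_PROTON,
                 m + linker$stub_long + MASS_PROTON)
        pk <- rbind(pk, cbind(
          mz = dmz * (1 + rnorm(2L, 0, cfg$ppm_error_sd) * 1e-6),
          intensity = rlnorm(2L, log(INT_SCALE_DOUBLET), 0.5)))
      }
    }
  }

  if (cfg$noise_peaks > 0L) {
    pk <- rbind(pk, cbind(mz = runif(cfg$noise_peaks, 100, 2000),
                          intensity = rlnorm(cfg$noise_peaks,
                                             log(INT_SCALE_NOISE), 1.0)))
  }
  pk <- pk[order(pk[, 1L]), , drop = FALSE]
  colnames(pk) <- c("mz", "intensity")

  total <- ma + mb + linker$intact_mass
  z <- sample(3:5, 1L)
  pmz <- (total + z * MASS_PROTON) / z *
    (1 + rnorm(1L, 0, cfg$ppm_error_sd) * 1e-6)
  s <- structure(list(spectrum_id = spectrum_id, precursor_mz = pmz,
                      precursor_charge = z,
                      neutral_mass = pmz * z - z * MASS_PROTON, peaks = pk),
                 class = "spectrum")
  truth <- data.frame(spectrum_id = spectrum_id,
                      alpha_sequence = alpha$sequence,
                      beta_sequence = beta$sequence,
                      alpha_site = alpha$site, beta_site = beta$site,
                      alpha_protein = alpha$protein,
                      beta_protein = beta$protein,
                      stringsAsFactors = FALSE)
  list(spectrum = s, truth = truth)
}

# Peptides a cross-link can realistically sit on: mass small enough that a
# pair fits the instrument range, and at least one internal lysine -- a
# cross-linked K blocks tryptic cleavage, so linked residues are observed as
# internal missed-cleavage sites.
.truth_peptides <- function(protein_row, max_pep_mass = 2800) {
  peps <- digest(protein_row$sequence, protein_row$accession,
                 protein_row$is_decoy)
  if (!nrow(peps)) return(peps)
  aa_len <- nchar(peps$sequence)
  internal <- lapply(seq_len(nrow(peps)), function(i) {
    s <- peps$link_sites[[i]]
    s <- s[s > 0L & s < aa_len[i] - 1L]
    if (!length(s)) return(integer())
    s[substring(peps$sequence[i], s + 1L, s + 1L) == "K"]
  })
  keep <- peps$mono_mass >= 500 & peps$mono_mass <= max_pep_mass &
    lengths(internal) > 0L
  peps <- peps[keep, , drop = FALSE]
  peps$internal_sites <- internal[keep]
  peps
}

#' Generate a complete synthetic fixture
#'
#' Writes a target FASTA, an MGF with cross-linked plus null spectra, and a
#' ground-truth table.  Cross-linked pairs are drawn from a "hub" subset
#' (60% of the proteins), each hub receiving at least three spectra in
#' round-robin order, so sibling-peptide evidence exists for the feedback
#' stage to exploit.  Null spectra are simulated from a small foreign
#' proteome that is not written to the FASTA, so their peptides cannot be
#' found by the search.
#'
#' @param cfg A `sim_config`.
#' @param dir Output directory (created if needed).
#' @return List with `fasta`, `mgf` (paths), `truth` (data.frame, 0-based
#'   sites), and `truth_path` (TSV with 1-based sites).
#' @export
generate_fixture <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  proteins <- .gen_proteins(cfg$n_proteins, cfg$protein_len)
  eligible <- lapply(seq_len(nrow(proteins)), function(i)
    .truth_peptides(proteins[i, ]))
  has_pep <- which(vapply(eligible, nrow, 0L) > 0L)
  if (length(has_pep) < 2L) stop("proteome too small for cross-link sampling")

  # Hubs are a small minority of the database: real XL experiments
  # concentrate links on the purified complex while most FASTA entries are
  # background, and that sparsity is what makes protein-level evidence
  # informative.  Background proteins stay in the database as foil space.
  n_hub <- max(2L, min(length(has_pep), ceiling(0.2 * cfg$n_proteins),
                       max(2L, floor(cfg$n_xl_spectra / 3))))
  hubs <- sort(sample(has_pep, n_hub))

  draw_pep <- function(prot_i) {
    peps <- eligible[[prot_i]]
    r <- peps[sample(nrow(peps), 1L), ]
    site <- r$internal_sites[[1L]]
    site <- site[sample(length(site), 1L)]
    list(sequence = r$sequence, site = site,
         protein = proteins$accession[prot_i])
  }

  spectra <- vector("list", cfg$n_xl_spectra + cfg$n_null_spectra)
  truth <- vector("list", cfg$n_xl_spectra)
  for (k in seq_len(cfg$n_xl_spectra)) {
    prot_a <- hubs[((k - 1L) %% n_hub) + 1L]
    prot_b <- hubs[sample(n_hub, 1L)]
    sim <- simulate_crosslinked_spectrum(
      draw_pep(prot_a), draw_pep(prot_b), cfg, sprintf("XL_%05d", k))
    spectra[[k]] <- sim$spectrum
    truth[[k]] <- sim$truth
  }

  if (cfg$n_null_spectra > 0L) {
    foreign <- .gen_proteins(max(5L, ceiling(cfg$n_proteins / 5)),
                             cfg$protein_len, prefix = "FGN")
    felig <- lapply(seq_len(nrow(foreign)), function(i)
      .truth_peptides(foreign[i, ]))
    fok <- which(vapply(felig, nrow, 0L) > 0L)
    draw_foreign <- function() {
      i <- fok[sample(length(fok), 1L)]
      peps <- felig[[i]]
      r <- peps[sample(nrow(peps), 1L), ]
      site <- r$internal_sites[[1L]]
      list(sequence = r$sequence, site = site[sample(length(site), 1L)],
           protein = foreign$accession[i])
    }
    for (k in seq_len(cfg$n_null_spectra)) {
      sim <- simulate_crosslinked_spectrum(
        draw_foreign(), draw_foreign(), cfg, sprintf("NULL_%05d", k))
      spectra[[cfg$n_xl_spectra + k]] <- sim$spectrum
    }
  }

  truth <- do.call(rbind, truth)
  fasta <- file.path(dir, "proteome.fasta")
  mgf <- file.path(dir, "spectra.mgf")
  truth_path <- file.path(dir, "truth.tsv")
  write_fasta(proteins, fasta)
  write_mgf(spectra, mgf)
  truth_out <- truth
  truth_out$alpha_site <- truth_out$alpha_site + 1L  # 1-based on disk
  truth_out$beta_site <- truth_out$beta_site + 1L
  write.table(truth_out, truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  list(fasta = fasta, mgf = mgf, truth = truth, truth_path = truth_path)
}

#' Compare reported CSMs with the ground truth
#'
#' A CSM is a true positive iff its unordered set of (sequence, site) pairs
#' equals the truth record of its spectrum; any other reported CSM (wrong
#' pair, wrong site, or a null spectrum) is a false positive.
#'
#' @param csms data.frame of reported CSMs (`spectrum_id`, `alpha_seq`,
#'   `alpha_site`, `beta_seq`, `beta_site`; 0-based sites).
#' @param truth Ground-truth data.frame from [generate_fixture()].
#' @return List with `tp`, `fp`, `recall` (TP / number of cross-linked
#'   spectra) and `precision` (TP / reported; 0 with a warning if nothing is
#'   reported).
#' @export
evaluate_csms <- function(csms, truth) {
  n_xl <- nrow(truth)
  if (nrow(csms) == 0L) {
    warning("no CSMs reported; precision undefined, reported as 0")
    return(list(tp = 0L, fp = 0L, recall = 0, precision = 0))
  }
  key <- function(s1, p1, s2, p2) {
    a <- paste0(s1, "@", p1)
    b <- paste0(s2, "@", p2)
    ifelse(a <= b, paste(a, b, sep = "|"), paste(b, a, sep = "|"))
  }
  truth_key <- key(truth$alpha_sequence, truth$alpha_site,
                   truth$beta_sequence, truth$beta_site)
  names(truth_key) <- truth$spectrum_id
  csm_key <- key(csms$alpha_seq, csms$alpha_site,
                 csms$beta_seq, csms$beta_site)
  tp <- sum(!is.na(truth_key[csms$spectrum_id]) &
              csm_key == truth_key[csms$spectrum_id], na.rm = TRUE)
  fp <- nrow(csms) - tp
  list(tp = as.integer(tp), fp = as.integer(fp),
       recall = tp / n_xl, precision = tp / (tp + fp))
}
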