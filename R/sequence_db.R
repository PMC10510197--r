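# FASTA input, decoy generation, tryptic digestion, and the mass-sorted
# peptide index the pair search queries.

#' Read a protein FASTA database
#'
#' The accession is the first whitespace-delimited token of the header;
#' sequences are uppercased and trailing/internal `*` stripped.  Entries
#' containing ambiguous or non-standard letters (B, J, O, U, X, Z) are dropped
#' with a warning: the search needs exact residue masses.
#'
#' @param path FASTA file.
#' @return data.frame with columns `accession`, `sequence`, `is_decoy`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  aas <- Biostrings::readAAStringSet(path)
  if (length(aas) == 0L) stop("no FASTA records in ", path)
  seqs <- toupper(gsub("*", "", as.character(aas), fixed = TRUE))
  seqs <- gsub("[[:space:]]", "", seqs)
  acc <- vapply(strsplit(names(aas), "[[:space:]]+"), `[`, "", 1L)
  ok <- nzchar(seqs) & !grepl("[^ACDEFGHIKLMNPQRSTVWY]", seqs)
  if (any(!ok)) {
    warning(sum(!ok), " record(s) dropped (empty or non-standard residues): ",
            paste(head(acc[!ok], 5L), collapse = ", "))
  }
  if (!any(ok)) stop("no valid protein records in ", path)
  data.frame(accession = acc[ok], sequence = unname(seqs[ok]),
             is_decoy = FALSE, stringsAsFactors = FALSE)
}

#' Append reversed-sequence decoy proteins
#'
#' One decoy per target: the full protein sequence reversed, accession
#' prefixed `REV_`.  Full-protein reversal keeps the decoy residue (and hence
#' mass) composition identical to the target space.
#'
#' @param proteins data.frame from [read_fasta()] (targets only).
#' @return data.frame of targets followed by decoys.
#' @export
generate_decoys <- function(proteins) {
  if (any(proteins$is_decoy)) stop("input already contains decoys")
  rev_one <- function(s) paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]),
                               collapse = "")
  decoys <- data.frame(
    accession = paste0("REV_", proteins$accession),
    sequence = vapply(proteins$sequence, rev_one, "", USE.NAMES = FALSE),
    is_decoy = TRUE, stringsAsFactors = FALSE)
  rbind(proteins, decoys)
}

#' Tryptic digestion of one protein
#'
#' Cleaves C-terminal to K or R except before P, emitting all peptides with at
#' most `max_missed` internal missed cleavages and length within
#' `[min_len, max_len]`.  Cross-link sites are the positions (0-based) of
#' linker-reactive residues, plus position 0 of the protein N-terminal peptide
#' when `nterm_reactive`.  A peptide C-terminal K that is also the cleavage
#' site is kept as a link site by default (`allow_cterm_k`): cross-linked
#' lysines usually escape cleavage, so such sites mostly matter as candidate
#' foils, and excluding them is a configuration choice.
#'
#' @param sequence Protein sequence.
#' @param accession Protein accession carried onto the peptides.
#' @param is_decoy Decoy flag carried onto the peptides.
#' @param max_missed Maximum internal missed cleavages.
#' @param min_len,max_len Peptide length bounds.
#' @param linker_residues Residues reactive toward the linker (default K).
#' @param nterm_reactive Protein N-terminus is linkable.
#' @param allow_cterm_k Keep a cleavage-site C-terminal K as a link site.
#' @param cys_cam Fixed carbamidomethyl-C for the mass calculation.
#' @return data.frame with columns `sequence`, `mono_mass`, `missed_cleavages`,
#'   `accession`, `is_decoy`, and list column `link_sites` (0-based).
#' @export
digest <- function(sequence, accession = NA_character_, is_decoy = FALSE,
                   max_missed = 2L, min_len = 5L, max_len = 50L,
                   linker_residues = "K", nterm_reactive = TRUE,
                   allow_cterm_k = TRUE, cys_cam = TRUE) {
  stopifnot(max_missed >= 0L, min_len >= 1L)
  aa <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(aa)
  res_m <- residue_masses(sequence, cys_cam)
  prefix <- c(0, cumsum(res_m))

  cle <- which(aa %in% c("K", "R"))
  cle <- cle[cle < n]
  if (length(cle)) cle <- cle[aa[cle + 1L] != "P"]
  starts <- c(1L, cle + 1L)           # segment starts, 1-based
  ends <- c(cle, n)                   # segment ends
  nseg <- length(starts)

  out <- vector("list", (max_missed + 1L) * nseg)
  k <- 0L
  for (mc in 0:max_missed) {
    if (nseg - mc < 1L) break
    for (i in seq_len(nseg - mc)) {
      s <- starts[i]; e <- ends[i + mc]
      len <- e - s + 1L
      if (len < min_len || len > max_len) next
      pep <- substr(sequence, s, e)
      sites <- which(aa[s:e] %in% linker_residues) - 1L  # 0-based in peptide
      if (!allow_cterm_k && e < n && length(sites) &&
          sites[length(sites)] == len - 1L) {
        sites <- sites[-length(sites)]
      }
      if (nterm_reactive && s == 1L) sites <- sort(unique(c(0L, sites)))
      k <- k + 1L
      out[[k]] <- list(sequence = pep,
                       mono_mass = prefix[e + 1L] - prefix[s] + MASS_WATER,
                       missed_cleavages = mc,
                       link_sites = sites)
    }
  }
  if (k == 0L) {
    return(data.frame(sequence = character(), mono_mass = numeric(),
                      missed_cleavages = integer(), accession = character(),
                      is_decoy = logical(),
                      link_sites = I(list()), stringsAsFactors = FALSE))
  }
  out <- out[seq_len(k)]
  data.frame(sequence = vapply(out, `[[`, "", "sequence"),
             mono_mass = vapply(out, `[[`, 0, "mono_mass"),
             missed_cleavages = vapply(out, `[[`, 0L, "missed_cleavages"),
             accession = accession, is_decoy = is_decoy,
             link_sites = I(lapply(out, `[[`, "link_sites")),
             stringsAsFactors = FALSE)
}

#' Digest every protein of a database
#'
#' @param proteins data.frame of proteins (targets + decoys).
#' @param ... Passed to [digest()].
#' @return Row-bound digest of all proteins.
#' @export
digest_proteins <- function(proteins, ...) {
  res <- lapply(seq_len(nrow(proteins)), function(i) {
    digest(proteins$sequence[i], proteins$accession[i],
           proteins$is_decoy[i], ...)
  })
  do.call(rbind, res)
}

#' Build the mass-sorted peptide index
#'
#' Duplicate sequences are merged (parent proteins unioned; a peptide shared
#' between target and decoy space stays a target, the conservative choice for
#' FDR).  Entries are sorted by monoisotopic mass and the per-peptide residue
#' masses are pre-flattened for the scoring kernel.
#'
#' @param peptides data.frame from [digest_proteins()].
#' @param mass_range Numeric length-2: admitted peptide mass window in Da.
#' @param require_link_site Drop peptides with no cross-linkable site.
#' @param cys_cam Fixed carbamidomethyl-C (must match the digestion setting).
#' @return Object of class `peptide_index`.
#' @export
build_index <- function(peptides, mass_range = c(500, 6000),
                        require_link_site = TRUE, cys_cam = TRUE) {
  stopifnot(nrow(peptides) > 0L)
  keep <- peptides$mono_mass >= mass_range[1L] &
    peptides$mono_mass <= mass_range[2L]
  if (require_link_site) keep <- keep & lengths(peptides$link_sites) > 0L
  peptides <- peptides[keep, , drop = FALSE]
  if (nrow(peptides) == 0L) stop("no peptides admitted to the index")

  key <- peptides$sequence
  first <- !duplicated(key)
  prot_by_seq <- lapply(split(peptides$accession, key), function(x)
    sort(unique(x)))
  decoy_by_seq <- vapply(split(peptides$is_decoy, key), all, NA)
  mc_by_seq <- vapply(split(peptides$missed_cleavages, key), min, 0)

  df <- peptides[first, c("sequence", "mono_mass", "link_sites")]
  df$proteins <- I(prot_by_seq[df$sequence])
  df$is_decoy <- unname(decoy_by_seq[df$sequence])
  df$missed_cleavages <- as.integer(mc_by_seq[df$sequence])
  ord <- order(df$mono_mass, df$sequence, method = "radix")
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL

  res_list <- lapply(df$sequence, residue_masses, cys_cam = cys_cam)
  sites <- df$link_sites
  idx <- list(
    peptides = df,
    res_flat = unlist(res_list, use.names = FALSE),
    pep_off = c(0L, cumsum(lengths(res_list))),
    site_flat = as.integer(unlist(sites, use.names = FALSE)),
    site_off = c(0L, cumsum(lengths(sites))),
    cys_cam = cys_cam,
    mass_range = mass_range)
  class(idx) <- "peptide_index"
  idx
}

#' @export
print.peptide_index <- function(x, ...) {
  cat("peptide_index:", nrow(x$peptides), "peptides,",
      sum(x$peptides$is_decoy), "decoy;",
      sprintf("mass %.2f-%.2f Da\n", min(x$peptides$mono_mass),
              max(x$peptides$mono_mass)))
  invisible(x)
}

#' Range query on the peptide index
#'
#' @param index A `peptide_index`.
#' @param lo,hi Inclusive neutral-mass interval in Da.
#' @return Integer vector of row indices into `index$peptides` (contiguous,
#'   possibly empty).
#' @export
query_mass_range <- function(index, lo, hi) {
  m <- index$peptides$mono_mass
  if (hi < lo) return(integer())
  from <- findInterval(lo, m, left.open = TRUE) + 1L
  to <- findInterval(hi, m)
  if (from > to) integer() else from:to
}
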