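# MGF input/output and spectrum preprocessing.
#
# MGF dialect: BEGIN IONS / END IONS blocks with TITLE, PEPMASS (first field
# is the precursor m/z; an optional second intensity field is ignored) and
# CHARGE accepted as "3+", "+3" or "3".  Blocks without a charge are skipped —
# the neutral precursor mass cannot be formed without it.

#' Read an MGF peak-list file
#'
#' @param path MGF file.
#' @param min_charge Minimum precursor charge retained.  Cross-linked
#'   precursors are typically 3+ and higher; set to 1 to keep everything.
#' @return List of `spectrum` objects: `spectrum_id`, `precursor_mz`,
#'   `precursor_charge`, `neutral_mass`, and a two-column `peaks` matrix
#'   (mz, intensity) sorted by m/z.
#' @export
read_mgf <- function(path, min_charge = 3L) {
  if (!file.exists(path)) stop("MGF file not found: ", path)
  lines <- readLines(path)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) == 0L || length(begins) != length(ends)) {
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS in ", path)
  }
  out <- vector("list", length(begins))
  n_ok <- 0L; n_skip <- 0L
  for (b in seq_along(begins)) {
    block <- lines[(begins[b] + 1L):(ends[b] - 1L)]
    is_param <- grepl("=", block, fixed = TRUE)
    params <- block[is_param]
    key <- sub("=.*$", "", params)
    val <- sub("^[^=]*=", "", params)
    title <- if ("TITLE" %in% key) val[match("TITLE", key)] else
      paste0("index=", b)
    pepmass <- if ("PEPMASS" %in% key) {
      as.numeric(strsplit(trimws(val[match("PEPMASS", key)]),
                          "[[:space:]]+")[[1L]][1L])
    } else NA_real_
    charge <- if ("CHARGE" %in% key) {
      cs <- strsplit(trimws(val[match("CHARGE", key)]), "[[:space:]]+")[[1L]][1L]
      suppressWarnings(as.integer(gsub("[+]", "", cs)))
    } else NA_integer_
    if (is.na(pepmass) || is.na(charge) || charge < 1L) {
      n_skip <- n_skip + 1L
      next
    }
    if (charge < min_charge) next
    peak_lines <- block[!is_param]
    peak_lines <- peak_lines[nzchar(trimws(peak_lines))]
    if (length(peak_lines)) {
      fields <- strsplit(trimws(peak_lines), "[[:space:]]+")
      mz <- as.numeric(vapply(fields, `[`, "", 1L))
      int <- as.numeric(vapply(fields, `[`, "", 2L))
      ok <- !is.na(mz) & !is.na(int) & int > 0
      mz <- mz[ok]; int <- int[ok]
      o <- order(mz)
      peaks <- cbind(mz = mz[o], intensity = int[o])
    } else {
      peaks <- cbind(mz = numeric(), intensity = numeric())
    }
    s <- list(spectrum_id = title, precursor_mz = pepmass,
              precursor_charge = charge,
              neutral_mass = pepmass * charge - charge * MASS_PROTON,
              peaks = peaks)
    class(s) <- "spectrum"
    n_ok <- n_ok + 1L
    out[[n_ok]] <- s
  }
  if (n_skip > 0L) {
    warning(n_skip, " MGF block(s) skipped (missing PEPMASS or CHARGE)")
  }
  out <- out[seq_len(n_ok)]
  if (length(out) == 0L) stop("no usable spectra in ", path)
  out
}

#' Write spectra to an MGF file
#'
#' Numbers are printed with fixed six-decimal formatting so identical inputs
#' yield byte-identical files.
#'
#' @param spectra List of `spectrum` objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  blocks <- vapply(spectra, function(s) {
    paste0("BEGIN IONS\n",
           "TITLE=", s$spectrum_id, "\n",
           sprintf("PEPMASS=%.6f\n", s$precursor_mz),
           sprintf("CHARGE=%d+\n", s$precursor_charge),
           if (nrow(s$peaks)) {
             paste0(sprintf("%.6f %.6f", s$peaks[, 1L], s$peaks[, 2L]),
                    collapse = "\n")
           } else "",
           if (nrow(s$peaks)) "\n" else "",
           "END IONS")
  }, "")
  writeLines(blocks, path)
  invisible(path)
}

#' Preprocess a spectrum for scoring
#'
#' Removes peaks within 2 Th of the precursor m/z, square-roots intensities
#' (dynamic-range compression), keeps the `top_k` most intense peaks per
#' `window` Th, and normalizes each window to a maximum of 1.  Applying it to
#' an already-processed spectrum is a no-op: the transform is defined on raw
#' peak lists.
#'
#' @param s A `spectrum` from [read_mgf()].
#' @param top_k Peaks retained per window.
#' @param window Window width in Th.
#' @return A `processed_spectrum`: `spectrum_id`, `neutral_mass`, `charge`,
#'   and parallel vectors `mz`, `intensity` (normalized, in (0, 1]).
#' @export
preprocess_spectrum <- function(s, top_k = 10L, window = 100) {
  if (inherits(s, "processed_spectrum")) return(s)
  stopifnot(top_k >= 1L, window > 0)
  mz <- s$peaks[, 1L]; int <- s$peaks[, 2L]
  keep <- abs(mz - s$precursor_mz) > 2
  mz <- mz[keep]; int <- sqrt(int[keep])
  if (length(mz)) {
    win <- floor(mz / window)
    ord <- order(win, -int, mz, method = "radix")
    win_o <- win[ord]
    rank_in_win <- sequence(rle(win_o)$lengths)
    sel <- ord[rank_in_win <= top_k]
    mz <- mz[sel]; int <- int[sel]; win <- win[sel]
    wmax <- tapply(int, win, max)
    int <- int / as.numeric(wmax[as.character(win)])
    o <- order(mz)
    mz <- unname(mz[o]); int <- unname(int[o])
  }
  ps <- list(spectrum_id = s$spectrum_id, neutral_mass = s$neutral_mass,
             charge = s$precursor_charge, precursor_mz = s$precursor_mz,
             mz = mz, intensity = int)
  class(ps) <- "processed_spectrum"
  ps
}
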