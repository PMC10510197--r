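# Linker chemistry registry and theoretical b/y fragment generation.
#
# Any cross-link attachment is modeled as a site-localized neutral mass offset
# on one peptide: the partner peptide plus intact linker in non-cleavable
# searches, or a cleaved linker stub in MS-cleavable searches.  Ion series are
# limited to b/y at fragment charges 1..max_frag_charge (CID/HCD dominant
# series); no neutral losses or isotope peaks.

#' Construct a cross-linker specification
#'
#' @param name Linker name.
#' @param intact_mass Neutral mass added to the peptide pair when joined (Da).
#' @param reactive_residues Residues the linker reacts with.
#' @param cleavable Does the linker cleave in MS2 into stub remnants?
#' @param stub_short,stub_long Stub masses in Da (cleavable linkers only),
#'   short < long.
#' @return Object of class `linker_spec`.
#' @export
linker_spec <- function(name, intact_mass, reactive_residues = "K",
                        cleavable = FALSE, stub_short = NA_real_,
                        stub_long = NA_real_) {
  stopifnot(intact_mass > 0)
  if (cleavable) {
    stopifnot(!is.na(stub_short), !is.na(stub_long),
              stub_short > 0, stub_short < stub_long)
  }
  structure(list(name = name, intact_mass = intact_mass,
                 reactive_residues = reactive_residues,
                 cleavable = cleavable,
                 stub_short = stub_short, stub_long = stub_long),
            class = "linker_spec")
}

#' Built-in cross-linkers
#'
#' DSS (non-cleavable), DSSO and DSBU (MS-cleavable), all amine-reactive
#' (lysine and protein N-terminus).  Monoisotopic masses derive from the
#' elemental compositions of the linked/cleaved remnants: DSS bridge C8H10O2;
#' DSSO bridge C6H6O3S with alkene/thiol stubs C3H2O and C3H2OS; DSBU bridge
#' C9H12N2O3 with stubs C4H7NO and C5H5NO2.
#'
#' @return Named list of `linker_spec` objects.
#' @export
builtin_linkers <- function() {
  list(
    DSS  = linker_spec("DSS", 138.068080, "K", cleavable = FALSE),
    DSSO = linker_spec("DSSO", 158.003765, "K", cleavable = TRUE,
                       stub_short = 54.010565, stub_long = 85.982636),
    DSBU = linker_spec("DSBU", 196.084792, "K", cleavable = TRUE,
                       stub_short = 85.052764, stub_long = 111.032028)
  )
}

#' Resolve a linker by name or pass a spec through
#'
#' @param linker A `linker_spec` or the name of a built-in linker.
#' @return A `linker_spec`.
#' @export
get_linker <- function(linker) {
  if (inherits(linker, "linker_spec")) return(linker)
  reg <- builtin_linkers()
  if (!linker %in% names(reg)) {
    stop("unknown linker '", linker, "'; built-in linkers: ",
         paste(names(reg), collapse = ", "))
  }
  reg[[linker]]
}

#' Theoretical b/y ions with a site-localized mass offset
#'
#' b_i is the sum of the first i residues plus a proton; y_i the sum of the
#' last i residues plus water and a proton.  Ions whose residue span covers
#' `site` carry the extra neutral mass `delta`.  `delta = 0` yields plain
#' linear-peptide ions.
#'
#' @param sequence Peptide sequence.
#' @param site 0-based link-site position within the peptide.
#' @param delta Neutral mass offset in Da (>= 0).
#' @param max_frag_charge Fragment charges 1..max_frag_charge.
#' @param cys_cam Fixed carbamidomethyl-C.
#' @return data.frame with `series`, `index`, `charge`, `mz`,
#'   `contains_link_site`.
#' @export
fragment_with_site_mass <- function(sequence, site, delta,
                                    max_frag_charge = 2L, cys_cam = TRUE) {
  res <- residue_masses(sequence, cys_cam)
  n <- length(res)
  if (site < 0L || site >= n) stop("link site out of range: ", site)
  if (delta < 0) stop("delta must be >= 0")
  if (n < 2L) {
    return(data.frame(series = character(), index = integer(),
                      charge = integer(), mz = numeric(),
                      contains_link_site = logical()))
  }
  prefix <- cumsum(res)
  i <- seq_len(n - 1L)
  b_cov <- site <= i - 1L
  y_cov <- site >= n - i
  b_neut <- prefix[i] + delta * b_cov
  y_neut <- (prefix[n] - prefix[n - i]) + MASS_WATER + delta * y_cov
  zs <- seq_len(max_frag_charge)
  out <- do.call(rbind, lapply(zs, function(z) {
    data.frame(series = rep(c("b", "y"), each = n - 1L),
               index = c(i, i), charge = z,
               mz = c((b_neut + z * MASS_PROTON) / z,
                      (y_neut + z * MASS_PROTON) / z),
               contains_link_site = c(b_cov, y_cov),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Ions of a peptide in a non-cleavable cross-link
#'
#' The partner peptide plus the intact linker ride as one opaque neutral mass
#' on the link site.
#'
#' @inheritParams fragment_with_site_mass
#' @param partner_plus_linker_mass Neutral mass of partner peptide + linker.
#' @return As [fragment_with_site_mass()].
#' @export
ions_noncleavable <- function(sequence, site, partner_plus_linker_mass,
                              max_frag_charge = 2L, cys_cam = TRUE) {
  if (partner_plus_linker_mass <= 0) stop("partner mass must be positive")
  fragment_with_site_mass(sequence, site, partner_plus_linker_mass,
                          max_frag_charge, cys_cam)
}

#' Ions of a stub-modified peptide (MS-cleavable linker)
#'
#' @inheritParams fragment_with_site_mass
#' @param stub Stub neutral mass (the linker's short or long remnant).
#' @return As [fragment_with_site_mass()].
#' @export
ions_cleavable <- function(sequence, site, stub, max_frag_charge = 2L,
                           cys_cam = TRUE) {
  if (stub <= 0) stop("stub mass must be positive")
  fragment_with_site_mass(sequence, site, stub, max_frag_charge, cys_cam)
}
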