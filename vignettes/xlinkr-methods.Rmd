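---
title: "Cross-link search with protein feedback: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-link search with protein feedback: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xlinkr)
```

## The problem

Cross-linking mass spectrometry (XL-MS) identifies pairs of peptides joined
by a bifunctional reagent.  Each MS/MS spectrum of a cross-linked precursor
contains fragments of *two* peptides, and fragmentation is notoriously
unequal: the heavier peptide tends to dominate the ion current while the
lighter one may leave few or no interpretable fragments.  A scoring function
alone cannot distinguish candidate pairs that differ only in the starved
peptide.  `xlinkr` implements a search engine for non-cleavable (DSS) and
MS-cleavable (DSSO, DSBU) linkers whose distinguishing stage is *protein
feedback*: peptides from proteins that are confidently identified elsewhere
in the run are more plausible partners, because cross-linked samples
concentrate links on a limited set of proteins whose sibling peptides recur
across spectra.

## Pipeline

1. **Database**: FASTA proteins are reversed to create decoys (`REV_`
   prefix), digested with the trypsin rule (cleave after K/R, not before P,
   up to 2 missed cleavages, length 5–50, peptide mass 500–6000 Da), and
   indexed by monoisotopic mass.  Cross-link sites are lysines and the
   protein N-terminus.  Cysteines carry fixed carbamidomethylation
   (+57.021464 Da).  Peptides shared between target and decoy space are
   labeled target (conservative for FDR).
2. **Spectra**: MGF peak lists (centroided; precursor charge required,
   default minimum 3+).  Preprocessing removes peaks within 2 Th of the
   precursor, square-roots intensities, keeps the 10 most intense peaks per
   100 Th window, and rescales each window to a maximum of 1.  The transform
   is defined on raw spectra; re-applying it to processed output is a no-op.
3. **Candidate pairs**: every mass-eligible peptide is scored **once** per
   spectrum — the partner peptide plus intact linker (non-cleavable) or the
   cleaved linker stub (cleavable) enters as an opaque, site-localized mass
   offset, so scoring cost is linear in the number of eligible peptides, not
   quadratic in pairs.  The score is the sum of matched normalized
   intensities over theoretical b/y ions (charges 1–2), each theoretical ion
   matching at most its nearest peak within 20 ppm and each peak claimed by
   at most one ion.  Pairs satisfying the precursor mass constraint (10 ppm
   on the pair mass) are ranked by combined score and the top `N = 20` are
   cached.  For cleavable linkers, signature doublets (peak pairs spaced by
   the long−short stub difference) add a bonus equal to their summed
   intensity for candidates whose peptide mass matches the doublet-implied
   mass.
4. **Protein feedback**: candidates scoring below 80% of each spectrum's top
   combined score are discarded; the remaining rank-1 hits are filtered at a
   data-driven 10% FDR cutoff, and the surviving target-target hits credit
   each peptide's site score to its parent proteins.  Each spectrum's
   retained candidates are then re-ranked by
   `combined_score + ln(1 + PS(alpha)) + ln(1 + PS(beta))`, where `PS` is the
   maximum accumulated weight over a peptide's parent proteins.
5. **FDR**: the selected CSMs are ranked by combined score; the estimate at
   each rank is `max(0, TD − DD) / TT` (a target-decoy hit contains one
   random peptide, a decoy-decoy hit two, so the difference estimates the
   random-target count), converted to q-values by a running minimum.
   Reported results are target-target CSMs with `q ≤ 0.05`.

## Design choices in the open parts

Three parts of the method are genuinely open and fixed here as the package's
own choices.

**The spectral score.** The matched-normalized-intensity sum is
deterministic, non-negative (a requirement for the 80% retention rule),
monotone in the tolerance, and easy to validate against an exhaustive
assignment oracle.  Ties (two equidistant peaks for one ion, or two ions
contesting one peak) resolve toward lower m/z, making ranking fully
deterministic.

**Additive feedback re-ranking.** Re-ranking is by
`combined + ln(1 + PS_alpha) + ln(1 + PS_beta)` rather than by protein score
alone.  A purely lexicographic "protein score first" rule lets arbitrarily
small weight differences override arbitrarily large spectral margins; with
realistic, similarly-weighted supported proteins that reassigns ambiguous
spectra essentially at random.  In the additive form the protein term
(≈ 5–6 nats for a well-supported protein versus 0 for an unsupported one)
dominates exactly when the spectral margin between candidates is small —
the fragmentation-starved case the mechanism targets — and defers to the
spectrum otherwise.  `ln(1+·)` damps domination by heavily covered proteins
and leaves an all-zero database as an exact no-op (the no-feedback identity,
asserted in the tests).

**Decoy mirror weights.** The protein score database is built exclusively
from confident target-target first hits, but at lookup time a decoy protein
reads back the weight of its target mirror (`REV_P` → `P`).  Without this,
feedback can never select a decoy candidate: every ambiguous spectrum is
steered onto some target-target pair, the TD count collapses, and the
target-decoy FDR estimate becomes strongly anti-conservative (we measured
~29% realized error at a nominal 5% before introducing the mirror).  Mirror
weights keep the target/decoy competition symmetric for equally
(un)supported candidates, restoring calibration, while genuine targets still
win whenever their protein has real support and the spectrum provides any
margin.

Other notable conventions: alpha is the higher-scoring peptide of a pair
(ties lexicographic by sequence); homodimers are allowed; a peptide
C-terminal lysine at a cleavage site remains an eligible link site
(configurable) — missed-cleavage peptides cover the chemically realistic
cases and the extra sites only cost candidates; site ties within a peptide
resolve to the lowest position; internal coordinates are 0-based and all
output 1-based.

## The synthetic-data generator

The generator emulates the statistical structure the feedback mechanism
assumes, so the engine is testable offline:

* **Proteome**: random sequences (default 50 proteins of 200–400 residues),
  residues i.i.d. with K and R boosted to ~8% so tryptic and link sites are
  plentiful; every protein contains at least one K.
* **Truth sampling**: cross-linked pairs are drawn from a *hub* subset (20%
  of proteins, each receiving ≥3 spectra round-robin).  Real XL experiments
  concentrate links on the purified complex while most database entries are
  background; that sparsity is what makes protein-level evidence
  informative, and the background proteins remain in the FASTA as foil
  space.  The linked lysine is always an internal (missed-cleavage) lysine:
  a cross-linked K blocks tryptic cleavage, so linked residues appear as
  missed cleavages.
* **Imbalanced fragmentation**: each peptide of a pair receives a
  per-spectrum fragmentation efficiency drawn from a Beta distribution with
  mean `p_frag_heavy = 0.9` (heavier) or `p_frag_light = 0.3` (lighter) and
  concentration 1.5; theoretical ions are then retained i.i.d. at that rate.
  The marginal per-ion detection probability equals `p_frag_*`, while the
  spectrum-level correlation reproduces the real phenomenon of spectra with
  essentially *no* fragments of the lighter peptide — the regime the
  feedback stage exists for, which independent per-ion thinning essentially
  never produces at this scale.  Lighter-peptide fragment intensities are
  also drawn ~5× weaker than heavier-peptide ones.  `p = 1` (or `0`)
  degenerates to exact retention (or none), giving a noise-free sanity
  ceiling.
* **Peaks**: retained ions get Gaussian m/z error (5 ppm SD) and log-normal
  intensities; 60 uniform noise peaks are added per spectrum; precursors
  (charge 3–5) carry the same ppm error.  In cleavable mode each peptide's
  signature doublet appears with probability 0.8.
* **Null spectra**: 100 spectra are simulated from a small *foreign*
  proteome absent from the searched FASTA, so none of their peptides can be
  correctly identified — they exercise the null behavior of the FDR
  estimator.

What the generator does **not** model: isotope envelopes, neutral losses,
co-isolation chimeras, retention-time structure, non-tryptic cleavage, and
real intensity patterns of peptide bond fragmentation.  Passing tests on
these fixtures therefore demonstrate the correctness and calibration of the
search and feedback machinery under the stated statistical assumptions, not
instrument-level realism.

## Problem sizes and numerical conventions

The default benchmark fixture is 50 proteins (≈8,000 indexed peptides with
decoys) and 300 cross-linked + 100 null spectra; the FDR-calibration batches
use 20 proteins and 80 + 40 spectra over 20 seeds.  Monoisotopic constants:
water 18.0105646837 Da, proton 1.00727646677 Da; linker masses derive from
elemental compositions (DSS bridge C8H10O2 = 138.06808 Da; DSSO
158.003765 Da with stubs 54.010565/85.982636 Da; DSBU 196.084792 Da with
stubs 85.052764/111.032028 Da).  Degenerate inputs follow explicit rules:
spectra without charge are skipped, empty candidate lists yield no CSM,
zero reported CSMs give precision 0 with a warning, and all randomness is
confined to the generator (searches are fully deterministic, so identical
inputs give byte-identical output files).

## Known limitations

* Peptide-level one-to-one matching is applied per peptide, not jointly per
  pair, so both peptides of a candidate pair may claim the same peak; this
  is the price of linear-time scoring and mirrors the partner-as-mass
  design.  A related, physically irreducible ambiguity: fragment ions that
  span the link site depend on the observed precursor mass minus the
  peptide's own prefix/suffix masses, so candidates sharing terminal
  residue compositions share those ions.
* With only ~300 spectra, the running-minimum q-value is sensitive to the
  rank of the first few decoy hits, so accepted counts vary substantially
  between fixture seeds; this is inherent small-sample behavior of
  target-decoy competition, not estimator bias (calibration is tested over
  20 seeds).
* Site localization within a peptide has no protein-level signal; when the
  starved peptide contributes no site-discriminating ions the lowest
  eligible site is reported.
* One combined FDR is computed (no separate intra/inter-protein FDR), and
  loop-links, mono-links, and variable modifications are out of scope.
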