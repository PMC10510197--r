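test_that("read_fasta parses, normalizes and validates records", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">P1 some description", "MKR", ">P2", "mk r", ">P3", "MKXR",
               ">P4", "GGKA*"), f)
  w <- capture_warnings(db <- read_fasta(f))
  expect_true(any(grepl("dropped", w)))  # plus Biostrings' note about '*'
  expect_equal(db$accession, c("P1", "P2", "P4"))
  expect_equal(db$sequence, c("MKR", "MKR", "GGKA"))
  expect_false(any(db$is_decoy))

  empty <- tempfile(fileext = ".fasta")
  writeLines(character(), empty)
  expect_error(read_fasta(empty))
  expect_error(read_fasta("no/such/file.fasta"))
})

test_that("generate_decoys reverses sequences and preserves composition", {
  db <- data.frame(accession = c("P1", "P2"),
                   sequence = c("MKRGGK", "AVLDEK"), is_decoy = FALSE)
  out <- generate_decoys(db)
  expect_equal(nrow(out), 4L)
  expect_equal(out$accession[3:4], c("REV_P1", "REV_P2"))
  expect_equal(out$sequence[3], "KGGRKM")
  # mass-preserving permutation
  comp <- function(s) sort(strsplit(s, "")[[1]])
  expect_equal(comp(out$sequence[3]), comp("MKRGGK"))
  expect_true(all(out$is_decoy[3:4]))
  expect_error(generate_decoys(out))
})

test_that("digest applies the trypsin rule with the KP exception", {
  p <- digest("MKRGGK", max_missed = 0L, min_len = 2L, max_len = 50L)
  expect_setequal(p$sequence, c("MK", "GGK"))

  p2 <- digest("AKPA", max_missed = 0L, min_len = 2L, max_len = 50L)
  expect_equal(p2$sequence, "AKPA")

  # non-standard residues are rejected outright
  expect_error(digest("AAAKBBBK", max_missed = 0L, min_len = 2L,
                      max_len = 50L), "non-standard")
  # missed cleavages are counted and bounded
  p3 <- digest("AAAKGGGKCCCK", max_missed = 1L, min_len = 2L, max_len = 50L)
  expect_setequal(p3$sequence[p3$missed_cleavages == 1L],
                  c("AAAKGGGK", "GGGKCCCK"))
})

test_that("digest masses match an independent residue-mass summation", {
  p <- digest("MKRGGK", max_missed = 0L, min_len = 2L, max_len = 50L)
  ggk <- p$mono_mass[p$sequence == "GGK"]
  expect_equal(ggk, oracle_peptide_mass("GGK"), tolerance = 1e-9)
  expect_equal(ggk, 260.148445, tolerance = 1e-4)  # published 5-dp table value
  expect_equal(peptide_mass("PEPTIDEK", cys_cam = FALSE),
               oracle_peptide_mass("PEPTIDEK", cys_cam = FALSE),
               tolerance = 1e-9)
})

test_that("digest link sites are reactive residues plus the N-terminus", {
  p <- digest("MKAGGKAK", max_missed = 2L, min_len = 3L, max_len = 50L)
  full <- p[p$sequence == "MKAGGKAK", ]
  # protein N-terminal peptide: position 0 plus every K
  expect_equal(full$link_sites[[1]], c(0L, 1L, 5L, 7L))
  # C-terminal cleavage-site K excluded when allow_cterm_k = FALSE
  p2 <- digest("AAGKAAAR", max_missed = 0L, min_len = 3L, max_len = 50L,
               allow_cterm_k = FALSE, nterm_reactive = FALSE)
  expect_equal(p2$link_sites[[which(p2$sequence == "AAGK")]], integer())
})

test_that("zero-missed-cleavage digest re-concatenates to the protein", {
  set.seed(31)
  for (rep in 1:10) {
    prot <- paste(sample(names(ORACLE_AA), 120, TRUE), collapse = "")
    p <- digest(prot, max_missed = 0L, min_len = 1L, max_len = 1000L)
    expect_equal(paste(p$sequence, collapse = ""), prot)
  }
})

test_that("decoy digestion preserves the total residue count", {
  set.seed(32)
  prots <- data.frame(
    accession = paste0("P", 1:5),
    sequence = replicate(5, paste(sample(names(ORACLE_AA), 150, TRUE),
                                  collapse = "")),
    is_decoy = FALSE)
  all <- digest_proteins(generate_decoys(prots), max_missed = 0L,
                         min_len = 1L, max_len = 1000L)
  expect_equal(sum(nchar(all$sequence[all$is_decoy])),
               sum(nchar(all$sequence[!all$is_decoy])))
})

test_that("index merges duplicates and marks shared peptides target", {
  peps <- rbind(
    digest("AAAGGKR", accession = "P1", max_missed = 0L, min_len = 3L,
           max_len = 50L),
    digest("AAAGGKR", accession = "P2", max_missed = 0L, min_len = 3L,
           max_len = 50L),
    digest("RAAAGGK", accession = "REV_P9", is_decoy = TRUE,
           max_missed = 0L, min_len = 3L, max_len = 50L))
  idx <- build_index(peps, mass_range = c(100, 5000))
  entry <- idx$peptides[idx$peptides$sequence == "AAAGGK", ]
  # shared between target and decoy space: parents unioned, labeled target
  expect_equal(entry$proteins[[1]], c("P1", "P2", "REV_P9"))
  expect_false(entry$is_decoy)
})

test_that("range query equals brute-force scan on random windows", {
  set.seed(33)
  prots <- data.frame(
    accession = paste0("P", 1:8),
    sequence = replicate(8, paste(sample(names(ORACLE_AA), 200, TRUE,
                                         prob = c(rep(1, 10), 2, rep(1, 9))),
                                  collapse = "")),
    is_decoy = FALSE)
  idx <- build_index(digest_proteins(generate_decoys(prots)),
                     mass_range = c(400, 4000))
  m <- idx$peptides$mono_mass
  for (k in 1:100) {
    lo <- runif(1, 350, 4000)
    hi <- lo + runif(1, 0, 300)
    expect_identical(query_mass_range(idx, lo, hi),
                     which(m >= lo & m <= hi))
  }
  expect_identical(query_mass_range(idx, 100, 90), integer())
  # the GGK-sized mass window example
  idx2 <- build_index(digest("MKRGGK", max_missed = 0L, min_len = 2L,
                             max_len = 10L),
                      mass_range = c(100, 500))
  hit <- query_mass_range(idx2, 260.14, 260.16)
  expect_equal(idx2$peptides$sequence[hit], "GGK")
})
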