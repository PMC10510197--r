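dss <- get_linker("DSS")

test_that("mass eligibility and best-site reduction in peptide scoring", {
  prots <- data.frame(accession = "P1",
                      sequence = "AAKGGVLKRMMMKTTTVLKRSSSGGGKAAAR",
                      is_decoy = FALSE)
  idx <- build_index(digest_proteins(prots), mass_range = c(300, 4000))
  ps <- make_ps(runif(40, 100, 1500), runif(40, 0.1, 1), neutral_mass = 2200)
  scored <- score_peptides_noncleavable(ps, idx, dss, 20)
  bound <- 2200 - dss$intact_mass - 300
  expect_true(all(scored$mono_mass <= bound))
  heavy <- idx$peptides$mono_mass > bound
  expect_false(any(idx$peptides$sequence[heavy] %in% scored$sequence))
  # one row per eligible peptide (scored once, not once per partner)
  expect_equal(nrow(scored), sum(!heavy))
  expect_false(any(duplicated(scored$sequence)))
  # work is linear: one kernel evaluation per (site, delta) of the prefix
  n_sites <- lengths(idx$peptides$link_sites[!heavy])
  expect_equal(attr(scored, "n_eval"), sum(n_sites))
})

test_that("cleavable scoring records the better stub with short-stub ties", {
  dsso <- get_linker("DSSO")
  prots <- data.frame(accession = "P1", sequence = "AAKGGVLKRMMMKTTTVLKR",
                      is_decoy = FALSE)
  idx <- build_index(digest_proteins(prots), mass_range = c(300, 4000))
  # spectrum with no matching peaks at all: every score 0, tie -> short
  ps0 <- make_ps(c(3000, 3100), c(1, 1), neutral_mass = 2500)
  s0 <- score_peptides_cleavable(ps0, idx, dsso, 20)
  expect_true(all(s0$stub == "short"))
  expect_true(all(s0$score == 0))
  expect_equal(attr(s0, "n_eval"),
               2L * sum(lengths(idx$peptides$link_sites[
                 idx$peptides$mono_mass <= 2500 - dsso$intact_mass - 300])))
  # plant long-stub ions for one peptide
  pep <- s0$sequence[1]
  site <- s0$site[1]
  ions <- ions_cleavable(pep, site, dsso$stub_long, max_frag_charge = 2L)
  ps1 <- make_ps(ions$mz, rep(1, nrow(ions)), neutral_mass = 2500)
  s1 <- score_peptides_cleavable(ps1, idx, dsso, 20)
  expect_equal(s1$stub[s1$sequence == pep], "long")
})

test_that("doublet detection recovers planted stub pairs", {
  dsso <- get_linker("DSSO")
  m <- 1234.567
  mz <- c(m + dsso$stub_short + ORACLE_PROTON,
          m + dsso$stub_long + ORACLE_PROTON, 700.1)
  ps <- make_ps(mz, c(0.8, 0.6, 1.0), neutral_mass = 3000)
  d <- detect_doublets(ps, dsso, tol_ppm = 20)
  expect_equal(nrow(d[d$charge == 1L, ]), 1L)
  expect_equal(d$mass[d$charge == 1L], m, tolerance = 1e-4)
  expect_equal(d$evidence[d$charge == 1L], 1.4)
  # charge-2 spacing
  mz2 <- c(500, 500 + (dsso$stub_long - dsso$stub_short) / 2)
  d2 <- detect_doublets(make_ps(mz2, c(1, 1), neutral_mass = 3000), dsso, 20)
  expect_true(any(d2$charge == 2L))
  # no pair at the spacing -> empty
  d3 <- detect_doublets(make_ps(c(100, 150), c(1, 1), 3000), dsso, 20)
  expect_equal(nrow(d3), 0L)
})

test_that("top_pairs reproduces the pinned example with tie-breaks", {
  scores <- data.frame(
    pep = 1:3, sequence = c("AAA", "BBB", "CCC"),
    mono_mass = c(100, 200, 300), site = 0L, score = c(1, 2, 3),
    matched = 0L, stub = NA_character_, is_decoy = FALSE)
  scores$proteins <- as.list(paste0("P", 1:3))
  neutral <- 400 + dss$intact_mass
  ps <- make_ps(500, 1, neutral_mass = neutral)
  r <- top_pairs(scores, ps, dss, N = 2L, ms1_tol_ppm = 10)
  expect_equal(nrow(r$candidates), 2L)
  expect_equal(r$candidates$combined_score, c(4, 4))
  # homodimer (BBB, BBB) sorts before (CCC, AAA) on alpha sequence
  expect_equal(r$candidates$alpha_seq, c("BBB", "CCC"))
  expect_equal(r$candidates$beta_seq, c("BBB", "AAA"))
  # infeasible target -> empty result
  ps_small <- make_ps(500, 1, neutral_mass = 150 + dss$intact_mass)
  expect_equal(nrow(top_pairs(scores, ps_small, dss)$candidates), 0L)
  # homodimers can be disabled
  r2 <- top_pairs(scores, ps, dss, N = 5L, ms1_tol_ppm = 10,
                  homodimers = FALSE)
  expect_false(any(r2$candidates$alpha_seq == r2$candidates$beta_seq))
})

test_that("top_pairs equals the brute-force all-pairs oracle", {
  set.seed(71)
  for (rep in 1:40) {
    n <- sample(10:120, 1)
    scores <- random_score_table(n)
    i <- sample(nrow(scores), 1); j <- sample(nrow(scores), 1)
    neutral <- scores$mono_mass[i] + scores$mono_mass[j] + dss$intact_mass
    ps <- make_ps(500, 1, neutral_mass = neutral)
    tol <- sample(c(10, 100, 2000, 20000), 1)  # vary pair multiplicity
    N <- sample(c(1L, 5L, 20L), 1)
    got <- top_pairs(scores, ps, dss, N = N, ms1_tol_ppm = tol)$candidates
    want <- oracle_top_pairs(scores, ps, dss, N = N, ms1_tol_ppm = tol)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$alpha_seq, want$alpha_seq)
    expect_equal(got$beta_seq, want$beta_seq)
    expect_equal(got$alpha_site, want$alpha_site)
    expect_equal(got$combined_score, want$combined_score)
    # every returned pair satisfies the precursor constraint
    expect_true(all(abs(got$mass_error_ppm) <= tol + 1e-9))
  }
})

test_that("doublet evidence adds a bonus to matching candidates", {
  dsso <- get_linker("DSSO")
  scores <- data.frame(
    pep = 1:2, sequence = c("AAA", "BBB"), mono_mass = c(900, 1100),
    site = 0L, score = c(2, 1), matched = 0L, stub = "short",
    is_decoy = FALSE)
  scores$proteins <- as.list(paste0("P", 1:2))
  neutral <- 2000 + dsso$intact_mass
  ps <- make_ps(500, 1, neutral_mass = neutral)
  doub <- data.frame(mass = 900.001, evidence = 1.5, charge = 1L)
  r <- top_pairs(scores, ps, dsso, N = 5L, ms1_tol_ppm = 10,
                 ms2_tol_ppm = 20, doublet_bonus = 1, doublets = doub)
  expect_equal(r$candidates$doublet_evidence, 1.5)
  expect_equal(r$candidates$combined_score,
               r$candidates$alpha_score + r$candidates$beta_score + 1.5)
  r0 <- top_pairs(scores, ps, dsso, N = 5L, ms1_tol_ppm = 10,
                  ms2_tol_ppm = 20, doublet_bonus = 0, doublets = doub)
  expect_equal(r0$candidates$doublet_evidence, 0)
})
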