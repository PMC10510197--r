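# Builders for hand-made spectrum results.
mk_cand <- function(aseq, ascore, aprot, bseq, bscore, bprot,
                    adecoy = FALSE, bdecoy = FALSE, asite = 0L, bsite = 0L) {
  df <- data.frame(
    alpha_seq = aseq, alpha_site = asite, alpha_score = ascore,
    alpha_mass = 1000, alpha_is_decoy = adecoy, alpha_stub = NA_character_,
    beta_seq = bseq, beta_site = bsite, beta_score = bscore,
    beta_mass = 900, beta_is_decoy = bdecoy, beta_stub = NA_character_,
    doublet_evidence = 0, stringsAsFactors = FALSE)
  df$alpha_proteins <- list(aprot)
  df$beta_proteins <- list(bprot)
  df$combined_score <- df$alpha_score + df$beta_score
  df$mass_error_ppm <- 0
  df$decoy_class <- if (adecoy && bdecoy) "DD" else
    if (!adecoy && !bdecoy) "TT" else "TD"
  df
}

mk_result <- function(id, ...) {
  cand <- do.call(rbind, list(...))
  cand <- cand[order(-cand$combined_score, cand$alpha_seq, cand$beta_seq), ]
  rownames(cand) <- NULL
  structure(list(spectrum_id = id, neutral_mass = 2038, candidates = cand),
            class = "spectrum_result")
}

test_that("the 80% candidate filter keeps the top and near-top", {
  r <- mk_result("s1",
                 mk_cand("AAA", 6, "P1", "BBB", 4, "P2"),
                 mk_cand("CCC", 5, "P3", "DDD", 4, "P4"),
                 mk_cand("EEE", 4.4, "P5", "FFF", 3.5, "P6"))
  # combined scores 10, 9, 7.9: 7.9 < 0.8 * 10
  f <- filter_candidates(r, 0.8)
  expect_equal(f$candidates$combined_score, c(10, 9))
  # ratio 1: only exact ties with the top survive
  f1 <- filter_candidates(r, 1.0)
  expect_equal(nrow(f1$candidates), 1L)
  # single candidate always kept
  r1 <- mk_result("s2", mk_cand("AAA", 1, "P1", "BBB", 0.5, "P2"))
  expect_equal(nrow(filter_candidates(r1, 0.8)$candidates), 1L)
})

test_that("collect_first_hits applies the data-driven cutoff and drops decoys", {
  # well-separated targets above, decoys below
  results <- c(
    lapply(1:10, function(i)
      mk_result(paste0("hi", i),
                mk_cand("AAA", 10 + i, "P1", "BBB", 8, "P2"))),
    lapply(1:4, function(i)
      mk_result(paste0("lo", i),
                mk_cand("XXX", 1 + 0.1 * i, "RP", "YYY", 0.5, "RQ",
                        adecoy = TRUE))))
  hits <- collect_first_hits(results, firsthit_fdr = 0.10)
  expect_equal(nrow(hits), 10L)
  expect_true(all(hits$decoy_class == "TT"))
  expect_true(all(hits$combined_score >= 18))

  # all first hits decoys -> empty with a warning
  dec <- lapply(1:3, function(i)
    mk_result(paste0("d", i),
              mk_cand("XXX", 5, "RP", "YYY", 4, "RQ", adecoy = TRUE,
                      bdecoy = TRUE)))
  expect_warning(h0 <- collect_first_hits(dec, 0.10), "no first hit")
  expect_equal(nrow(h0), 0L)

  # firsthit_fdr = 1 admits every target-target first hit
  all_tt <- collect_first_hits(results, firsthit_fdr = 1.0)
  expect_equal(nrow(all_tt), 10L)
})

test_that("protein scores accumulate per-peptide site scores over parents", {
  hits <- rbind(mk_cand("AAA", 5, "P1", "BBB", 3, "P2"),
                mk_cand("CCC", 4, c("P1", "P3"), "DDD", 1, "P2"))
  db <- build_protein_scores(hits)
  expect_equal(unname(db["P1"]), 9)   # 5 + shared-peptide credit 4
  expect_equal(unname(db["P3"]), 4)
  expect_equal(unname(db["P2"]), 4)   # 3 + 1
  # empty database: every lookup is 0
  db0 <- build_protein_scores(hits[0, ])
  expect_equal(length(db0), 0L)
  expect_equal(protein_score(db0, "P1"), 0)
})

test_that("decoy accessions read their target mirror's weight", {
  hits <- mk_cand("AAA", 5, "P1", "BBB", 3, "P2")
  db <- build_protein_scores(hits)
  expect_equal(protein_score(db, "REV_P1"), 5)
  expect_equal(protein_score(db, "REV_P9"), 0)
  expect_equal(protein_score(db, c("P2", "REV_P1")), 5)
})

test_that("rerank keeps the top pair under an empty database", {
  r <- mk_result("s1",
                 mk_cand("AAA", 6, "P1", "BBB", 4, "P2"),
                 mk_cand("CCC", 5, "P3", "DDD", 4, "P4"))
  db0 <- structure(numeric(), class = "protein_score_db")
  out <- rerank_candidates(r, db0)
  expect_equal(out$alpha_seq, "AAA")
  expect_equal(out$feedback_score, 0)
  expect_null(rerank_candidates(
    structure(list(spectrum_id = "e", candidates = r$candidates[0, ]),
              class = "spectrum_result"), db0))
})

test_that("protein support can overturn a small spectral margin", {
  r <- mk_result("s1",
                 mk_cand("AAA", 6, "P1", "BBB", 4, "Punk"),
                 mk_cand("AAA", 6, "P1", "DDD", 3, "Phub"))
  db <- structure(c(Phub = 200, P1 = 300), class = "protein_score_db")
  out <- rerank_candidates(r, db)
  # feedback advantage ln(1+200) = 5.3 nats beats the 1-point score deficit
  expect_equal(out$beta_seq, "DDD")
  expect_gt(out$feedback_score, 5)
  # but a large spectral margin survives modest support
  r2 <- mk_result("s2",
                  mk_cand("AAA", 16, "P1", "BBB", 4, "Punk"),
                  mk_cand("AAA", 6, "P1", "DDD", 3, "Phub"))
  expect_equal(rerank_candidates(r2, db)$beta_seq, "BBB")
})

test_that("raising a winner's protein weight never dethrones it", {
  set.seed(81)
  for (rep in 1:30) {
    n <- sample(2:6, 1)
    cands <- lapply(seq_len(n), function(i)
      mk_cand(paste0("A", i), runif(1, 0, 10), paste0("PA", i),
              paste0("B", i), runif(1, 0, 5), paste0("PB", i)))
    r <- do.call(mk_result, c(list("s"), cands))
    w <- runif(2 * n, 0, 50)
    names(w) <- c(paste0("PA", 1:n), paste0("PB", 1:n))
    db <- structure(w, class = "protein_score_db")
    win <- rerank_candidates(r, db)
    db2 <- db
    db2[win$alpha_proteins[[1]][1]] <- db2[win$alpha_proteins[[1]][1]] + 100
    win2 <- rerank_candidates(r, db2)
    expect_equal(win2$alpha_seq, win$alpha_seq)
    expect_equal(win2$beta_seq, win$beta_seq)
  }
})
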