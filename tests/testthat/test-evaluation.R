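test_that("binary-overlap presence follows the 50% gold-token rule", {
  corpus <- tiny_corpus()
  ext <- rbind(
    make_extraction("n1", "c1_f1", "denies fever"), # exact
    make_extraction("n1", "c1_f2", "chest pain"), # exact
    make_extraction("n1", "c1_f3", ""), # gold absent, nothing asserted
    make_extraction("n2", "c1_f1", ""), # gold absent
    make_extraction("n2", "c1_f2", ""), # FN: gold present, no extraction
    make_extraction("n2", "c1_f3", "diarhea") # exact
  )
  dec <- presence_decisions(ext, corpus, "binary_overlap", run_gate = TRUE)
  expect_identical(
    dec$present_pred,
    c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE)
  )
  expect_identical(
    dec$present_gold,
    c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE)
  )
  m <- prf(dec)
  expect_identical(m$tp, 3L)
  expect_identical(m$fn, 1L)
  expect_identical(m$fp, 0L)
})

test_that("word-order-insensitive overlap still counts as present", {
  corpus <- list(
    notes = tibble::tibble(
      note_id = "n1", case_id = "c1",
      text = "reports shortness of breath today."
    ),
    features = tibble::tibble(
      feature_id = "f1", case_id = "c1", description = "shortness of breath"
    ),
    gold = tibble::tibble(
      note_id = "n1", feature_id = "f1", texts = list("shortness of breath"),
      spans = list(list(matrix(c(8L, 27L),
        ncol = 2,
        dimnames = list(NULL, c("start", "end"))
      )))
    )
  )
  ext <- make_extraction("n1", "f1", "breath shortness")
  dec <- presence_decisions(ext, corpus, "binary_overlap", run_gate = TRUE)
  expect_true(dec$present_pred) # 2/3 gold tokens recovered >= 0.5
  expect_equal(dec$similarity, 2 / 3)
})

test_that("semantic presence thresholds at 0.5 and flags the borderline band", {
  corpus <- tiny_corpus()
  # controlled embedder: angle chosen per extraction text
  emb <- function(text) {
    switch(text,
      "fever" = c(1, 0),
      "borderline probe" = c(0.6, sqrt(1 - 0.36)),
      "orthogonal probe" = c(0, 1),
      c(1, 0) # feature descriptions and anything else
    )
  }
  ext <- rbind(
    make_extraction("n1", "c1_f1", "fever"), # sim 1, in note
    make_extraction("n1", "c1_f2", "chest pain") # sim 1 via fallback vector
  )
  dec <- presence_decisions(ext, corpus, "semantic", embedder = emb, run_gate = TRUE)
  expect_true(all(dec$present_pred))
  expect_false(any(dec$borderline))

  # borderline: validated text with cosine 0.6 against the description
  corpus2 <- corpus
  corpus2$notes$text[1] <- paste(corpus$notes$text[1], "borderline probe noted.")
  ext2 <- make_extraction("n1", "c1_f1", "borderline probe")
  dec2 <- presence_decisions(ext2, corpus2, "semantic", embedder = emb, run_gate = TRUE)
  expect_true(dec2$present_pred)
  expect_true(dec2$borderline)
  expect_equal(dec2$similarity, 0.6)

  # gate precedence: fabricated text is absent regardless of similarity
  ext3 <- make_extraction("n1", "c1_f1", "zygomatic implosion")
  dec3 <- presence_decisions(ext3, corpus, "semantic", embedder = function(t) c(1, 0), run_gate = TRUE)
  expect_false(dec3$present_pred)
  expect_false(dec3$validated)
})

test_that("precision/recall/F1 follow the stated conventions", {
  d <- make_decisions(
    pred = c(rep(TRUE, 10), rep(FALSE, 3)),
    gold = c(rep(TRUE, 9), FALSE, rep(TRUE, 3))
  )
  m <- prf(d)
  expect_equal(m$precision, 0.9)
  expect_equal(m$recall, 0.75)
  expect_equal(m$f1, 2 * 0.9 * 0.75 / 1.65)

  all_right <- make_decisions(pred = c(TRUE, TRUE), gold = c(TRUE, TRUE))
  expect_equal(prf(all_right)$f1, 1)

  none_pred <- make_decisions(pred = rep(FALSE, 5), gold = rep(TRUE, 5))
  m0 <- prf(none_pred)
  expect_equal(c(m0$precision, m0$recall, m0$f1), c(0, 0, 0))

  vacuous <- make_decisions(pred = rep(FALSE, 3), gold = rep(FALSE, 3))
  m1 <- prf(vacuous)
  expect_equal(c(m1$precision, m1$recall, m1$f1), c(1, 1, 1))

  mixed <- rbind(
    make_decisions(TRUE, TRUE, mode = "binary_overlap"),
    make_decisions(TRUE, TRUE, mode = "semantic")
  )
  expect_error(prf(mixed), "mix")
})

test_that("ECE reproduces hand-computed bin gaps and the brute-force oracle", {
  # perfectly calibrated within bins
  expect_equal(ece(c(0.65, 0.75), c(0.65, 0.75)), 0)
  # single bin: all confidence 0.9, all score 0.6
  expect_equal(ece(rep(0.9, 4), rep(0.6, 4)), 0.3, tolerance = 1e-12)
  # two bins with counts 3 and 1
  confs <- c(0.65, 0.66, 0.64, 0.95)
  scores <- c(0.5, 0.6, 0.4, 0.9)
  gap1 <- abs(mean(confs[1:3]) - mean(scores[1:3]))
  gap2 <- abs(0.95 - 0.9)
  expect_equal(ece(confs, scores), (3 * gap1 + 1 * gap2) / 4, tolerance = 1e-12)
  expect_error(ece(c(0.5), c(0.5, 0.6)), "equal length")
  expect_warning(z <- ece(numeric(0), numeric(0)), "ECE")
  expect_equal(z, 0)

  set.seed(19)
  for (i in 1:20) {
    c_i <- stats::runif(50)
    s_i <- stats::runif(50)
    expect_equal(ece(c_i, s_i), oracle_ece(c_i, s_i), tolerance = 1e-12)
    expect_equal(
      ece(c_i, s_i, underflow = FALSE),
      oracle_ece(c_i, s_i, underflow = FALSE),
      tolerance = 1e-12
    )
  }
})

test_that("Brier score is the mean squared confidence-score gap", {
  expect_equal(brier(c(0.5, 0.7), c(0.5, 0.7)), 0)
  expect_equal(brier(1, 0), 1)
  expect_equal(brier(c(0.8, 0.9), c(0.6, 0.9)), 0.02)
  set.seed(23)
  c_i <- stats::runif(100)
  s_i <- stats::runif(100)
  perm <- sample(100)
  expect_equal(brier(c_i, s_i), brier(c_i[perm], s_i[perm]))
  expect_gte(brier(c_i, s_i), 0)
  expect_lte(brier(c_i, s_i), 1)
})

test_that("reliability table reports per-bin means and signed gaps", {
  # a bin whose mean score is 0.692 sits 0.308 below optimal performance
  confs <- rep(0.65, 3)
  scores <- c(0.676, 0.7, 0.7) # mean 0.692
  tab <- reliability_table(confs, scores)
  bin <- tab[tab$lower == 0.6, ]
  expect_equal(bin$mean_score, 0.692)
  expect_equal(bin$gap_to_optimum, -0.308)
  expect_equal(bin$gap, 0.692 - 0.65)
  # perfectly calibrated bin has zero confidence gap
  tab2 <- reliability_table(c(0.75, 0.85), c(0.75, 0.85))
  expect_equal(tab2$gap[tab2$count > 0], c(0, 0))
  # brute-force check of constructed two-bin means
  confs3 <- c(0.61, 0.69, 0.91, 0.99)
  scores3 <- c(0.2, 0.4, 0.8, 1.0)
  tab3 <- reliability_table(confs3, scores3)
  expect_equal(tab3$mean_confidence[tab3$lower == 0.6], mean(c(0.61, 0.69)))
  expect_equal(tab3$mean_score[tab3$lower == 0.9], mean(c(0.8, 1.0)))
  expect_identical(tab3$count[tab3$lower == 0.7], 0L)
})

test_that("the error ledger reproduces printed-style rates and reductions", {
  mk <- function(total, halluc, missing) {
    correct <- total - halluc - missing
    make_decisions(
      pred = c(rep(FALSE, halluc), rep(FALSE, missing), rep(TRUE, correct)),
      gold = c(rep(FALSE, halluc), rep(TRUE, missing), rep(TRUE, correct)),
      asserted = c(rep(TRUE, halluc), rep(FALSE, missing), rep(TRUE, correct)),
      note_id = rep("n1", total)
    )
  }
  # vanilla private split: 3081 hallucinated of 20360; final model: 311
  ledger <- error_ledger(list(
    vanilla = mk(20360, 3081, 6376),
    final = mk(20360, 311, 708)
  ))
  expect_equal(ledger$hallucination_rate, c(15.1, 1.5))
  expect_equal(ledger$hallucination_reduction, c(0, 89.9))
  expect_equal(ledger$miss_reduction, c(0, 88.9))
  # vanilla public split: 599 missing of 2861 features is a 20.9% miss rate
  ledger2 <- error_ledger(list(vanilla = mk(2861, 335, 599)))
  expect_equal(ledger2$miss_rate, 20.9)
  expect_equal(ledger2$hallucination_rate, 11.7)
  # identical counts give 0.0% reduction; zero baseline is undefined
  same <- error_ledger(list(a = mk(100, 10, 5), b = mk(100, 10, 5)))
  expect_equal(same$hallucination_reduction, c(0, 0))
  none <- error_ledger(list(a = mk(100, 0, 5), b = mk(100, 2, 5)))
  expect_true(all(is.na(none$hallucination_reduction)))
})

test_that("percent reduction rounds half-up to one decimal", {
  expect_equal(percent_reduction(3081, 311), 89.9)
  expect_equal(percent_reduction(599, 62), 89.6)
  expect_equal(percent_reduction(100, 100), 0)
  expect_true(is.na(percent_reduction(0, 5)))
})

test_that("per-feature rates are complement precision/recall per feature", {
  d <- tibble::tibble(
    note_id = c("n1", "n2", "n3", "n1", "n2"),
    feature_id = c("f1", "f1", "f1", "f2", "f2"),
    asserted = c(TRUE, TRUE, FALSE, TRUE, FALSE),
    validated = c(TRUE, TRUE, FALSE, TRUE, FALSE),
    present_pred = c(TRUE, TRUE, FALSE, TRUE, FALSE),
    present_gold = c(TRUE, FALSE, TRUE, TRUE, TRUE),
    mode = "binary_overlap", similarity = NA_real_, borderline = FALSE
  )
  rates <- per_feature_error_rates(d)
  f1r <- rates[rates$feature_id == "f1", ]
  expect_equal(f1r$hallucination_rate, 1 / 2) # FP 1 of TP+FP 2
  expect_equal(f1r$miss_rate, 1 / 2) # FN 1 of TP+FN 2
  f2r <- rates[rates$feature_id == "f2", ]
  expect_equal(f2r$hallucination_rate, 0)
  expect_equal(f2r$miss_rate, 1 / 2)
})

test_that("paired comparison: identity, exact McNemar, and symmetry", {
  d <- make_decisions(
    pred = c(TRUE, TRUE, FALSE, FALSE, TRUE),
    gold = c(TRUE, FALSE, TRUE, FALSE, TRUE),
    note_id = c("n1", "n1", "n2", "n2", "n3")
  )
  same <- paired_comparison(d, d, n_boot = 200, seed = 42)
  expect_equal(same$f1_diff, 0)
  expect_lte(same$ci95[1], 0)
  expect_gte(same$ci95[2], 0)
  expect_equal(same$mcnemar_p, 1)

  # B corrects 10 of A's errors, A corrects none of B's:
  # exact binomial tail p = 2 * 0.5^10
  a <- make_decisions(
    pred = rep(FALSE, 12), gold = rep(TRUE, 12),
    note_id = paste0("n", 1:12)
  )
  b <- a
  b$present_pred[1:10] <- TRUE
  cmp <- paired_comparison(a, b, n_boot = 200, seed = 1)
  expect_identical(unname(cmp$discordant), c(0L, 10L))
  expect_equal(cmp$mcnemar_p, 2 * 0.5^10, tolerance = 1e-12)
  expect_gt(cmp$f1_diff, 0)

  # symmetry up to sign
  rev <- paired_comparison(b, a, n_boot = 200, seed = 1)
  expect_equal(rev$f1_diff, -cmp$f1_diff)
  expect_equal(rev$mcnemar_p, cmp$mcnemar_p)
  expect_identical(unname(rev$discordant), c(10L, 0L))

  # misaligned keys are rejected
  shifted <- d
  shifted$feature_id <- paste0(shifted$feature_id, "_x")
  expect_error(paired_comparison(d, shifted), "aligned")
})

test_that("large discordant tables switch to the continuity-corrected chi-square", {
  a <- make_decisions(
    pred = rep(FALSE, 40), gold = rep(TRUE, 40),
    note_id = paste0("n", 1:40)
  )
  b <- a
  b$present_pred[1:30] <- TRUE
  cmp <- paired_comparison(a, b, n_boot = 50, seed = 2)
  expected <- stats::pchisq((abs(0 - 30) - 1)^2 / 30, df = 1, lower.tail = FALSE)
  expect_equal(cmp$mcnemar_p, expected, tolerance = 1e-12)
})

test_that("the review queue lists borderline matches then misses, by similarity", {
  d <- tibble::tibble(
    note_id = paste0("n", 1:6), feature_id = paste0("f", 1:6),
    asserted = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
    validated = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
    present_pred = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
    present_gold = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    mode = "semantic",
    similarity = c(0.65, 0.55, 0.9, NA, 0.62, 0.8),
    borderline = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)
  )
  q <- review_queue(d)
  expect_identical(q$reason, c(rep("borderline", 3), "missing"))
  expect_identical(q$feature_id[1:3], c("f2", "f5", "f1")) # ascending similarity
  expect_identical(q$feature_id[4], "f4")
  empty <- review_queue(d[3, ])
  expect_identical(nrow(empty), 0L)
  expect_error(review_queue(make_decisions(TRUE, TRUE)), "semantic")
})

test_that("accounting conservation holds on generated corpora", {
  corpus <- generate_corpus(synth_config(
    n_cases = 3, notes_per_case = 4, features_per_case = 6, seed = 15
  ))
  ext <- mock_extract(corpus, mock_profile(), seed = 16)
  dec <- presence_decisions(ext, corpus, "binary_overlap", run_gate = TRUE)
  m <- prf(dec)
  expect_identical(m$tp + m$fp, sum(dec$present_pred))
  expect_identical(m$tp + m$fn, sum(dec$present_gold))
})
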