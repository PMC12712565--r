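gold_row2 <- function(note_id, feature_id, texts) {
  tibble::tibble(
    note_id = note_id, feature_id = feature_id,
    texts = list(texts), spans = list(list())
  )
}

test_that("overconfidence penalty gates on threshold and penalty base", {
  expect_equal(overconfidence_penalty(0.8, 0.5, 0.6), 0) # c <= tau
  expect_equal(overconfidence_penalty(0.8, 0.6, 0.6), 0) # boundary: not over
  expect_equal(overconfidence_penalty(0, 0.9, 0.6), 0) # perfect F1
  expect_equal(overconfidence_penalty(0.8, 0.8, 0.6, 2), 0.8 * (0.8 + 2 * 0.04))
  expect_equal(
    overconfidence_penalty(1, 0.9, 0.6, 2, penalty_form = "quadratic_only"),
    2 * 0.09
  )
})

test_that("overconfidence penalty is continuous and monotone above threshold", {
  tau <- 0.6
  cs <- seq(tau + 1e-6, 1, length.out = 200)
  pen <- overconfidence_penalty(0.5, cs, tau)
  expect_true(all(diff(pen) > 0)) # monotone increasing in c
  # continuity as c approaches tau from above: penalty tends to base * tau
  expect_equal(overconfidence_penalty(0.5, tau + 1e-9, tau), 0.5 * tau, tolerance = 1e-6)
  # raising tau never increases the penalty
  set.seed(13)
  for (i in 1:50) {
    c <- stats::runif(1)
    base <- stats::runif(1)
    t1 <- stats::runif(1, 0, 0.9)
    t2 <- stats::runif(1, t1, 1)
    expect_lte(
      overconfidence_penalty(base, c, t2),
      overconfidence_penalty(base, c, t1) + 1e-12
    )
  }
})

test_that("note penalties compose matching, confidence and gating", {
  gold <- rbind(
    gold_row2("n1", "g1", "fever"),
    gold_row2("n1", "g2", "chest pain")
  )
  # perfect extractor: zero penalties whatever the confidence
  perfect <- rbind(
    make_extraction("n1", "g1", "fever", confidence = 0.99),
    make_extraction("n1", "g2", "chest pain", confidence = 0.95)
  )
  np <- note_penalties(perfect, gold, tau = 0.6)
  expect_equal(np$hallucination_penalty, 0)
  expect_equal(np$missing_penalty, 0)

  # one fabricated prediction at confidence 0.9 with no gold at all
  fab <- make_extraction("n1", "p1", "zygomatic implosion", confidence = 0.9)
  np2 <- note_penalties(fab, gold[0, ], tau = 0.6)
  expect_equal(np2$hallucination_penalty, 0.9 + 2 * 0.09) # base 1
  expect_equal(np2$missing_penalty, 0)
  expect_identical(np2$penalized_feature_count, 1L)

  # extractor returning nothing with k gold features
  silent <- rbind(
    make_extraction("n1", "g1", ""),
    make_extraction("n1", "g2", "")
  )
  np3 <- note_penalties(silent, gold, tau = 0.6)
  expect_equal(np3$hallucination_penalty, 0)
  expect_equal(np3$missing_penalty, 1) # all best_f1 = 0 under mean_all
})

test_that("total loss is the exact linear form and flags the gradient contract", {
  cfg <- penalty_config()
  lb <- total_loss(1, 0.5, 0.2, cfg)
  expect_equal(lb$total, 1 + 0.2 * 0.5 + 0.5 * 0.2)
  expect_true(lb$penalty_gradient)

  pure <- total_loss(0.37, 0, 0, cfg)
  expect_equal(pure$total, 0.37)
  expect_false(pure$penalty_gradient) # no penalty => no penalty gradient

  zero_w <- penalty_config(w_hallucination = 0, w_missing = 0)
  expect_equal(total_loss(1, 5, 7, zero_w)$total, 1)
  expect_error(total_loss(-1, 0, 0, cfg), "non-negative")

  set.seed(17)
  for (i in 1:25) {
    ce <- stats::runif(1, 0, 3)
    h <- stats::runif(1, 0, 2)
    m <- stats::runif(1, 0, 2)
    wh <- stats::runif(1, 0, 1)
    wm <- stats::runif(1, 0, 1)
    cfg_i <- penalty_config(w_hallucination = wh, w_missing = wm)
    expect_equal(total_loss(ce, h, m, cfg_i)$total, ce + wh * h + wm * m)
  }
})

test_that("run_epoch on a perfect generator yields zero penalties everywhere", {
  corpus <- generate_corpus(synth_config(
    n_cases = 2, notes_per_case = 2, features_per_case = 4, seed = 5
  ))
  gen <- mock_generator(corpus, mock_profile(hallucination_rate = 0, miss_rate = 0))
  out <- run_epoch(gen, corpus, epoch_state(0, 5),
    conf_cfg = confidence_config(beta_noise = 0), seed = 2
  )
  expect_true(all(out$losses$hallucination_penalty == 0))
  expect_true(all(out$losses$missing_penalty == 0))
  expect_false(any(out$losses$penalty_gradient))
  expect_equal(out$epoch_f1, 1)
  expect_equal(out$tau, 0.6)
  expect_identical(out$state$epoch_index, 1L)
})

test_that("run_epoch enforces the one-record-per-feature generator contract", {
  corpus <- generate_corpus(synth_config(
    n_cases = 1, notes_per_case = 1, features_per_case = 3, seed = 6
  ))
  bad_gen <- function(note, features) {
    tibble::tibble(
      feature_id = features$feature_id[1], text = "x", token_probs = list(0.9)
    )
  }
  expect_error(
    run_epoch(bad_gen, corpus, epoch_state(0, 5)),
    "generator contract violation on note"
  )
})

test_that("a single-note epoch reproduces the hand-computed loss composition", {
  corpus <- list(
    notes = tibble::tibble(
      note_id = "n1", case_id = "c1",
      text = "presents for evaluation. patient reports fever."
    ),
    features = tibble::tibble(
      feature_id = c("f1", "f2"), case_id = "c1",
      description = c("fever", "rash")
    ),
    gold = rbind(
      tibble::tibble(
        note_id = "n1", feature_id = "f1", texts = list("fever"),
        spans = list(list(matrix(c(41L, 46L),
          ncol = 2,
          dimnames = list(NULL, c("start", "end"))
        )))
      ),
      tibble::tibble(
        note_id = "n1", feature_id = "f2",
        texts = list(character(0)), spans = list(list())
      )
    )
  )
  # generator asserts fever correctly and hallucinates rash at high confidence
  gen <- function(note, features) {
    tibble::tibble(
      feature_id = c("f1", "f2"),
      text = c("fever", "purple spots"),
      token_probs = list(c(0.9, 0.9), c(0.8, 0.8))
    )
  }
  conf_cfg <- confidence_config(beta_noise = 0)
  out <- run_epoch(gen, corpus, epoch_state(0, 5),
    conf_cfg = conf_cfg, seed = 4
  )
  # hand trace: tau = 0.6.
  # f1 "fever": forward F1 = 1 -> base 0 -> penalty 0.
  # f2 "purple spots": forward F1 vs {"fever"} = 0 -> base 1;
  #   confidence = complexity_adjust(0.8, 2 tokens) = 0.8^(1 + 2/20) = 0.8^1.1
  c2 <- 0.8^1.1
  pen2 <- c2 + 2 * (c2 - 0.6)^2
  expect_equal(out$losses$hallucination_penalty, (0 + pen2) / 2)
  # backward: fever matched at 1, so no missing contribution
  expect_equal(out$losses$missing_penalty, 0)
  expect_equal(
    out$losses$total,
    0 + 0.2 * (0 + pen2) / 2 + 0.5 * 0
  )
  expect_identical(out$losses$penalized_feature_count, 1L)
})
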