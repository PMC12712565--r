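note1 <- tibble::tibble(
  note_id = "n1", case_id = "c1",
  text = "presents for evaluation. denies fever or chills. reports chest pain since yesterday."
)
note2 <- tibble::tibble(
  note_id = "n2", case_id = "c1",
  text = "pt has diarhea. fever started about 3 days ago."
)

test_that("step 1 finds verbatim substrings with original-text offsets", {
  d <- gate_exact("fever", note1)
  expect_identical(d$status, "validated")
  expect_identical(d$method, "exact")
  expect_identical(slice_spans(note1$text, d$spans), "fever")
  # whitespace-flexible and case-insensitive
  d2 <- gate_exact("Chest   Pain", note1)
  expect_identical(slice_spans(note1$text, d2$spans), "chest pain")
  expect_null(gate_exact("zygomatic implosion", note1))
})

test_that("step 1 falls back to Levenshtein for misspellings", {
  d <- gate_exact("diarrhea", note2, gate_config(lev_norm_min = 0.85))
  expect_identical(d$method, "levenshtein")
  expect_identical(slice_spans(note2$text, d$spans), "diarhea")
  expect_equal(levenshtein_norm("diarhea", "diarrhea"), 7 / 8) # 0.875 >= 0.85
  # a stricter threshold rejects the same misspelling
  expect_null(gate_exact("diarrhea", note2, gate_config(lev_norm_min = 0.9)))
})

test_that("step 2 aligns extraction tokens inside the best TF-IDF sentence", {
  d <- gate_sentence("no chest pain", tibble::tibble(
    note_id = "n3", case_id = "c1",
    text = "presents today. denies chest pain or pressure. vitals stable."
  ))
  expect_identical(d$status, "validated")
  expect_identical(d$method, "sentence_tfidf")
  expect_identical(d$matched_text, "chest pain")
  # extraction equal to one full sentence covers that sentence's tokens
  dfull <- gate_sentence("denies chest pain or pressure", tibble::tibble(
    note_id = "n3", case_id = "c1",
    text = "presents today. denies chest pain or pressure. vitals stable."
  ))
  expect_identical(dfull$matched_text, "denies chest pain or pressure")
  expect_null(gate_sentence("zygomatic implosion", note1))
})

test_that("step 2 can return discontinuous spans over separated token runs", {
  note <- tibble::tibble(
    note_id = "n4", case_id = "c1",
    text = "reports fever with intermittent chills overnight."
  )
  d <- gate_sentence("fever chills", note)
  expect_identical(d$status, "validated")
  expect_identical(nrow(d$spans), 2L)
  expect_identical(slice_spans(note$text, d$spans), c("fever", "chills"))
})

test_that("step 3 windowed matching matches a brute-force window oracle", {
  d <- gate_windowed("fever for 3 days", note2, gate_config(window_slack = 2))
  expect_identical(d$status, "validated")
  # covering span runs from the first to the last matched token
  expect_identical(substr(d$matched_text, 1, 5), "fever")
  expect_true(grepl("days", d$matched_text))
  expect_null(gate_windowed("zygomatic implosion binge", note2))

  # oracle: enumerate every window of the same size and check the accepted
  # fraction is the maximum
  cfg <- gate_config(window_slack = 2)
  ext <- "fever for 3 days"
  toks <- strsplit(normalize_text(note2$text), " ")[[1]]
  ext_toks <- unique(tokenize(ext))
  w <- length(tokenize(ext)) + 2
  fracs <- vapply(seq_len(length(toks) - w + 1), function(i) {
    win <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", toks[i:(i + w - 1)])
    length(intersect(ext_toks, win)) / length(ext_toks)
  }, numeric(1))
  got_frac <- length(intersect(
    ext_toks,
    tokenize(paste(slice_spans(note2$text, d$spans), collapse = " "))
  )) / length(ext_toks)
  expect_equal(got_frac, max(fracs))
})

test_that("the gate applies steps in order and records the first method", {
  expect_identical(validate_extraction("chest pain", note1)$method, "exact")
  fab <- validate_extraction("zygomatic implosion", note1)
  expect_identical(fab$status, "rejected")
  expect_identical(fab$method, "none")
  expect_identical(nrow(fab$spans), 0L)
  empty <- validate_extraction("", note1)
  expect_identical(empty$status, "rejected")
  expect_identical(empty$method, "none")
  # disabling step 1 can only hand the match to a later step, never create
  # a rejection out of different offsets
  d_all <- validate_extraction("fever", note2)
  d_no1 <- validate_extraction("fever", note2, steps = c("sentence", "windowed"))
  expect_identical(d_all$status, "validated")
  expect_identical(d_no1$status, "validated")
  expect_identical(d_all$method, "exact")
  expect_false(d_no1$method == "exact")
})

test_that("gate decisions are deterministic", {
  for (txt in c("fever", "chest pain", "no chills", "diarrhea")) {
    a <- validate_extraction(txt, note1)
    b <- validate_extraction(txt, note1)
    expect_identical(a, b)
  }
})

test_that("every validated span reconstructs its matched text from the note", {
  corpus <- generate_corpus(synth_config(
    n_cases = 3, notes_per_case = 3, features_per_case = 6, seed = 77
  ))
  ext <- mock_extract(corpus, mock_profile(paraphrase_noise = 0.3), seed = 78)
  gated <- gate_corpus(ext, corpus$notes)
  note_text <- stats::setNames(corpus$notes$text, corpus$notes$note_id)
  for (i in which(gated$gate_status == "validated")) {
    spans <- parse_location(gated$gate_location[[i]])
    expect_gt(nrow(spans), 0L)
    txt <- note_text[[gated$note_id[[i]]]]
    expect_true(all(spans[, "end"] <= nchar(txt)))
    expect_identical(
      paste(slice_spans(txt, spans), collapse = " "),
      gated$gate_matched_text[[i]]
    )
  }
  # rejected decisions carry no span
  expect_true(all(gated$gate_location[gated$gate_status == "rejected"] == ""))
})
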