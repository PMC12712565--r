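# Independent brute-force oracles. These deliberately avoid the package's
# implementation paths (no char_ngrams/adist/reliability_table) so that
# agreement is evidence, not tautology.

oracle_ngrams <- function(text, n) {
  s <- tolower(trimws(gsub("[[:space:]]+", " ", text)))
  if (nchar(s) < n) {
    return(character(0))
  }
  out <- character(nchar(s) - n + 1L)
  for (i in seq_along(out)) {
    out[[i]] <- substr(s, i, i + n - 1L)
  }
  out
}

oracle_chrf <- function(a, b, n) {
  ga <- oracle_ngrams(a, n)
  gb <- oracle_ngrams(b, n)
  norm <- function(x) tolower(trimws(gsub("[[:space:]]+", " ", x)))
  if (length(ga) == 0L || length(gb) == 0L) {
    return(if (identical(norm(a), norm(b))) 1 else 0)
  }
  inter <- 0L
  gb_pool <- gb
  for (g in ga) {
    hit <- match(g, gb_pool)
    if (!is.na(hit)) {
      inter <- inter + 1L
      gb_pool <- gb_pool[-hit]
    }
  }
  if (inter == 0L) {
    return(0)
  }
  p <- inter / length(ga)
  r <- inter / length(gb)
  2 * p * r / (p + r)
}

oracle_levenshtein <- function(a, b) {
  ca <- strsplit(a, "")[[1L]]
  cb <- strsplit(b, "")[[1L]]
  la <- length(ca)
  lb <- length(cb)
  d <- matrix(0L, la + 1L, lb + 1L)
  d[, 1L] <- 0L:la
  d[1L, ] <- 0L:lb
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      cost <- if (ca[[i]] == cb[[j]]) 0L else 1L
      d[i + 1L, j + 1L] <- min(
        d[i, j + 1L] + 1L, d[i + 1L, j] + 1L, d[i, j] + cost
      )
    }
  }
  d[la + 1L, lb + 1L]
}

oracle_overlap <- function(pred, gold) {
  tok <- function(x) {
    s <- tolower(trimws(gsub("[[:space:]]+", " ", x)))
    t <- strsplit(s, " ", fixed = TRUE)[[1L]]
    t <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", t)
    unique(t[nzchar(t)])
  }
  gt <- tok(gold)
  if (length(gt) == 0L) {
    return(0)
  }
  sum(gt %in% tok(pred)) / length(gt)
}

oracle_ece <- function(confidences, scores, edges = c(0.6, 0.7, 0.8, 0.9, 1),
                       underflow = TRUE) {
  assign_bin <- function(c) {
    if (c < edges[1L]) {
      return(if (underflow) 0L else NA_integer_)
    }
    for (b in seq_len(length(edges) - 1L)) {
      hi_ok <- if (b == length(edges) - 1L) c <= edges[b + 1L] else c < edges[b + 1L]
      if (c >= edges[b] && hi_ok) {
        return(b)
      }
    }
    NA_integer_
  }
  bins <- vapply(confidences, assign_bin, integer(1))
  keep <- !is.na(bins)
  bins <- bins[keep]
  confidences <- confidences[keep]
  scores <- scores[keep]
  if (length(confidences) == 0L) {
    return(0)
  }
  total <- 0
  for (b in unique(bins)) {
    sel <- bins == b
    total <- total + sum(sel) * abs(mean(confidences[sel]) - mean(scores[sel]))
  }
  total / length(confidences)
}

random_phrase <- function(max_tokens = 4L, alphabet = letters[1:6]) {
  k <- sample(0:max_tokens, 1L)
  if (k == 0L) {
    return("")
  }
  paste(
    vapply(seq_len(k), function(i) {
      paste(sample(alphabet, sample(1:6, 1L), replace = TRUE), collapse = "")
    }, character(1)),
    collapse = " "
  )
}

# small fully-specified corpus used by gate/evaluation tests
tiny_corpus <- function() {
  notes <- tibble::tibble(
    note_id = c("n1", "n2"),
    case_id = c("c1", "c1"),
    text = c(
      "presents for evaluation. denies fever or chills. reports chest pain since yesterday.",
      "presents for evaluation. pt has diarhea. no chest pain today."
    )
  )
  features <- tibble::tibble(
    feature_id = c("c1_f1", "c1_f2", "c1_f3"),
    case_id = "c1",
    description = c("fever", "chest pain", "diarrhea")
  )
  gold <- tibble::tibble(
    note_id = c("n1", "n1", "n1", "n2", "n2", "n2"),
    feature_id = rep(c("c1_f1", "c1_f2", "c1_f3"), 2L),
    texts = list(
      "denies fever", "chest pain", character(0),
      character(0), "no chest pain", "diarhea"
    ),
    spans = list(
      list(find_span(1L, "denies fever")), list(find_span(1L, "chest pain")), list(),
      list(), list(find_span(2L, "no chest pain")), list(find_span(2L, "diarhea"))
    )
  )
  list(notes = notes, features = features, gold = gold)
}

find_span <- function(note_idx, phrase) {
  texts <- c(
    "presents for evaluation. denies fever or chills. reports chest pain since yesterday.",
    "presents for evaluation. pt has diarhea. no chest pain today."
  )
  start <- regexpr(phrase, texts[[note_idx]], fixed = TRUE)[[1L]] - 1L
  stopifnot(start >= 0L)
  matrix(c(start, start + nchar(phrase)),
    ncol = 2L,
    dimnames = list(NULL, c("start", "end"))
  )
}

make_extraction <- function(note_id, feature_id, text,
                            token_probs = if (nzchar(text)) c(0.9, 0.9) else numeric(0),
                            confidence = NA_real_) {
  tibble::tibble(
    note_id = note_id, feature_id = feature_id, text = text,
    token_probs = list(token_probs), confidence = confidence
  )
}

# decision tables built directly (for prf/ledger/comparison tests)
make_decisions <- function(pred, gold, asserted = pred | FALSE,
                           mode = "binary_overlap",
                           note_id = paste0("n", seq_along(pred)),
                           similarity = rep(NA_real_, length(pred)),
                           borderline = rep(FALSE, length(pred))) {
  tibble::tibble(
    note_id = note_id,
    feature_id = paste0("f", seq_along(pred)),
    asserted = asserted, validated = asserted,
    present_pred = pred, present_gold = gold,
    mode = mode, similarity = similarity, borderline = borderline
  )
}
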