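#' Matching-gate configuration
#'
#' Thresholds of the three-step inference gate. All are design knobs of this
#' package, not values fixed by the method:
#'
#' * `lev_norm_min` — minimum normalized Levenshtein similarity for the
#'   misspelling fallback of step 1 (default 0.85, i.e. roughly one edit per
#'   seven characters).
#' * `tfidf_min` — minimum TF-IDF cosine between extraction and best note
#'   sentence in step 2 (default 0.5).
#' * `window_overlap_min` — minimum token-overlap fraction for the windowed
#'   match of step 3 (default 0.5).
#' * `window_slack` — extra tokens allowed in the sliding window beyond the
#'   extraction's own token count (default 2).
#'
#' @param lev_norm_min,tfidf_min,window_overlap_min,window_slack See above.
#' @return A list of class `gate_config`.
#' @export
gate_config <- function(lev_norm_min = 0.85, tfidf_min = 0.5,
                        window_overlap_min = 0.5, window_slack = 2L) {
  stopifnot(
    lev_norm_min >= 0, lev_norm_min <= 1,
    tfidf_min >= 0, tfidf_min <= 1,
    window_overlap_min >= 0, window_overlap_min <= 1,
    window_slack >= 0
  )
  structure(
    list(
      lev_norm_min = lev_norm_min, tfidf_min = tfidf_min,
      window_overlap_min = window_overlap_min,
      window_slack = as.integer(window_slack)
    ),
    class = "gate_config"
  )
}

gate_decision <- function(status, method, spans, note_text) {
  spans <- if (is.null(spans)) empty_span_matrix() else spans
  structure(
    list(
      status = status, method = method, spans = spans,
      matched_text = paste(slice_spans(note_text, spans), collapse = " ")
    ),
    class = "gate_decision"
  )
}

#' Tokenize a note keeping character offsets
#'
#' Splits on whitespace; each token carries its 0-based half-open offsets
#' into the original text and its normalized form (lowercased,
#' punctuation-stripped).
#'
#' @param text Note text.
#' @return Tibble: `token` (raw), `norm`, `start`, `end`.
#' @keywords internal
note_tokens <- function(text) {
  m <- gregexpr("[^[:space:]]+", text)[[1L]]
  if (m[1L] == -1L) {
    return(tibble::tibble(
      token = character(0), norm = character(0),
      start = integer(0), end = integer(0)
    ))
  }
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  raw <- substring(text, starts, starts + lens - 1L)
  lead <- nchar(sub("^([[:punct:]]*).*$", "\\1", raw))
  trail <- nchar(sub("^.*?([[:punct:]]*)$", "\\1", sub("^[[:punct:]]+", "", raw)))
  tibble::tibble(
    token = raw,
    norm = gsub("^[[:punct:]]+|[[:punct:]]+$", "", tolower(raw)),
    start = starts - 1L,
    end = starts + lens - 1L,
    core_start = starts - 1L + lead,
    core_end = starts + lens - 1L - trail
  )
}

#' Gate step 1: exact and Levenshtein matching
#'
#' First tries a whitespace-flexible, case-insensitive literal search for
#' the extraction in the original note (regular-expression match on escaped
#' tokens joined by a whitespace class); leftmost hit wins. Failing that,
#' slides a token-aligned window of the extraction's token count over the
#' note and accepts the best window whose normalized text reaches
#' `lev_norm_min` normalized Levenshtein similarity — this is the
#' misspelling path. Offsets always index the original note text.
#'
#' @param extraction_text Non-empty extraction text.
#' @param note One row of the notes table (needs `text`).
#' @param cfg A [gate_config()].
#' @return A `gate_decision` (status `"validated"`, method `"exact"` or
#'   `"levenshtein"`) or `NULL` when no match.
#' @export
gate_exact <- function(extraction_text, note, cfg = gate_config()) {
  text <- note$text
  chunks <- strsplit(normalize_text(extraction_text), " ", fixed = TRUE)[[1L]]
  chunks <- chunks[nzchar(chunks)]
  if (length(chunks) == 0L) {
    return(NULL)
  }
  esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", chunks)
  pattern <- paste(esc, collapse = "[[:space:]]+")
  m <- regexpr(pattern, text, ignore.case = TRUE)
  if (m[1L] != -1L) {
    start <- as.integer(m) - 1L
    end <- start + attr(m, "match.length")
    spans <- matrix(c(start, end), ncol = 2L, dimnames = list(NULL, c("start", "end")))
    return(gate_decision("validated", "exact", spans, text))
  }
  # Levenshtein fallback on token-aligned windows
  toks <- note_tokens(text)
  k <- length(tokenize(extraction_text))
  if (nrow(toks) == 0L || k == 0L || nrow(toks) < k) {
    return(NULL)
  }
  target <- paste(tokenize(extraction_text), collapse = " ")
  best <- NULL
  for (i in seq_len(nrow(toks) - k + 1L)) {
    # compare punctuation-stripped token cores; the span covers the cores
    window <- paste(toks$norm[i:(i + k - 1L)], collapse = " ")
    sim <- levenshtein_norm(window, target)
    if (sim >= cfg$lev_norm_min && (is.null(best) || sim > best$sim)) {
      best <- list(
        sim = sim,
        start = toks$core_start[[i]], end = toks$core_end[[i + k - 1L]]
      )
    }
  }
  if (is.null(best)) {
    return(NULL)
  }
  spans <- matrix(c(best$start, best$end),
    ncol = 2L,
    dimnames = list(NULL, c("start", "end"))
  )
  gate_decision("validated", "levenshtein", spans, text)
}

split_sentences <- function(text) {
  m <- gregexpr("[^.;!?\n]+", text)[[1L]]
  if (m[1L] == -1L) {
    return(tibble::tibble(sentence = character(0), start = integer(0), end = integer(0)))
  }
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  tibble::tibble(
    sentence = substring(text, starts, starts + lens - 1L),
    start = starts - 1L,
    end = starts + lens - 1L
  )
}

#' Gate step 2: sentence-level TF-IDF matching with segment alignment
#'
#' Splits the note into sentences (on `.`, `;`, `!`, `?` and newlines; no
#' sentence model), scores each against the extraction by TF-IDF cosine
#' with the note's sentences as the background corpus, and — if the best
#' sentence reaches `tfidf_min` — aligns the extraction's tokens to that
#' sentence's matching token runs, returning their covering intervals
#' (possibly discontinuous).
#'
#' @inheritParams gate_exact
#' @return A `gate_decision` (method `"sentence_tfidf"`) or `NULL`.
#' @export
gate_sentence <- function(extraction_text, note, cfg = gate_config()) {
  text <- note$text
  sents <- split_sentences(text)
  if (nrow(sents) == 0L) {
    return(NULL)
  }
  sims <- vapply(sents$sentence, function(s) {
    tfidf_cosine(extraction_text, s, corpus = sents$sentence)
  }, numeric(1))
  best <- which.max(sims)
  if (sims[[best]] < cfg$tfidf_min) {
    return(NULL)
  }
  # align extraction tokens to runs of matching tokens in the best sentence
  ext_tokens <- unique(tokenize(extraction_text))
  sent_text <- sents$sentence[[best]]
  toks <- note_tokens(sent_text)
  hit <- toks$norm %in% ext_tokens & nzchar(toks$norm)
  if (!any(hit)) {
    return(NULL)
  }
  idx <- which(hit)
  runs <- split(idx, cumsum(c(1L, diff(idx) != 1L)))
  offset <- sents$start[[best]]
  spans <- do.call(rbind, lapply(runs, function(r) {
    c(
      start = offset + toks$core_start[[r[1L]]],
      end = offset + toks$core_end[[r[length(r)]]]
    )
  }))
  colnames(spans) <- c("start", "end")
  gate_decision("validated", "sentence_tfidf", spans, text)
}

#' Gate step 3: windowed token-overlap matching
#'
#' Slides a token window of size `length(tokens(extraction)) + window_slack`
#' over the note and accepts the window maximizing the extraction-relative
#' token overlap, provided it reaches `window_overlap_min`. Ties are broken
#' by leftmost covering span, then shortest. The evidence span is the
#' covering interval of the window tokens that match extraction tokens, so
#' features scattered across a phrase are still localized.
#'
#' @inheritParams gate_exact
#' @return A `gate_decision` (method `"windowed"`) or `NULL`.
#' @export
gate_windowed <- function(extraction_text, note, cfg = gate_config()) {
  text <- note$text
  toks <- note_tokens(text)
  ext_tokens <- unique(tokenize(extraction_text))
  if (nrow(toks) == 0L || length(ext_tokens) == 0L) {
    return(NULL)
  }
  w <- min(length(tokenize(extraction_text)) + cfg$window_slack, nrow(toks))
  best <- NULL
  for (i in seq_len(nrow(toks) - w + 1L)) {
    win <- toks[i:(i + w - 1L), , drop = FALSE]
    frac <- length(intersect(ext_tokens, win$norm)) / length(ext_tokens)
    if (frac < cfg$window_overlap_min) next
    hit <- which(win$norm %in% ext_tokens)
    span_start <- win$core_start[[hit[1L]]]
    span_end <- win$core_end[[hit[length(hit)]]]
    better <- is.null(best) ||
      frac > best$frac ||
      (frac == best$frac && span_start < best$start) ||
      (frac == best$frac && span_start == best$start &&
        (span_end - span_start) < (best$end - best$start))
    if (better) {
      best <- list(frac = frac, start = span_start, end = span_end)
    }
  }
  if (is.null(best)) {
    return(NULL)
  }
  spans <- matrix(c(best$start, best$end),
    ncol = 2L,
    dimnames = list(NULL, c("start", "end"))
  )
  gate_decision("validated", "windowed", spans, text)
}

#' Validate an extraction against its note (three-step matching gate)
#'
#' Applies the gate steps in order — exact/Levenshtein, sentence TF-IDF,
#' windowed overlap — and returns the first success with its method
#' recorded. An empty extraction text is rejected with method `"none"`, as
#' is an extraction no step can locate. Only text-supported extractions
#' pass, which is what blocks hallucinated features at inference.
#'
#' Deterministic: identical inputs give identical decisions, ties broken by
#' leftmost-then-shortest span.
#'
#' @param extraction_text Extraction text (may be empty).
#' @param note One row of the notes table.
#' @param cfg A [gate_config()].
#' @param steps Character vector selecting which steps run (subset of
#'   `c("exact", "sentence", "windowed")`, in that fixed order).
#' @return A `gate_decision`.
#' @export
validate_extraction <- function(extraction_text, note, cfg = gate_config(),
                                steps = c("exact", "sentence", "windowed")) {
  if (!nzchar(trimws(extraction_text))) {
    return(gate_decision("rejected", "none", NULL, note$text))
  }
  if ("exact" %in% steps) {
    d <- gate_exact(extraction_text, note, cfg)
    if (!is.null(d)) {
      return(d)
    }
  }
  if ("sentence" %in% steps) {
    d <- gate_sentence(extraction_text, note, cfg)
    if (!is.null(d)) {
      return(d)
    }
  }
  if ("windowed" %in% steps) {
    d <- gate_windowed(extraction_text, note, cfg)
    if (!is.null(d)) {
      return(d)
    }
  }
  gate_decision("rejected", "none", NULL, note$text)
}

#' Gate every extraction in a corpus
#'
#' Runs [validate_extraction()] for each extraction record against its note
#' and appends the decision columns.
#'
#' @param extractions Extraction tibble.
#' @param notes Notes tibble.
#' @param cfg A [gate_config()].
#' @return The extraction tibble with added columns `gate_status`,
#'   `gate_method`, `gate_location` (span string, `"start end[;start end]"`)
#'   and `gate_matched_text`.
#' @export
gate_corpus <- function(extractions, notes, cfg = gate_config()) {
  note_by_id <- stats::setNames(split(notes, seq_len(nrow(notes))), notes$note_id)
  status <- character(nrow(extractions))
  method <- character(nrow(extractions))
  location <- character(nrow(extractions))
  matched <- character(nrow(extractions))
  for (i in seq_len(nrow(extractions))) {
    note <- note_by_id[[extractions$note_id[[i]]]]
    if (is.null(note)) {
      stop("extraction references unknown note '", extractions$note_id[[i]], "'",
        call. = FALSE
      )
    }
    d <- validate_extraction(extractions$text[[i]], note, cfg)
    status[[i]] <- d$status
    method[[i]] <- d$method
    location[[i]] <- format_location(d$spans)
    matched[[i]] <- d$matched_text
  }
  extractions$gate_status <- status
  extractions$gate_method <- method
  extractions$gate_location <- location
  extractions$gate_matched_text <- matched
  extractions
}
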