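#' Normalize free text for similarity computation
#'
#' Lowercases, collapses every run of whitespace (spaces, tabs, newlines) to a
#' single space, and strips leading/trailing space. All similarity primitives
#' in the package normalize their inputs through this function, so scores are
#' insensitive to case and whitespace layout.
#'
#' Normalization is idempotent: `normalize_text(normalize_text(x))` equals
#' `normalize_text(x)`.
#'
#' @param text Character vector (any strings, possibly empty).
#' @return Character vector of normalized strings.
#' @export
#' @examples
#' normalize_text("  Denies  Dyspnea ")  # "denies dyspnea"
normalize_text <- function(text) {
  stopifnot(is.character(text))
  out <- tolower(text)
  out <- gsub("[[:space:]]+", " ", out)
  trimws(out)
}

#' Character n-gram profile of a string
#'
#' Returns the multiset of all contiguous length-`n` character substrings of
#' the normalized text, spaces included as ordinary characters. Strings
#' shorter than `n` yield an empty profile.
#'
#' @param text A single string (normalized internally).
#' @param n N-gram order, integer >= 1.
#' @return Named integer vector: names are n-grams, values are counts.
#' @export
char_ngrams <- function(text, n = 3L) {
  check_ngram_order(n)
  stopifnot(is.character(text), length(text) == 1L)
  s <- normalize_text(text)
  len <- nchar(s)
  if (len < n) {
    return(stats::setNames(integer(0), character(0)))
  }
  starts <- seq_len(len - n + 1L)
  grams <- substring(s, starts, starts + n - 1L)
  tab <- table(grams)
  stats::setNames(as.integer(tab), names(tab))
}

check_ngram_order <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 || n != floor(n)) {
    stop("n-gram order `n` must be a single integer >= 1", call. = FALSE)
  }
  invisible(as.integer(n))
}

#' Character n-gram F1 similarity (chrF-style, single order)
#'
#' Similarity between two strings as the harmonic mean of character n-gram
#' precision and recall. Precision is the clipped-multiset intersection size
#' over the candidate's gram count; recall the same over the reference's.
#' A single n-gram order is used (default `n = 3`), not a multi-order
#' average, and the intersection clips repeated grams at the minimum count in
#' either string.
#'
#' Edge conventions: when either profile is empty (a string shorter than
#' `n`), the score is 0 unless the two normalized strings are equal, in which
#' case it is 1 — exact matches of very short features are never zero-scored.
#'
#' The score is symmetric: swapping candidate and reference exchanges
#' precision and recall and leaves F1 unchanged.
#'
#' @param candidate,reference Strings to compare (normalized internally).
#' @param n N-gram order, integer in 1..6 is typical; default 3.
#' @param set_semantics If `TRUE`, use set (presence/absence) intersection
#'   instead of clipped counts. Default `FALSE`.
#' @return A similarity in \[0, 1\].
#' @export
#' @examples
#' chrf_f1("fever", "fevers")       # 6/7 ~ 0.857
#' chrf_f1("abc", "xyz")            # 0
chrf_f1 <- function(candidate, reference, n = 3L, set_semantics = FALSE) {
  check_ngram_order(n)
  a <- normalize_text(candidate)
  b <- normalize_text(reference)
  pa <- char_ngrams(a, n)
  pb <- char_ngrams(b, n)
  if (length(pa) == 0L || length(pb) == 0L) {
    return(if (identical(a, b)) 1 else 0)
  }
  if (set_semantics) {
    pa[] <- 1L
    pb[] <- 1L
  }
  shared <- intersect(names(pa), names(pb))
  inter <- sum(pmin(pa[shared], pb[shared]))
  if (inter == 0L) {
    return(0)
  }
  p <- inter / sum(pa)
  r <- inter / sum(pb)
  2 * p * r / (p + r)
}

#' Levenshtein edit distance and its normalized similarity
#'
#' `levenshtein()` is the standard unit-cost edit distance (insertions,
#' deletions, substitutions), computed on the raw strings as given.
#' `levenshtein_norm()` maps it to a similarity
#' `1 - dist / max(nchar(a), nchar(b))`, which is 1 exactly when the strings
#' are equal (two empty strings have distance 0 and similarity 1).
#'
#' @param a,b Strings.
#' @return `levenshtein()` an integer distance; `levenshtein_norm()` a
#'   similarity in \[0, 1\].
#' @export
#' @examples
#' levenshtein("kitten", "sitting")   # 3
#' levenshtein_norm("diarhea", "diarrhea")  # 7/8
levenshtein <- function(a, b) {
  stopifnot(is.character(a), is.character(b), length(a) == 1L, length(b) == 1L)
  as.integer(utils::adist(a, b)[1L, 1L])
}

#' @rdname levenshtein
#' @export
levenshtein_norm <- function(a, b) {
  m <- max(nchar(a), nchar(b))
  if (m == 0L) {
    return(1)
  }
  1 - levenshtein(a, b) / m
}

#' Tokenize normalized text
#'
#' Tokens are the normalized text split on spaces with leading/trailing
#' punctuation stripped from each token; empty tokens are dropped. No
#' stop-word removal.
#'
#' @param text A single string.
#' @return Character vector of tokens (possibly empty).
#' @export
tokenize <- function(text) {
  s <- normalize_text(text)
  if (!nzchar(s)) {
    return(character(0))
  }
  toks <- strsplit(s, " ", fixed = TRUE)[[1L]]
  toks <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", toks)
  toks[nzchar(toks)]
}

#' Gold-relative token overlap fraction
#'
#' Fraction of the gold string's distinct tokens that also appear in the
#' prediction: `|tokens(gold) n tokens(pred)| / |tokens(gold)|` with set
#' semantics. Used for binary-overlap presence scoring ("50% of feature
#' words recovered counts as found"). Returns 0 when gold has no tokens.
#'
#' @param pred Predicted string.
#' @param gold Gold string (denominator side).
#' @return A fraction in \[0, 1\].
#' @export
#' @examples
#' token_overlap_fraction("breath shortness", "shortness of breath")  # 2/3
token_overlap_fraction <- function(pred, gold) {
  gt <- unique(tokenize(gold))
  if (length(gt) == 0L) {
    return(0)
  }
  pt <- unique(tokenize(pred))
  length(intersect(gt, pt)) / length(gt)
}

#' TF-IDF cosine similarity between two strings
#'
#' Both strings are embedded as TF-IDF vectors fitted on a supplied corpus
#' and compared by cosine. As in the standard TF-IDF fit, the vocabulary is
#' the corpus's: tokens never seen in the corpus are dropped. IDF is
#' smoothed as `log((1 + N) / (1 + df)) + 1`; term frequency is the raw
#' in-string count. All weights are non-negative, hence the cosine lies in
#' \[0, 1\].
#'
#' @param a,b Strings to compare.
#' @param corpus Non-empty character vector of documents supplying document
#'   frequencies.
#' @return Cosine similarity in \[0, 1\]; 0 if either string has no tokens.
#' @export
tfidf_cosine <- function(a, b, corpus) {
  if (!is.character(corpus) || length(corpus) == 0L) {
    stop("`corpus` must be a non-empty character vector", call. = FALSE)
  }
  docs <- lapply(corpus, tokenize)
  corpus_vocab <- unique(unlist(docs))
  ta_all <- tokenize(a)
  tb_all <- tokenize(b)
  ta <- ta_all[ta_all %in% corpus_vocab]
  tb <- tb_all[tb_all %in% corpus_vocab]
  if (length(ta) == 0L || length(tb) == 0L) {
    return(0)
  }
  vocab <- unique(c(ta, tb))
  n_docs <- length(docs)
  df <- vapply(vocab, function(w) {
    sum(vapply(docs, function(d) w %in% d, logical(1)))
  }, numeric(1))
  idf <- log((1 + n_docs) / (1 + df)) + 1
  tf <- function(tokens) vapply(vocab, function(w) sum(tokens == w), numeric(1))
  va <- tf(ta) * idf
  vb <- tf(tb) * idf
  na2 <- sqrt(sum(va^2))
  nb2 <- sqrt(sum(vb^2))
  if (na2 == 0 || nb2 == 0) {
    return(0)
  }
  min(1, sum(va * vb) / (na2 * nb2))
}

#' Embedding cosine similarity under a pluggable embedder
#'
#' The embedder is a contract, not a fixed model: any function mapping a
#' string to a fixed-length numeric vector. Cosine similarity is clipped at
#' zero so the result lies in \[0, 1\]. A zero-vector embedding yields
#' similarity 0 with a warning.
#'
#' [bow_embedder()] builds a deterministic bag-of-words embedder over a
#' fixed vocabulary, sufficient for testing and for corpora with a closed
#' feature lexicon; a real sentence-embedding model can be plugged in with
#' the same signature.
#'
#' @param a,b Strings to compare.
#' @param embedder Function: string -> numeric vector (fixed length).
#' @return Similarity in \[0, 1\].
#' @export
embed_cosine <- function(a, b, embedder) {
  stopifnot(is.function(embedder))
  va <- as.numeric(embedder(a))
  vb <- as.numeric(embedder(b))
  stopifnot(length(va) == length(vb))
  na2 <- sqrt(sum(va^2))
  nb2 <- sqrt(sum(vb^2))
  if (na2 == 0 || nb2 == 0) {
    warning("zero-vector embedding; similarity set to 0", call. = FALSE)
    return(0)
  }
  max(0, sum(va * vb) / (na2 * nb2))
}

#' @rdname embed_cosine
#' @param vocabulary Character vector of tokens spanning the embedding space.
#' @export
bow_embedder <- function(vocabulary) {
  vocabulary <- unique(vocabulary)
  force(vocabulary)
  function(text) {
    toks <- tokenize(text)
    vapply(vocabulary, function(w) sum(toks == w), numeric(1))
  }
}
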