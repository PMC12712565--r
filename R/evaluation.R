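#' Presence decisions for a gated extraction table
#'
#' Turns extraction records into per-(note, feature) presence decisions in
#' one of two modes:
#'
#' * `"binary_overlap"` — the feature is predicted present when the
#'   extraction is gate-validated and at least 50% of the gold tokens
#'   (best alternative) appear in it ([token_overlap_fraction()] >= 0.5).
#'   When the feature is gold-absent, any validated extraction counts as a
#'   false positive.
#' * `"semantic"` — the feature is predicted present when the extraction is
#'   gate-validated and the embedding cosine between the extracted text and
#'   the rubric feature description reaches 0.5; similarities in
#'   \[0.5, 0.7\] are flagged borderline for manual review.
#'
#' Gate precedence: a gate-rejected extraction is never counted present,
#' whatever its similarity. The gate can be run here (`run_gate = TRUE`) or
#' pre-computed columns `gate_status` from [gate_corpus()] can be reused.
#'
#' @param extractions Extraction tibble (all (note, feature) pairs,
#'   empty-text rows meaning "extractor reports absent").
#' @param corpus List with `notes`, `features`, `gold`.
#' @param mode `"binary_overlap"` or `"semantic"`.
#' @param embedder Embedder function for semantic mode (default: a
#'   [bow_embedder()] over the corpus feature descriptions and extractions).
#' @param gate_cfg A [gate_config()].
#' @param run_gate Run the matching gate on asserted extractions; set
#'   `FALSE` to treat every non-empty extraction as validated (cheap
#'   training-feedback metric) or when `gate_status` is already present.
#' @param overlap_min Binary-overlap presence threshold (default 0.5).
#' @param semantic_min,borderline_max Semantic presence threshold and upper
#'   edge of the borderline band (defaults 0.5 and 0.7).
#' @return Decision tibble: `note_id`, `feature_id`, `asserted`,
#'   `validated`, `present_pred`, `present_gold`, `mode`, `similarity`,
#'   `borderline`.
#' @export
presence_decisions <- function(extractions, corpus,
                               mode = c("binary_overlap", "semantic"),
                               embedder = NULL,
                               gate_cfg = gate_config(),
                               run_gate = FALSE,
                               overlap_min = 0.5,
                               semantic_min = 0.5,
                               borderline_max = 0.7) {
  mode <- match.arg(mode)
  if (run_gate && !"gate_status" %in% names(extractions)) {
    extractions <- gate_corpus(extractions, corpus$notes, gate_cfg)
  }
  if (mode == "semantic" && is.null(embedder)) {
    embedder <- bow_embedder(unlist(lapply(
      c(corpus$features$description, extractions$text), tokenize
    )))
  }
  gold_key <- paste(corpus$gold$note_id, corpus$gold$feature_id, sep = "\r")
  gold_texts <- stats::setNames(corpus$gold$texts, gold_key)
  desc <- stats::setNames(corpus$features$description, corpus$features$feature_id)

  n <- nrow(extractions)
  asserted <- nzchar(extractions$text)
  validated <- if ("gate_status" %in% names(extractions)) {
    extractions$gate_status == "validated"
  } else {
    asserted
  }
  present_gold <- logical(n)
  present_pred <- logical(n)
  similarity <- rep(NA_real_, n)
  borderline <- logical(n)
  for (i in seq_len(n)) {
    key <- paste(extractions$note_id[[i]], extractions$feature_id[[i]], sep = "\r")
    gt <- gold_texts[[key]]
    present_gold[[i]] <- !is.null(gt) && length(gt) > 0L
    if (!asserted[[i]] || !validated[[i]]) next
    if (mode == "binary_overlap") {
      if (present_gold[[i]]) {
        ov <- max(vapply(gt, function(g) {
          token_overlap_fraction(extractions$text[[i]], g)
        }, numeric(1)))
        similarity[[i]] <- ov
        present_pred[[i]] <- ov >= overlap_min
      } else {
        present_pred[[i]] <- TRUE
      }
    } else {
      d <- desc[[extractions$feature_id[[i]]]]
      sim <- embed_cosine(extractions$text[[i]], d, embedder)
      similarity[[i]] <- sim
      present_pred[[i]] <- sim >= semantic_min
      borderline[[i]] <- present_pred[[i]] && sim <= borderline_max
    }
  }
  tibble::tibble(
    note_id = extractions$note_id, feature_id = extractions$feature_id,
    asserted = asserted, validated = validated & asserted,
    present_pred = present_pred, present_gold = present_gold,
    mode = mode, similarity = similarity, borderline = borderline
  )
}

#' Precision, recall and F1 from presence decisions
#'
#' Counts TP (predicted and gold present), FP (predicted, gold absent) and
#' FN (gold present, not predicted) over the decision table and returns
#' precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and their harmonic mean.
#' Zero-denominator conventions: with no predictions but gold present, all
#' three are 0; with neither predictions nor gold, all three are 1.
#'
#' @param decisions Decision tibble from [presence_decisions()] (one mode).
#' @return List: `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
prf <- function(decisions) {
  if (length(unique(decisions$mode)) > 1L) {
    stop("decisions mix evaluation modes; score one mode at a time", call. = FALSE)
  }
  tp <- sum(decisions$present_pred & decisions$present_gold)
  fp <- sum(decisions$present_pred & !decisions$present_gold)
  fn <- sum(!decisions$present_pred & decisions$present_gold)
  if (tp + fp == 0L && tp + fn == 0L) {
    return(list(tp = tp, fp = fp, fn = fn, precision = 1, recall = 1, f1 = 1))
  }
  if (tp + fp == 0L || tp + fn == 0L || tp == 0L) {
    p <- if (tp + fp > 0L) tp / (tp + fp) else 0
    r <- if (tp + fn > 0L) tp / (tp + fn) else 0
    f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
    return(list(tp = tp, fp = fp, fn = fn, precision = p, recall = r, f1 = f1))
  }
  p <- tp / (tp + fp)
  r <- tp / (tp + fn)
  list(
    tp = tp, fp = fp, fn = fn,
    precision = p, recall = r, f1 = 2 * p * r / (p + r)
  )
}

default_bin_edges <- c(0.6, 0.7, 0.8, 0.9, 1.0)

bin_index <- function(x, edges, underflow) {
  # bins are [lower, upper) except the last, which is closed
  k <- length(edges) - 1L
  idx <- rep(NA_integer_, length(x))
  for (b in seq_len(k)) {
    upper_ok <- if (b == k) x <= edges[b + 1L] else x < edges[b + 1L]
    idx[x >= edges[b] & upper_ok] <- b
  }
  if (underflow) {
    idx[x < edges[1L]] <- 0L
  }
  idx
}

#' Expected calibration error over confidence bins
#'
#' Count-weighted mean absolute gap between mean confidence and mean
#' performance score across confidence bins. The default bins are the four
#' intervals 0.6–0.7, 0.7–0.8, 0.8–0.9 and 0.9–1.0 plus (by default) an
#' underflow bin \[0, 0.6) so low-confidence predictions are not dropped;
#' set `underflow = FALSE` to use the four bins alone. Scores are intended
#' to be continuous feature-level chrF values, keeping calibration
#' assessment granular rather than binary.
#'
#' @param confidences,scores Equal-length numeric vectors in \[0, 1\].
#' @param bin_edges Increasing bin edges (default `c(0.6, 0.7, 0.8, 0.9, 1)`).
#' @param underflow Include the `[0, bin_edges[1])` underflow bin.
#' @return The ECE (0 for empty input, with a warning).
#' @export
ece <- function(confidences, scores, bin_edges = default_bin_edges,
                underflow = TRUE) {
  check_paired(confidences, scores)
  if (length(confidences) == 0L) {
    warning("no predictions; ECE is 0 by convention", call. = FALSE)
    return(0)
  }
  tab <- reliability_table(confidences, scores, bin_edges, underflow)
  used <- tab$count > 0L
  sum(tab$count[used] * abs(tab$mean_confidence[used] - tab$mean_score[used])) /
    sum(tab$count[used])
}

#' Brier score
#'
#' Mean squared difference between predicted confidence and observed score,
#' `mean((c - s)^2)`; with continuous feature-level scores this reflects
#' both calibration and sharpness. Bounded in \[0, 1\] and invariant to pair
#' order.
#'
#' @inheritParams ece
#' @return The Brier score.
#' @export
brier <- function(confidences, scores) {
  check_paired(confidences, scores)
  if (length(confidences) == 0L) {
    return(0)
  }
  mean((confidences - scores)^2)
}

check_paired <- function(confidences, scores) {
  if (length(confidences) != length(scores)) {
    stop("confidences and scores must have equal length", call. = FALSE)
  }
  if (any(confidences < 0 | confidences > 1 | scores < 0 | scores > 1)) {
    stop("confidences and scores must lie in [0, 1]", call. = FALSE)
  }
}

#' Per-bin reliability table
#'
#' The detail behind [ece()]: per bin, the count, mean confidence, mean
#' score, the signed calibration gap `mean_score - mean_confidence`
#' (performance minus confidence: negative = overconfident), and
#' `gap_to_optimum = mean_score - 1`, the bin's distance below perfect
#' performance (the quantity quoted when a reliability diagram's bin is
#' compared with the diagonal's upper end).
#'
#' @inheritParams ece
#' @return Tibble: `lower`, `upper`, `count`, `mean_confidence`,
#'   `mean_score`, `gap`, `gap_to_optimum` (gap columns `NA` in empty bins).
#' @export
reliability_table <- function(confidences, scores,
                              bin_edges = default_bin_edges,
                              underflow = TRUE) {
  check_paired(confidences, scores)
  idx <- bin_index(confidences, bin_edges, underflow)
  bins <- if (underflow) 0L:(length(bin_edges) - 1L) else seq_len(length(bin_edges) - 1L)
  rows <- lapply(bins, function(b) {
    lower <- if (b == 0L) 0 else bin_edges[b]
    upper <- if (b == 0L) bin_edges[1L] else bin_edges[b + 1L]
    sel <- !is.na(idx) & idx == b
    cnt <- sum(sel)
    tibble::tibble(
      lower = lower, upper = upper, count = cnt,
      mean_confidence = if (cnt) mean(confidences[sel]) else NA_real_,
      mean_score = if (cnt) mean(scores[sel]) else NA_real_,
      gap = if (cnt) mean(scores[sel]) - mean(confidences[sel]) else NA_real_,
      gap_to_optimum = if (cnt) mean(scores[sel]) - 1 else NA_real_
    )
  })
  do.call(rbind, rows)
}

round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Error ledger across model variants
#'
#' Counts hallucinated and missing features per model variant on one corpus
#' and derives rates and pairwise percent reductions relative to the first
#' (baseline) variant.
#'
#' A *hallucinated* feature is an asserted extraction on a gold-absent
#' feature. By default gate-rejected assertions count too (an extractor that
#' asserts a feature the gate cannot find in the note has hallucinated it);
#' with `count_rejected = FALSE` only gate-validated false positives count.
#' A *missing* feature is a gold-present feature not predicted present
#' (a false negative). Rates are percentages of the total feature count,
#' reported to 1 decimal (half-up); `reduction = 100 * (baseline - model) /
#' baseline`, also to 1 decimal, `NA` when the baseline count is 0.
#'
#' @param decisions_by_model Named list of decision tibbles from
#'   [presence_decisions()], the first being the baseline.
#' @param count_rejected Count gate-rejected assertions on gold-absent
#'   features as hallucinations (default `TRUE`).
#' @return Tibble: `model`, `hallucinated_count`, `missing_count`,
#'   `total_features`, `hallucination_rate`, `miss_rate`,
#'   `hallucination_reduction`, `miss_reduction`.
#' @export
error_ledger <- function(decisions_by_model, count_rejected = TRUE) {
  stopifnot(is.list(decisions_by_model), length(decisions_by_model) >= 1L)
  if (is.null(names(decisions_by_model))) {
    names(decisions_by_model) <- paste0("model_", seq_along(decisions_by_model))
  }
  rows <- lapply(names(decisions_by_model), function(nm) {
    d <- decisions_by_model[[nm]]
    halluc <- if (count_rejected) {
      sum(d$asserted & !d$present_gold)
    } else {
      sum(d$present_pred & !d$present_gold)
    }
    missing <- sum(d$present_gold & !d$present_pred)
    total <- nrow(d)
    tibble::tibble(
      model = nm,
      hallucinated_count = halluc, missing_count = missing,
      total_features = total,
      hallucination_rate = round_half_up(100 * halluc / total),
      miss_rate = round_half_up(100 * missing / total)
    )
  })
  out <- do.call(rbind, rows)
  base <- out[1L, ]
  out$hallucination_reduction <- percent_reduction(
    base$hallucinated_count, out$hallucinated_count
  )
  out$miss_reduction <- percent_reduction(base$missing_count, out$missing_count)
  out
}

#' Percent reduction of an error count relative to a baseline
#'
#' `100 * (baseline - value) / baseline`, rounded half-up to 1 decimal;
#' `NA` when the baseline is 0 (undefined).
#'
#' @param baseline,value Non-negative counts (vectorized over `value`).
#' @return Percent reduction(s), 1 decimal.
#' @export
#' @examples
#' percent_reduction(3081, 311)  # 89.9
percent_reduction <- function(baseline, value) {
  baseline <- rep_len(baseline, length(value))
  ifelse(baseline > 0, round_half_up(100 * (baseline - value) / baseline), NA_real_)
}

#' Per-feature hallucination and miss rates
#'
#' For each rubric feature: the hallucination rate `FP / (TP + FP)` (the
#' complement of per-feature precision) and the miss rate `FN / (TP + FN)`
#' (complement of per-feature recall), with `NA` where a denominator is 0.
#'
#' @param decisions Decision tibble from [presence_decisions()].
#' @return Tibble: `feature_id`, `tp`, `fp`, `fn`, `hallucination_rate`,
#'   `miss_rate`.
#' @export
per_feature_error_rates <- function(decisions) {
  ids <- unique(decisions$feature_id)
  rows <- lapply(ids, function(fid) {
    d <- decisions[decisions$feature_id == fid, , drop = FALSE]
    tp <- sum(d$present_pred & d$present_gold)
    fp <- sum(d$present_pred & !d$present_gold)
    fn <- sum(!d$present_pred & d$present_gold)
    tibble::tibble(
      feature_id = fid, tp = tp, fp = fp, fn = fn,
      hallucination_rate = if (tp + fp > 0L) fp / (tp + fp) else NA_real_,
      miss_rate = if (tp + fn > 0L) fn / (tp + fn) else NA_real_
    )
  })
  do.call(rbind, rows)
}

#' Paired model comparison: bootstrap F1 difference and McNemar test
#'
#' Compares two decision tables aligned on identical (note, feature) pairs.
#' The F1 difference (`B - A`) is bootstrapped by resampling *notes* with
#' replacement (the test-set unit), giving a percentile 95% CI. Per-feature
#' correctness (`present_pred == present_gold`) feeds a McNemar test on the
#' discordant-pair table: exact binomial when fewer than 25 discordant
#' pairs, chi-squared with continuity correction otherwise. No discordant
#' pairs gives p = 1.
#'
#' @param decisions_a,decisions_b Decision tibbles on the same pairs
#'   (A first, e.g. the baseline).
#' @param n_boot Bootstrap replicates (default 10000).
#' @param seed RNG seed for the bootstrap.
#' @param exact_max Use the exact binomial McNemar below this many
#'   discordant pairs (default 25).
#' @return List: `f1_a`, `f1_b`, `f1_diff`, `ci95` (length-2), `mcnemar_p`,
#'   `discordant` (named: `a_only_correct`, `b_only_correct`).
#' @export
paired_comparison <- function(decisions_a, decisions_b, n_boot = 10000L,
                              seed = 1L, exact_max = 25L) {
  key_a <- paste(decisions_a$note_id, decisions_a$feature_id, sep = "\r")
  key_b <- paste(decisions_b$note_id, decisions_b$feature_id, sep = "\r")
  if (!setequal(key_a, key_b) || anyDuplicated(key_a) || anyDuplicated(key_b)) {
    stop("decision tables are not aligned on identical (note, feature) pairs",
      call. = FALSE
    )
  }
  decisions_b <- decisions_b[match(key_a, key_b), , drop = FALSE]

  f1_a <- prf(decisions_a)$f1
  f1_b <- prf(decisions_b)$f1

  notes <- unique(decisions_a$note_id)
  idx_by_note <- split(seq_len(nrow(decisions_a)), decisions_a$note_id)
  set.seed(seed)
  diffs <- vapply(seq_len(n_boot), function(b) {
    take <- unlist(idx_by_note[sample(notes, length(notes), replace = TRUE)],
      use.names = FALSE
    )
    prf(decisions_b[take, , drop = FALSE])$f1 -
      prf(decisions_a[take, , drop = FALSE])$f1
  }, numeric(1))
  ci95 <- unname(stats::quantile(diffs, c(0.025, 0.975), type = 7))

  correct_a <- decisions_a$present_pred == decisions_a$present_gold
  correct_b <- decisions_b$present_pred == decisions_b$present_gold
  n01 <- sum(correct_a & !correct_b) # A only correct
  n10 <- sum(!correct_a & correct_b) # B only correct
  nd <- n01 + n10
  mcnemar_p <- if (nd == 0L) {
    1
  } else if (nd < exact_max) {
    stats::binom.test(n10, nd, p = 0.5)$p.value
  } else {
    stat <- (abs(n01 - n10) - 1)^2 / nd
    stats::pchisq(stat, df = 1L, lower.tail = FALSE)
  }
  list(
    f1_a = f1_a, f1_b = f1_b, f1_diff = f1_b - f1_a, ci95 = ci95,
    mcnemar_p = mcnemar_p,
    discordant = c(a_only_correct = n01, b_only_correct = n10)
  )
}

#' Manual-review queue from semantic decisions
#'
#' Items needing human eyes: borderline matches (similarity in the
#' \[0.5, 0.7\] band) ordered by ascending similarity, followed by all
#' missing features (false negatives). Each item carries its similarity and
#' reason.
#'
#' @param decisions Semantic-mode decision tibble.
#' @return Tibble: `note_id`, `feature_id`, `reason`
#'   (`"borderline"`/`"missing"`), `similarity`.
#' @export
review_queue <- function(decisions) {
  if (!all(decisions$mode == "semantic")) {
    stop("review_queue expects semantic-mode decisions", call. = FALSE)
  }
  bl <- decisions[decisions$borderline, , drop = FALSE]
  bl <- bl[order(bl$similarity), , drop = FALSE]
  fn <- decisions[decisions$present_gold & !decisions$present_pred, , drop = FALSE]
  fn <- fn[order(fn$similarity, na.last = TRUE), , drop = FALSE]
  out <- rbind(
    if (nrow(bl)) {
      tibble::tibble(
        note_id = bl$note_id, feature_id = bl$feature_id,
        reason = "borderline", similarity = bl$similarity
      )
    },
    if (nrow(fn)) {
      tibble::tibble(
        note_id = fn$note_id, feature_id = fn$feature_id,
        reason = "missing", similarity = fn$similarity
      )
    }
  )
  if (is.null(out)) {
    out <- tibble::tibble(
      note_id = character(0), feature_id = character(0),
      reason = character(0), similarity = numeric(0)
    )
  }
  out
}

#' Feature-level chrF scores for calibration
#'
#' For each asserted extraction, the best chrF F1 against the gold
#' alternatives of its (note, feature) pair (0 when the feature is
#' gold-absent: a fully unsupported assertion). These continuous scores are
#' paired with pipeline confidences in [ece()]/[brier()].
#'
#' @param extractions Extraction tibble.
#' @param gold Gold annotation tibble.
#' @param n N-gram order.
#' @return Tibble: `note_id`, `feature_id`, `score` (asserted rows only).
#' @export
feature_chrf_scores <- function(extractions, gold, n = 3L) {
  keep <- nzchar(extractions$text)
  ext <- extractions[keep, , drop = FALSE]
  gold_key <- paste(gold$note_id, gold$feature_id, sep = "\r")
  gold_texts <- stats::setNames(gold$texts, gold_key)
  score <- vapply(seq_len(nrow(ext)), function(i) {
    gt <- gold_texts[[paste(ext$note_id[[i]], ext$feature_id[[i]], sep = "\r")]]
    if (is.null(gt) || length(gt) == 0L) {
      return(0)
    }
    max(vapply(gt, function(g) chrf_f1(ext$text[[i]], g, n), numeric(1)))
  }, numeric(1))
  tibble::tibble(note_id = ext$note_id, feature_id = ext$feature_id, score = score)
}
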