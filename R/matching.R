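#' Best gold phrasing score for a prediction
#'
#' A gold annotation can carry alternative phrasings; everywhere a
#' prediction is compared with gold, the best-scoring alternative is used.
#'
#' @param pred Predicted text.
#' @param gold_texts Character vector of alternative gold phrasings.
#' @param n N-gram order for [chrf_f1()].
#' @return Named list: `best_f1`, `best_index` (NA when `gold_texts` empty).
#' @keywords internal
best_gold_chrf <- function(pred, gold_texts, n = 3L) {
  if (length(gold_texts) == 0L) {
    return(list(best_f1 = 0, best_index = NA_integer_))
  }
  scores <- vapply(gold_texts, function(g) chrf_f1(pred, g, n), numeric(1))
  i <- which.max(scores)
  list(best_f1 = scores[[i]], best_index = i)
}

#' Bidirectional chrF matching between predictions and gold features
#'
#' `forward_match()` scores each non-empty predicted feature against every
#' gold feature text and keeps the maximum chrF F1 (hallucination side);
#' `backward_match()` mirrors it, scoring each gold-present feature against
#' every prediction (omission side). An empty partner set yields best F1 = 0
#' and no partner.
#'
#' @param predictions Tibble of extraction records (rows with empty `text`
#'   are dropped: the extractor reported the feature absent).
#' @param gold Gold annotation tibble for the same note (rows with no texts
#'   are dropped: the feature is absent from the note).
#' @param n N-gram order (default 3).
#' @return A tibble with one row per source feature: `source_id`, `best_f1`,
#'   `best_partner_id` (NA when no partner), `direction`.
#' @export
forward_match <- function(predictions, gold, n = 3L) {
  preds <- predictions[nzchar(predictions$text), , drop = FALSE]
  gold <- gold_present_rows(gold)
  if (nrow(preds) == 0L) {
    return(empty_match_tbl("forward"))
  }
  rows <- lapply(seq_len(nrow(preds)), function(i) {
    best <- list(best_f1 = 0, partner = NA_character_)
    for (j in seq_len(nrow(gold))) {
      b <- best_gold_chrf(preds$text[[i]], gold$texts[[j]], n)
      if (b$best_f1 > best$best_f1) {
        best <- list(best_f1 = b$best_f1, partner = gold$feature_id[[j]])
      }
    }
    tibble::tibble(
      source_id = preds$feature_id[[i]], best_f1 = best$best_f1,
      best_partner_id = best$partner, direction = "forward"
    )
  })
  do.call(rbind, rows)
}

#' @rdname forward_match
#' @export
backward_match <- function(gold, predictions, n = 3L) {
  gold <- gold_present_rows(gold)
  preds <- predictions[nzchar(predictions$text), , drop = FALSE]
  if (nrow(gold) == 0L) {
    return(empty_match_tbl("backward"))
  }
  rows <- lapply(seq_len(nrow(gold)), function(j) {
    best_f1 <- 0
    partner <- NA_character_
    for (i in seq_len(nrow(preds))) {
      b <- best_gold_chrf(preds$text[[i]], gold$texts[[j]], n)
      if (b$best_f1 > best_f1) {
        best_f1 <- b$best_f1
        partner <- preds$feature_id[[i]]
      }
    }
    tibble::tibble(
      source_id = gold$feature_id[[j]], best_f1 = best_f1,
      best_partner_id = partner, direction = "backward"
    )
  })
  do.call(rbind, rows)
}

gold_present_rows <- function(gold) {
  if (nrow(gold) == 0L) {
    return(gold)
  }
  keep <- vapply(gold$texts, function(t) length(t) > 0L, logical(1))
  gold[keep, , drop = FALSE]
}

empty_match_tbl <- function(direction) {
  tibble::tibble(
    source_id = character(0), best_f1 = numeric(0),
    best_partner_id = character(0), direction = character(0)
  )
}

#' Hallucination penalty base from a forward-match F1
#'
#' A predicted feature's penalty base measures how unsupported it is:
#' `1 - F1` in full when the best forward match is weak (`F1 <= 0.3`),
#' reduced to `0.7 * (1 - F1)` when the match is partial (`F1 > 0.3`,
#' strict). Perfect matches are unpenalized. The prescribed jump at 0.3 is
#' the only discontinuity.
#'
#' @param best_f1 Best forward-match chrF F1 in \[0, 1\] (vectorized).
#' @return Penalty base(s) in \[0, 1\].
#' @export
#' @examples
#' hallucination_base(0.8)  # 0.14
#' hallucination_base(0.3)  # 0.7 (boundary takes the full branch)
hallucination_base <- function(best_f1) {
  if (any(best_f1 < 0 | best_f1 > 1)) {
    stop("best_f1 must lie in [0, 1]", call. = FALSE)
  }
  ifelse(best_f1 > 0.3, 0.7 * (1 - best_f1), 1 - best_f1)
}

#' Missing-feature penalty from backward matches
#'
#' Gold features whose best backward-match F1 falls below `miss_threshold`
#' (default 0.5, strict) count as missing and contribute `1 - best_f1`.
#' Aggregation over the note's gold features is configurable:
#'
#' * `"mean_all"` (default) — mean contribution over *all* gold features, so
#'   the penalty scales with the fraction missed;
#' * `"mean_missing"` — mean over missing features only;
#' * `"sum"` — raw sum of contributions.
#'
#' Returns 0 when the note has no gold features (or none are missing under
#' `"mean_missing"`).
#'
#' @param backward Tibble from [backward_match()].
#' @param miss_threshold Strict threshold below which a gold feature counts
#'   as missing (default 0.5).
#' @param aggregation One of `"mean_all"`, `"mean_missing"`, `"sum"`.
#' @return A non-negative penalty.
#' @export
missing_penalty <- function(backward, miss_threshold = 0.5,
                            aggregation = c("mean_all", "mean_missing", "sum")) {
  aggregation <- match.arg(aggregation)
  if (nrow(backward) == 0L) {
    return(0)
  }
  contrib <- ifelse(backward$best_f1 < miss_threshold, 1 - backward$best_f1, 0)
  switch(aggregation,
    mean_all = mean(contrib),
    mean_missing = if (any(contrib > 0)) mean(contrib[contrib > 0]) else 0,
    sum = sum(contrib)
  )
}

#' Bidirectional match report for one note
#'
#' Runs [forward_match()] and [backward_match()] and derives the per-feature
#' hallucination penalty bases and missing-feature contributions.
#'
#' @inheritParams forward_match
#' @param note_id Identifier recorded on the report.
#' @param miss_threshold,aggregation Passed to [missing_penalty()].
#' @return A list of class `match_report`: `note_id`, `forward`, `backward`,
#'   `hallucination_bases`, `missing_contributions`.
#' @export
match_report <- function(note_id, predictions, gold, n = 3L,
                         miss_threshold = 0.5, aggregation = "mean_all") {
  fwd <- forward_match(predictions, gold, n)
  bwd <- backward_match(gold, predictions, n)
  structure(
    list(
      note_id = note_id,
      forward = fwd,
      backward = bwd,
      hallucination_bases = if (nrow(fwd)) hallucination_base(fwd$best_f1) else numeric(0),
      missing_contributions = if (nrow(bwd)) {
        ifelse(bwd$best_f1 < miss_threshold, 1 - bwd$best_f1, 0)
      } else {
        numeric(0)
      },
      missing_penalty = missing_penalty(bwd, miss_threshold, aggregation)
    ),
    class = "match_report"
  )
}
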