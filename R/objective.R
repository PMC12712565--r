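#' Penalty configuration for the confidence-regularized objective
#'
#' * `alpha_penalty` — scaling factor of the quadratic overconfidence term
#'   (default 2).
#' * `w_hallucination`, `w_missing` — loss weights of the hallucination and
#'   missing-feature penalties (defaults 0.2 and 0.5; the missing penalty is
#'   weighted higher to push recall).
#' * `miss_threshold` — backward-match F1 below which a gold feature counts
#'   as missing (0.5, strict).
#' * `hall_reduced_cut` — forward-match F1 above which the hallucination
#'   base takes the reduced branch (0.3, strict).
#' * `miss_aggregation` — see [missing_penalty()].
#' * `penalty_form` — how base, confidence and threshold compose in
#'   [overconfidence_penalty()]: `"proportional_quadratic"` (default,
#'   `base * (c + alpha * (c - tau)^2)`) or `"quadratic_only"`
#'   (`alpha * (c - tau)^2 * base`).
#'
#' @param alpha_penalty,w_hallucination,w_missing,miss_threshold,hall_reduced_cut,miss_aggregation,penalty_form See above.
#' @return A list of class `penalty_config`.
#' @export
penalty_config <- function(alpha_penalty = 2,
                           w_hallucination = 0.2,
                           w_missing = 0.5,
                           miss_threshold = 0.5,
                           hall_reduced_cut = 0.3,
                           miss_aggregation = "mean_all",
                           penalty_form = c("proportional_quadratic", "quadratic_only")) {
  stopifnot(
    alpha_penalty >= 0, w_hallucination >= 0, w_missing >= 0,
    miss_threshold >= 0, hall_reduced_cut >= 0
  )
  structure(
    list(
      alpha_penalty = alpha_penalty,
      w_hallucination = w_hallucination, w_missing = w_missing,
      miss_threshold = miss_threshold, hall_reduced_cut = hall_reduced_cut,
      miss_aggregation = miss_aggregation,
      penalty_form = match.arg(penalty_form)
    ),
    class = "penalty_config"
  )
}

#' Overconfidence penalty for one prediction
#'
#' Penalizes overconfident incorrect extractions only: the penalty is 0
#' whenever the confidence does not exceed the threshold tau, or the
#' penalty base is 0 (a perfect match). Above threshold the default form is
#' `base * (confidence + alpha_penalty * (confidence - tau)^2)` —
#' proportional to the confidence, with a quadratic term sharpening the
#' response to overconfidence (`alpha_penalty = 2` by default).
#'
#' The penalty is continuous in the confidence on `c > tau`, monotone
#' increasing in `c` for a fixed positive base, and monotone non-increasing
#' in tau.
#'
#' @param base Penalty base in \[0, 1\] (from [hallucination_base()] or a
#'   missing contribution).
#' @param confidence Prediction confidence in \[0, 1\].
#' @param tau Overconfidence threshold.
#' @param alpha_penalty Quadratic scaling factor (default 2).
#' @param penalty_form See [penalty_config()].
#' @return A non-negative penalty.
#' @export
#' @examples
#' overconfidence_penalty(0.8, 0.8, 0.6)  # 0.8 * (0.8 + 2 * 0.04) = 0.704
#' overconfidence_penalty(0.8, 0.5, 0.6)  # 0: not overconfident
overconfidence_penalty <- function(base, confidence, tau, alpha_penalty = 2,
                                   penalty_form = "proportional_quadratic") {
  stopifnot(
    all(base >= 0), all(confidence >= 0), all(confidence <= 1),
    alpha_penalty >= 0
  )
  quad <- alpha_penalty * (confidence - tau)^2
  pen <- switch(penalty_form,
    proportional_quadratic = base * (confidence + quad),
    quadratic_only = base * quad,
    stop("unknown penalty_form: ", penalty_form, call. = FALSE)
  )
  ifelse(confidence <= tau | base == 0, 0, pen)
}

#' Hallucination and missing penalties for one note
#'
#' Composes the confidence pipeline, bidirectional matching and the
#' overconfidence penalty for a single note:
#'
#' 1. each non-empty extraction gets a confidence via
#'    [feature_confidence()] (unless a `confidence` column is already set);
#' 2. forward matching yields per-prediction hallucination bases, each
#'    gated and scaled by [overconfidence_penalty()] at threshold `tau`,
#'    then averaged over the note's non-empty predictions;
#' 3. the missing penalty comes from backward matching via
#'    [missing_penalty()].
#'
#' Both penalties are 0 for empty inputs.
#'
#' @param extractions Extraction tibble for one note (`feature_id`, `text`,
#'   `token_probs`, optional `confidence`).
#' @param gold Gold annotation tibble for the same note.
#' @param tau Confidence threshold (from [dynamic_threshold()]).
#' @param cfg A [penalty_config()].
#' @param conf_cfg A [confidence_config()].
#' @param n N-gram order for matching.
#' @param training Passed to [feature_confidence()] (noise injection).
#' @return List: `hallucination_penalty`, `missing_penalty`, `report`
#'   (a [match_report()]), `confidences`, `penalized_feature_count`.
#' @export
note_penalties <- function(extractions, gold, tau, cfg = penalty_config(),
                           conf_cfg = confidence_config(), n = 3L,
                           training = FALSE) {
  report <- match_report(
    note_id = if (nrow(extractions)) extractions$note_id[[1]] else NA_character_,
    predictions = extractions, gold = gold, n = n,
    miss_threshold = cfg$miss_threshold, aggregation = cfg$miss_aggregation
  )
  nonempty <- extractions[nzchar(extractions$text), , drop = FALSE]
  if (nrow(nonempty) == 0L) {
    return(list(
      hallucination_penalty = 0,
      missing_penalty = report$missing_penalty,
      report = report, confidences = numeric(0), penalized_feature_count = 0L
    ))
  }
  confs <- vapply(seq_len(nrow(nonempty)), function(i) {
    if ("confidence" %in% names(nonempty) && !is.na(nonempty$confidence[[i]])) {
      nonempty$confidence[[i]]
    } else {
      feature_confidence(
        nonempty$token_probs[[i]],
        length(tokenize(nonempty$text[[i]])),
        conf_cfg, training = training
      )
    }
  }, numeric(1))
  pens <- overconfidence_penalty(
    report$hallucination_bases, confs, tau,
    cfg$alpha_penalty, cfg$penalty_form
  )
  list(
    hallucination_penalty = mean(pens),
    missing_penalty = report$missing_penalty,
    report = report,
    confidences = confs,
    penalized_feature_count = sum(pens > 0)
  )
}

#' Combine cross-entropy and penalties into the total loss
#'
#' `total = ce + w_hallucination * hall + w_missing * miss` (defaults
#' 0.2 and 0.5), an exact linear form. When both penalties are zero the
#' breakdown carries `penalty_gradient = FALSE`: a differentiable
#' implementation must skip the penalty term's backward pass entirely in
#' that case (no gradient is propagated for penalty-free steps).
#'
#' @param ce Cross-entropy (base language-modeling) loss, >= 0.
#' @param hall Hallucination penalty, >= 0.
#' @param miss Missing-feature penalty, >= 0.
#' @param cfg A [penalty_config()].
#' @param penalized_feature_count Number of features that incurred a
#'   positive overconfidence penalty.
#' @return A list of class `loss_breakdown`: `ce_loss`,
#'   `hallucination_penalty`, `missing_penalty`, `total`,
#'   `penalized_feature_count`, `penalty_gradient`.
#' @export
total_loss <- function(ce, hall, miss, cfg = penalty_config(),
                       penalized_feature_count = 0L) {
  if (ce < 0 || hall < 0 || miss < 0) {
    stop("loss components must be non-negative", call. = FALSE)
  }
  structure(
    list(
      ce_loss = ce,
      hallucination_penalty = hall,
      missing_penalty = miss,
      total = ce + cfg$w_hallucination * hall + cfg$w_missing * miss,
      penalized_feature_count = as.integer(penalized_feature_count),
      penalty_gradient = (hall > 0 || miss > 0)
    ),
    class = "loss_breakdown"
  )
}

#' Run one training epoch of the confidence-regularized objective
#'
#' Drives an abstract generator over a corpus for one epoch: for each note,
#' the generator is asked for one extraction per rubric feature of the
#' note's case, penalties are computed via [note_penalties()] at the
#' epoch's dynamic threshold, and a [total_loss()] breakdown is recorded.
#' The epoch's binary-overlap F1 on the training slice and the EMA-smoothed
#' mean confidence are fed back into the returned epoch state.
#'
#' The generator contract: `generator(note, features)` receives one row of
#' the notes table and the feature tibble of that note's case, and must
#' return a tibble with exactly one row per requested feature, columns
#' `feature_id`, `text` (empty = feature absent) and `token_probs`
#' (list-column). A violation aborts with an error naming the note.
#'
#' Deterministic given `seed` and a deterministic generator.
#'
#' @param generator A generator function (see Details).
#' @param corpus List with `notes`, `features`, `gold` tibbles.
#' @param state An [epoch_state()].
#' @param pen_cfg A [penalty_config()].
#' @param conf_cfg A [confidence_config()].
#' @param n N-gram order.
#' @param ce Per-note cross-entropy losses (single value recycled or vector
#'   of length `nrow(notes)`); the mock path has no language model, so the
#'   default is 0.
#' @param seed Seed applied before the epoch (noise injection and any
#'   generator randomness drawn from R's RNG stream).
#' @return List: `losses` (tibble, one row per note: ids, penalty
#'   components, total), `case_penalties` (tibble of per-case penalty
#'   means), `state` (updated [epoch_state()] for the next epoch),
#'   `epoch_f1`, `tau`.
#' @export
run_epoch <- function(generator, corpus, state, pen_cfg = penalty_config(),
                      conf_cfg = confidence_config(), n = 3L, ce = 0,
                      seed = conf_cfg$seed) {
  stopifnot(nrow(corpus$notes) > 0L)
  set.seed(seed)
  tau <- dynamic_threshold(state, conf_cfg)
  ce <- rep_len(ce, nrow(corpus$notes))

  loss_rows <- vector("list", nrow(corpus$notes))
  all_extractions <- vector("list", nrow(corpus$notes))
  all_confs <- numeric(0)
  for (i in seq_len(nrow(corpus$notes))) {
    note <- corpus$notes[i, ]
    feats <- corpus$features[corpus$features$case_id == note$case_id, , drop = FALSE]
    ext <- generator(note, feats)
    if (!is.data.frame(ext) || nrow(ext) != nrow(feats) ||
      !setequal(ext$feature_id, feats$feature_id)) {
      stop("generator contract violation on note '", note$note_id,
        "': expected exactly one record per requested feature",
        call. = FALSE
      )
    }
    ext$note_id <- note$note_id
    gold_i <- corpus$gold[corpus$gold$note_id == note$note_id, , drop = FALSE]
    np <- note_penalties(ext, gold_i, tau, pen_cfg, conf_cfg,
      n = n, training = conf_cfg$beta_noise > 0
    )
    lb <- total_loss(ce[[i]], np$hallucination_penalty, np$missing_penalty,
      pen_cfg,
      penalized_feature_count = np$penalized_feature_count
    )
    loss_rows[[i]] <- tibble::tibble(
      note_id = note$note_id, case_id = note$case_id,
      ce_loss = lb$ce_loss,
      hallucination_penalty = lb$hallucination_penalty,
      missing_penalty = lb$missing_penalty,
      total = lb$total,
      penalized_feature_count = lb$penalized_feature_count,
      penalty_gradient = lb$penalty_gradient
    )
    all_extractions[[i]] <- ext
    all_confs <- c(all_confs, np$confidences)
  }
  losses <- do.call(rbind, loss_rows)
  extractions <- do.call(rbind, all_extractions)

  # epoch-level feedback: binary-overlap F1 on the training slice
  decisions <- presence_decisions(extractions, corpus, mode = "binary_overlap")
  f1 <- prf(decisions)$f1
  mean_conf <- if (length(all_confs)) mean(all_confs) else NA_real_
  smoothed <- if (is.na(mean_conf)) {
    state$smoothed_confidence
  } else {
    ema_feedback(state$smoothed_confidence, mean_conf, conf_cfg$alpha_feedback)
  }
  next_state <- epoch_state(
    epoch_index = min(state$epoch_index + 1L, state$total_epochs - 1L),
    total_epochs = state$total_epochs,
    prev_f1 = f1, smoothed_confidence = smoothed
  )

  case_penalties <- stats::aggregate(
    losses[, c("hallucination_penalty", "missing_penalty")],
    by = list(case_id = losses$case_id), FUN = mean
  )
  list(
    losses = losses,
    case_penalties = tibble::as_tibble(case_penalties),
    state = next_state, epoch_f1 = f1, tau = tau
  )
}
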