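#' Built-in symptom phrase bank
#'
#' Forty symptom/history concepts, each with a rubric-style description, a
#' canonical mention, paraphrase variants and a negated surface variant
#' (rubrics routinely credit documented pertinent negatives, so a negated
#' mention still counts as the feature being documented). English only, by
#' construction; no external lexicon.
#'
#' @return A list of entries: `description`, `canonical`, `paraphrases`,
#'   `negated`.
#' @export
phrase_bank <- function() {
  e <- function(description, canonical, paraphrases, negated) {
    list(
      description = description, canonical = canonical,
      paraphrases = paraphrases, negated = negated
    )
  }
  list(
    e("chest pain", "chest pain", c("pain in the chest", "chest discomfort"), "denies chest pain"),
    e("shortness of breath", "shortness of breath", c("difficulty breathing", "short of breath"), "denies shortness of breath"),
    e("fever", "fever", c("febrile episodes", "elevated temperature"), "no fever reported"),
    e("chills", "chills", c("shaking chills"), "denies chills"),
    e("productive cough", "productive cough", c("cough with sputum"), "no productive cough"),
    e("dry cough", "dry cough", c("nonproductive cough"), "denies dry cough"),
    e("nausea", "nausea", c("feeling nauseated"), "denies nausea"),
    e("vomiting", "vomiting", c("emesis", "throwing up"), "no vomiting"),
    e("diarrhea", "diarrhea", c("loose stools"), "denies diarrhea"),
    e("constipation", "constipation", c("hard infrequent stools"), "no constipation"),
    e("abdominal pain", "abdominal pain", c("pain in the abdomen", "stomach pain"), "denies abdominal pain"),
    e("headache", "headache", c("head pain", "throbbing headache"), "denies headache"),
    e("dizziness", "dizziness", c("feeling lightheaded"), "no dizziness"),
    e("palpitations", "palpitations", c("racing heartbeat"), "denies palpitations"),
    e("fatigue", "fatigue", c("feeling tired", "low energy"), "no fatigue"),
    e("weight loss", "weight loss", c("unintentional weight loss"), "no weight loss"),
    e("night sweats", "night sweats", c("sweating at night"), "denies night sweats"),
    e("back pain", "back pain", c("pain in the lower back"), "denies back pain"),
    e("joint pain", "joint pain", c("aching joints"), "no joint pain"),
    e("muscle aches", "muscle aches", c("myalgias", "sore muscles"), "denies muscle aches"),
    e("sore throat", "sore throat", c("throat pain"), "denies sore throat"),
    e("runny nose", "runny nose", c("nasal discharge"), "no runny nose"),
    e("ear pain", "ear pain", c("pain in the ear"), "denies ear pain"),
    e("blurred vision", "blurred vision", c("blurry vision"), "denies blurred vision"),
    e("photophobia", "photophobia", c("light sensitivity"), "no photophobia"),
    e("neck stiffness", "neck stiffness", c("stiff neck"), "denies neck stiffness"),
    e("rash", "rash", c("skin eruption"), "no rash"),
    e("itching", "itching", c("pruritus"), "denies itching"),
    e("leg swelling", "leg swelling", c("swelling in the legs", "leg edema"), "no leg swelling"),
    e("numbness", "numbness", c("loss of sensation"), "denies numbness"),
    e("tingling", "tingling", c("pins and needles"), "no tingling"),
    e("urinary frequency", "urinary frequency", c("frequent urination"), "denies urinary frequency"),
    e("burning with urination", "burning with urination", c("painful urination", "dysuria"), "no burning with urination"),
    e("blood in stool", "blood in stool", c("bloody stools"), "denies blood in stool"),
    e("blood in urine", "blood in urine", c("bloody urine"), "no blood in urine"),
    e("loss of appetite", "loss of appetite", c("poor appetite"), "denies loss of appetite"),
    e("difficulty swallowing", "difficulty swallowing", c("trouble swallowing"), "no difficulty swallowing"),
    e("heartburn", "heartburn", c("burning after meals"), "denies heartburn"),
    e("anxiety", "anxiety", c("feeling anxious"), "no anxiety"),
    e("trouble sleeping", "trouble sleeping", c("insomnia", "difficulty sleeping"), "denies trouble sleeping")
  )
}

#' Synthetic-corpus configuration
#'
#' Defaults emulate the rubric-scored patient-note setting at desk scale:
#' 10 clinical cases, 10 notes per case, 14 rubric features per case (the
#' per-note rubric size typical of the task), features documented in 70% of
#' notes, with realistic surface variation (30% paraphrases, 10% single-edit
#' typos, 15% negated variants).
#'
#' @param n_cases,notes_per_case,features_per_case Corpus shape.
#' @param p_feature_present Probability a case feature is documented in a
#'   note.
#' @param p_paraphrase,p_typo,p_negation_variant Surface-variation
#'   probabilities for an inserted mention.
#' @param mock A [mock_profile()] for the companion extractor.
#' @param seed RNG seed; identical configs generate byte-identical corpora.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_cases = 10L, notes_per_case = 10L,
                         features_per_case = 14L,
                         p_feature_present = 0.7,
                         p_paraphrase = 0.3, p_typo = 0.1,
                         p_negation_variant = 0.15,
                         mock = mock_profile(), seed = 20260101L) {
  probs <- c(p_feature_present, p_paraphrase, p_typo, p_negation_variant)
  stopifnot(
    all(probs >= 0 & probs <= 1),
    n_cases >= 1L, notes_per_case >= 1L, features_per_case >= 1L
  )
  structure(
    list(
      n_cases = as.integer(n_cases),
      notes_per_case = as.integer(notes_per_case),
      features_per_case = as.integer(features_per_case),
      p_feature_present = p_feature_present,
      p_paraphrase = p_paraphrase, p_typo = p_typo,
      p_negation_variant = p_negation_variant,
      mock = mock, seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

#' Mock-extractor error profile
#'
#' Controls the statistical behavior of the mock extractor standing in for
#' a generative model:
#'
#' * `hallucination_rate` — probability of fabricating a mention for a
#'   gold-absent feature (default 0.1);
#' * `miss_rate` — probability of returning nothing for a gold-present
#'   feature (default 0.2);
#' * `paraphrase_noise` — probability of perturbing an emitted true mention
#'   (paraphrase or single-edit typo);
#' * `conf_correct`, `conf_incorrect` — Beta(shape1, shape2) parameters of
#'   the confidence distributions for true vs fabricated extractions
#'   (defaults Beta(10.5, 2), mean 0.84, and Beta(5, 2), mean 0.71: the
#'   mock is systematically more confident when right, so the
#'   overconfidence penalty has signal to find);
#' * `epoch_decay` — both error rates are scaled by `epoch_decay^epoch`,
#'   emulating an extractor improving over training epochs.
#'
#' @param hallucination_rate,miss_rate,paraphrase_noise,conf_correct,conf_incorrect,epoch_decay See above.
#' @return A list of class `mock_profile`.
#' @export
mock_profile <- function(hallucination_rate = 0.1, miss_rate = 0.2,
                         paraphrase_noise = 0.1,
                         conf_correct = c(10.5, 2),
                         conf_incorrect = c(5, 2),
                         epoch_decay = 0.5) {
  stopifnot(
    hallucination_rate >= 0, hallucination_rate <= 1,
    miss_rate >= 0, miss_rate <= 1,
    paraphrase_noise >= 0, paraphrase_noise <= 1,
    all(conf_correct > 0), all(conf_incorrect > 0),
    epoch_decay >= 0, epoch_decay <= 1
  )
  structure(
    list(
      hallucination_rate = hallucination_rate, miss_rate = miss_rate,
      paraphrase_noise = paraphrase_noise,
      conf_correct = conf_correct, conf_incorrect = conf_incorrect,
      epoch_decay = epoch_decay
    ),
    class = "mock_profile"
  )
}

single_edit_typo <- function(text) {
  chars <- strsplit(text, "")[[1L]]
  letters_at <- which(grepl("[a-z]", chars))
  if (length(letters_at) == 0L) {
    return(text)
  }
  i <- if (length(letters_at) == 1L) letters_at else sample(letters_at, 1L)
  op <- sample(c("sub", "del", "dup"), 1L)
  out <- switch(op,
    sub = {
      repl <- sample(setdiff(letters, chars[[i]]), 1L)
      chars[[i]] <- repl
      chars
    },
    del = chars[-i],
    dup = append(chars, chars[[i]], after = i)
  )
  paste(out, collapse = "")
}

mention_templates <- c(
  "patient reports %s.",
  "reports %s starting last week.",
  "notes %s over the past few days.",
  "history significant for %s.",
  "endorses %s today."
)

filler_sentences <- c(
  "vitals reviewed and stable.",
  "medications reconciled at intake.",
  "social history reviewed.",
  "family history noncontributory.",
  "follow up arranged with primary care."
)

#' Generate a seeded synthetic corpus
#'
#' Assembles templated clinical notes from the built-in [phrase_bank()].
#' Each case samples `features_per_case` distinct concepts as its rubric;
#' each note documents each case feature with probability
#' `p_feature_present`, choosing a canonical, paraphrased, negated and/or
#' typo'd surface form, and records the gold span as the exact character
#' offsets of the inserted mention (0-based, half-open). Absent features get
#' explicit empty gold rows. Fully reproducible: the same config yields a
#' byte-identical corpus.
#'
#' @param cfg A [synth_config()].
#' @return List: `notes`, `features` (with generator column `bank_id`),
#'   `gold` — see [corpus-tables].
#' @export
generate_corpus <- function(cfg = synth_config()) {
  bank <- phrase_bank()
  if (cfg$features_per_case > length(bank)) {
    stop("features_per_case exceeds the phrase bank size (",
      length(bank), ")",
      call. = FALSE
    )
  }
  set.seed(cfg$seed)

  feature_rows <- list()
  note_rows <- list()
  gold_rows <- list()
  note_counter <- 0L

  for (ci in seq_len(cfg$n_cases)) {
    case_id <- sprintf("case%02d", ci)
    bank_ids <- sample(length(bank), cfg$features_per_case)
    fids <- sprintf("%s_f%02d", case_id, seq_along(bank_ids))
    feature_rows[[ci]] <- tibble::tibble(
      feature_id = fids, case_id = case_id,
      description = vapply(bank[bank_ids], `[[`, character(1), "description"),
      bank_id = bank_ids
    )
    for (ni in seq_len(cfg$notes_per_case)) {
      note_counter <- note_counter + 1L
      note_id <- sprintf("note%04d", note_counter)
      sentences <- "presents for evaluation."
      mention_pos <- list() # fid -> c(start, end) filled as text grows
      text <- sentences
      for (j in seq_along(bank_ids)) {
        entry <- bank[[bank_ids[[j]]]]
        present <- stats::runif(1) < cfg$p_feature_present
        if (!present) {
          gold_rows[[length(gold_rows) + 1L]] <- tibble::tibble(
            note_id = note_id, feature_id = fids[[j]],
            texts = list(character(0)), spans = list(list())
          )
          next
        }
        negated <- stats::runif(1) < cfg$p_negation_variant
        mention <- if (negated) {
          entry$negated
        } else if (stats::runif(1) < cfg$p_paraphrase) {
          sample(entry$paraphrases, 1L)
        } else {
          entry$canonical
        }
        if (stats::runif(1) < cfg$p_typo) {
          mention <- single_edit_typo(mention)
        }
        sentence <- if (negated) {
          sprintf("%s.", mention)
        } else {
          sprintf(sample(mention_templates, 1L), mention)
        }
        prefix <- regexpr(mention, sentence, fixed = TRUE)[[1L]] - 1L
        start <- nchar(text) + 1L + prefix # +1 for the joining space
        text <- paste(text, sentence)
        gold_rows[[length(gold_rows) + 1L]] <- tibble::tibble(
          note_id = note_id, feature_id = fids[[j]],
          texts = list(mention),
          spans = list(list(matrix(c(start, start + nchar(mention)),
            ncol = 2L, dimnames = list(NULL, c("start", "end"))
          )))
        )
        if (stats::runif(1) < 0.3) {
          text <- paste(text, sample(filler_sentences, 1L))
        }
      }
      note_rows[[note_counter]] <- tibble::tibble(
        note_id = note_id, case_id = case_id, text = text
      )
    }
  }
  list(
    notes = do.call(rbind, note_rows),
    features = do.call(rbind, feature_rows),
    gold = do.call(rbind, gold_rows)
  )
}

draw_token_probs <- function(confidence, n_tokens) {
  n_tokens <- max(1L, n_tokens)
  if (confidence >= 1) {
    return(rep(1, n_tokens))
  }
  # exponents are positive and average to 1, so the geometric mean is exactly c
  w <- stats::runif(n_tokens, 0.5, 1.5)
  confidence^(w * n_tokens / sum(w))
}

#' Mock extractor over a synthetic corpus
#'
#' Emulates a generative extractor with controlled error structure. For
#' each (note, case-feature) pair:
#'
#' * gold-present: the gold mention is emitted unless missed (probability
#'   `miss_rate * epoch_decay^epoch`); an emitted mention is perturbed with
#'   probability `paraphrase_noise` (paraphrase or single-edit typo);
#' * gold-absent: a phrase verifiably not present in the note is fabricated
#'   with probability `hallucination_rate * epoch_decay^epoch`.
#'
#' Token probabilities are drawn so that their geometric mean equals a
#' confidence sampled from `Beta(conf_correct)` for true extractions and
#' `Beta(conf_incorrect)` for fabricated ones. Every pair yields a record;
#' empty text means "feature reported absent".
#'
#' @param corpus Corpus from [generate_corpus()] (features must carry
#'   `bank_id`).
#' @param profile A [mock_profile()].
#' @param epoch 0-based epoch index scaling the error rates.
#' @param seed RNG seed.
#' @return Extraction tibble: `note_id`, `feature_id`, `text`,
#'   `token_probs`, `confidence` (`NA`; computed downstream), `truthful`
#'   (generator-side flag: the emission reflects the note).
#' @export
mock_extract <- function(corpus, profile = mock_profile(), epoch = 0L,
                         seed = 20260102L) {
  stopifnot("bank_id" %in% names(corpus$features))
  set.seed(as.integer(seed %% .Machine$integer.max))
  bank <- phrase_bank()
  decay <- profile$epoch_decay^epoch
  gold_key <- paste(corpus$gold$note_id, corpus$gold$feature_id, sep = "\r")
  gold_texts <- stats::setNames(corpus$gold$texts, gold_key)

  rows <- vector("list", 0L)
  for (i in seq_len(nrow(corpus$notes))) {
    note <- corpus$notes[i, ]
    feats <- corpus$features[corpus$features$case_id == note$case_id, , drop = FALSE]
    note_norm <- normalize_text(note$text)
    for (j in seq_len(nrow(feats))) {
      gt <- gold_texts[[paste(note$note_id, feats$feature_id[[j]], sep = "\r")]]
      present <- !is.null(gt) && length(gt) > 0L
      text <- ""
      truthful <- TRUE
      if (present) {
        if (stats::runif(1) >= profile$miss_rate * decay) {
          text <- gt[[1L]]
          if (stats::runif(1) < profile$paraphrase_noise) {
            entry <- bank[[feats$bank_id[[j]]]]
            text <- if (stats::runif(1) < 0.5) {
              sample(entry$paraphrases, 1L)
            } else {
              single_edit_typo(text)
            }
          }
        } else {
          truthful <- FALSE # missed a documented feature
        }
      } else if (stats::runif(1) < profile$hallucination_rate * decay) {
        text <- fabricate_phrase(bank, feats$bank_id, note_norm)
        truthful <- FALSE
      }
      conf <- if (truthful && nzchar(text)) {
        stats::rbeta(1, profile$conf_correct[1], profile$conf_correct[2])
      } else if (nzchar(text)) {
        stats::rbeta(1, profile$conf_incorrect[1], profile$conf_incorrect[2])
      } else {
        NA_real_
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        note_id = note$note_id, feature_id = feats$feature_id[[j]],
        text = text,
        token_probs = list(if (nzchar(text)) {
          draw_token_probs(conf, length(tokenize(text)))
        } else {
          numeric(0)
        }),
        confidence = NA_real_,
        truthful = truthful
      )
    }
  }
  do.call(rbind, rows)
}

fabricate_phrase <- function(bank, case_bank_ids, note_norm) {
  candidates <- setdiff(seq_along(bank), case_bank_ids)
  for (k in sample(candidates)) {
    phrase <- bank[[k]]$canonical
    if (!grepl(phrase, note_norm, fixed = TRUE)) {
      return(phrase)
    }
  }
  "bilateral ear clicking" # nonsense fallback; never in any template
}

#' Extraction series over training epochs
#'
#' Runs the mock extractor once per epoch with error rates scaled by
#' `epoch_decay^epoch`, emulating an extractor improving over training —
#' the input for penalty-trend and epoch-wise reliability reports.
#' Deterministic per seed.
#'
#' @param corpus Corpus from [generate_corpus()].
#' @param profile A [mock_profile()] (use `epoch_decay < 1` for a
#'   decreasing-error series).
#' @param n_epochs Number of epochs.
#' @param seed Base seed; epoch `e` uses `seed + e`.
#' @return A list of extraction tibbles, one per epoch.
#' @export
epoch_series <- function(corpus, profile = mock_profile(), n_epochs = 5L,
                         seed = 20260103L) {
  lapply(seq_len(n_epochs) - 1L, function(e) {
    mock_extract(corpus, profile, epoch = e, seed = seed + e)
  })
}

#' Wrap a mock profile as a generator for [run_epoch()]
#'
#' Adapts [mock_extract()]'s sampling to the one-note generator contract.
#' Randomness is drawn from the ambient RNG stream (seeded by
#' [run_epoch()]).
#'
#' @param corpus Corpus from [generate_corpus()].
#' @param profile A [mock_profile()].
#' @param epoch 0-based epoch index.
#' @return A function `(note, features) -> extraction tibble`.
#' @export
mock_generator <- function(corpus, profile = mock_profile(), epoch = 0L) {
  bank <- phrase_bank()
  decay <- profile$epoch_decay^epoch
  gold_key <- paste(corpus$gold$note_id, corpus$gold$feature_id, sep = "\r")
  gold_texts <- stats::setNames(corpus$gold$texts, gold_key)
  function(note, features) {
    note_norm <- normalize_text(note$text)
    rows <- lapply(seq_len(nrow(features)), function(j) {
      gt <- gold_texts[[paste(note$note_id, features$feature_id[[j]], sep = "\r")]]
      present <- !is.null(gt) && length(gt) > 0L
      text <- ""
      truthful <- TRUE
      if (present) {
        if (stats::runif(1) >= profile$miss_rate * decay) {
          text <- gt[[1L]]
        } else {
          truthful <- FALSE
        }
      } else if (stats::runif(1) < profile$hallucination_rate * decay) {
        text <- fabricate_phrase(bank, features$bank_id, note_norm)
        truthful <- FALSE
      }
      conf <- if (nzchar(text)) {
        p <- if (truthful) profile$conf_correct else profile$conf_incorrect
        stats::rbeta(1, p[1], p[2])
      } else {
        NA_real_
      }
      tibble::tibble(
        feature_id = features$feature_id[[j]], text = text,
        token_probs = list(if (nzchar(text)) {
          draw_token_probs(conf, length(tokenize(text)))
        } else {
          numeric(0)
        })
      )
    })
    do.call(rbind, rows)
  }
}
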