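#' Corpus tables: notes, features, gold annotations, extractions
#'
#' The package represents a corpus as three tibbles plus an extraction
#' table, mirroring the rubric-scored patient-note layout:
#'
#' * **notes** — `note_id`, `case_id`, `text`: one free-text patient note per
#'   row, linked to a clinical case.
#' * **features** — `feature_id`, `case_id`, `description`: one rubric
#'   feature per row; notes of a case are searched for that case's features.
#' * **gold** — `note_id`, `feature_id`, `texts` (list of character vectors:
#'   alternative gold phrasings), `spans` (list of integer matrices with
#'   columns `start`,`end`): expert annotations. Offsets are 0-based,
#'   half-open character intervals into the note text; a feature absent from
#'   a note is an explicit row with zero spans/texts.
#' * **extractions** — `note_id`, `feature_id`, `text` (empty string means
#'   the extractor reports the feature absent), `token_probs` (list of
#'   numeric vectors in (0,1\]), optional `confidence`.
#'
#' Multiple alternative gold phrasings for one feature are all retained;
#' scoring functions use the best-scoring alternative.
#'
#' @name corpus-tables
NULL

new_gold_annotation <- function(note_id, feature_id, texts, spans) {
  tibble::tibble(
    note_id = note_id, feature_id = feature_id,
    texts = list(texts), spans = list(spans)
  )
}

empty_span_matrix <- function() {
  matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end")))
}

#' Parse a location string into a span matrix
#'
#' Locations use the syntax `"start end"` with discontinuous segments joined
#' by `";"`, e.g. `"0 4;8 13"`. Offsets are 0-based, half-open.
#'
#' @param location A single location string (may be empty: no spans).
#' @return Integer matrix with columns `start`, `end`.
#' @export
parse_location <- function(location) {
  if (is.na(location) || !nzchar(trimws(location))) {
    return(empty_span_matrix())
  }
  parts <- strsplit(trimws(location), ";", fixed = TRUE)[[1L]]
  rows <- lapply(parts, function(p) {
    nums <- suppressWarnings(as.integer(strsplit(trimws(p), "[[:space:]]+")[[1L]]))
    if (length(nums) != 2L || anyNA(nums)) {
      stop("malformed location segment: '", p, "'", call. = FALSE)
    }
    if (nums[1L] > nums[2L] || nums[1L] < 0L) {
      stop("invalid interval (start > end or negative): '", p, "'", call. = FALSE)
    }
    nums
  })
  m <- do.call(rbind, rows)
  colnames(m) <- c("start", "end")
  m
}

#' Format a span matrix as a location string
#' @param spans Integer matrix with columns `start`, `end`.
#' @return A single string, `"start end[;start end]"`; empty string for no spans.
#' @export
format_location <- function(spans) {
  if (is.null(spans) || nrow(spans) == 0L) {
    return("")
  }
  paste(apply(spans, 1L, function(r) paste(r[1L], r[2L])), collapse = ";")
}

#' Slice note text by 0-based half-open spans
#' @param text Note text.
#' @param spans Integer span matrix.
#' @return Character vector, one segment per span row.
#' @export
slice_spans <- function(text, spans) {
  if (nrow(spans) == 0L) {
    return(character(0))
  }
  substring(text, spans[, "start"] + 1L, spans[, "end"])
}

#' Read a corpus from three CSV files
#'
#' Expects the schemas documented in [corpus-tables]: `notes.csv`
#' (`note_id,case_id,text`), `features.csv` (`feature_id,case_id,description`)
#' and `annotations.csv` (`note_id,feature_id,texts,locations` where `texts`
#' is a JSON list of strings and `locations` a JSON list of
#' `"start end[;start end]"` strings, one per alternative annotation).
#'
#' Every parsed annotation is validated against its note: each span must lie
#' within the note and reconstruct the stored text up to normalization. Rows
#' failing validation are skipped with a warning reporting the count.
#'
#' @param notes_path,features_path,annotations_path CSV file paths.
#' @return A list with elements `notes`, `features`, `gold` (tibbles).
#' @export
read_corpus_csv <- function(notes_path, features_path, annotations_path) {
  notes <- read_checked_csv(notes_path, c("note_id", "case_id", "text"))
  features <- read_checked_csv(features_path, c("feature_id", "case_id", "description"))
  ann <- read_checked_csv(annotations_path, c("note_id", "feature_id", "texts", "locations"))

  note_text <- stats::setNames(notes$text, notes$note_id)
  skipped <- 0L
  rows <- vector("list", nrow(ann))
  for (i in seq_len(nrow(ann))) {
    rec <- try(parse_annotation_row(ann[i, ], note_text), silent = TRUE)
    if (inherits(rec, "try-error")) {
      skipped <- skipped + 1L
    } else {
      rows[[i]] <- rec
    }
  }
  if (skipped > 0L) {
    warning(skipped, " annotation row(s) failed validation and were skipped",
      call. = FALSE
    )
  }
  gold <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(gold)) {
    gold <- tibble::tibble(
      note_id = character(0), feature_id = character(0),
      texts = list(), spans = list()
    )
  }
  list(notes = tibble::as_tibble(notes), features = tibble::as_tibble(features), gold = gold)
}

read_checked_csv <- function(path, required) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(
      "file '", path, "' is missing required column(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  df
}

parse_annotation_row <- function(row, note_text) {
  texts <- jsonlite::fromJSON(row$texts, simplifyVector = TRUE)
  if (length(texts) == 0L) texts <- character(0)
  locs <- jsonlite::fromJSON(row$locations, simplifyVector = TRUE)
  if (length(locs) == 0L) locs <- character(0)
  if (length(texts) != length(locs)) {
    stop("texts/locations length mismatch for note ", row$note_id)
  }
  if (!row$note_id %in% names(note_text)) {
    stop("annotation references unknown note ", row$note_id)
  }
  txt <- note_text[[row$note_id]]
  spans <- lapply(locs, parse_location)
  for (k in seq_along(spans)) {
    validate_annotation_span(spans[[k]], texts[[k]], txt)
  }
  # store one span matrix per alternative phrasing
  tibble::tibble(
    note_id = row$note_id, feature_id = row$feature_id,
    texts = list(as.character(texts)), spans = list(spans)
  )
}

validate_annotation_span <- function(spans, text, note_text) {
  if (nrow(spans) == 0L) {
    return(invisible(TRUE))
  }
  if (any(spans[, "end"] > nchar(note_text))) {
    stop("span exceeds note length")
  }
  got <- paste(slice_spans(note_text, spans), collapse = " ")
  if (!identical(normalize_text(got), normalize_text(text))) {
    stop("span does not reconstruct annotated text")
  }
  invisible(TRUE)
}

#' Write a corpus to three CSV files
#' @param corpus List with `notes`, `features`, `gold` as from
#'   [read_corpus_csv()] or [generate_corpus()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_corpus_csv <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  np <- file.path(dir, "notes.csv")
  fp <- file.path(dir, "features.csv")
  ap <- file.path(dir, "annotations.csv")
  utils::write.csv(corpus$notes, np, row.names = FALSE)
  utils::write.csv(corpus$features, fp, row.names = FALSE)
  g <- corpus$gold
  ann <- data.frame(
    note_id = g$note_id,
    feature_id = g$feature_id,
    texts = vapply(g$texts, function(t) {
      as.character(jsonlite::toJSON(as.character(t)))
    }, character(1)),
    locations = vapply(g$spans, function(sp) {
      as.character(jsonlite::toJSON(vapply(sp, format_location, character(1))))
    }, character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(ann, ap, row.names = FALSE)
  invisible(c(notes = np, features = fp, annotations = ap))
}

#' Read and write extraction records as JSONL
#'
#' One JSON object per line with keys `note_id`, `feature_id`, `text`,
#' `token_probs`, and optionally `confidence`. Writing then reading
#' reproduces the records exactly. Token probabilities must lie in (0, 1\];
#' a value of 0 (or less) is rejected as a contract violation.
#'
#' @param path JSONL file path.
#' @return `read_extractions_jsonl()`: a tibble of extraction records.
#' @export
read_extractions_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(tibble::tibble(
      note_id = character(0), feature_id = character(0), text = character(0),
      token_probs = list(), confidence = numeric(0)
    ))
  }
  recs <- lapply(seq_along(lines), function(i) {
    obj <- try(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE), silent = TRUE)
    if (inherits(obj, "try-error")) {
      stop("malformed JSON on line ", i, " of '", path, "'", call. = FALSE)
    }
    tp <- as.numeric(obj$token_probs)
    if (any(tp <= 0) || any(tp > 1)) {
      stop("line ", i, ": token_probs must lie in (0, 1]", call. = FALSE)
    }
    tibble::tibble(
      note_id = as.character(obj$note_id),
      feature_id = as.character(obj$feature_id),
      text = as.character(obj$text),
      token_probs = list(tp),
      confidence = if (is.null(obj$confidence)) NA_real_ else as.numeric(obj$confidence)
    )
  })
  do.call(rbind, recs)
}

#' @rdname read_extractions_jsonl
#' @param records Tibble of extraction records (as read, or from
#'   [mock_extract()]).
#' @export
write_extractions_jsonl <- function(records, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    obj <- list(
      note_id = records$note_id[[i]],
      feature_id = records$feature_id[[i]],
      text = records$text[[i]],
      token_probs = as.numeric(records$token_probs[[i]])
    )
    if ("confidence" %in% names(records) && !is.na(records$confidence[[i]])) {
      obj$confidence <- records$confidence[[i]]
    }
    writeLines(as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)), con)
  }
  invisible(path)
}
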