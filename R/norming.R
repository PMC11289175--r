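#' Load a pronunciation lexicon
#'
#' Reads a UTF-8 tab-separated file with columns `word` and `ipa` mapping
#' orthographic words to IPA transcriptions. Lookup is case-insensitive:
#' words are folded to lowercase and IPA strings NFC-normalized. The lexicon
#' stands in for an external grapheme-to-phoneme transcriber; the bundled
#' `english_lexicon.tsv` covers the words used in examples and tests.
#'
#' @param path Path to the TSV file.
#' @return A [tibble::tibble] with columns `word` (lowercase) and `ipa`.
#' @examples
#' lex <- load_lexicon(system.file("extdata", "english_lexicon.tsv",
#'                                 package = "mafi"))
#' @export
load_lexicon <- function(path) {
  df <- utils::read.delim(path, fileEncoding = "UTF-8",
                          colClasses = "character")
  if (!all(c("word", "ipa") %in% names(df))) {
    stop("lexicon must have columns `word` and `ipa`", call. = FALSE)
  }
  out <- tibble::tibble(word = tolower(trimws(df$word)),
                        ipa = nfc(trimws(df$ipa)))
  dup <- out$word[duplicated(out$word)]
  if (length(dup) > 0L) {
    warning("duplicate lexicon entries, keeping first: ",
            paste(unique(dup), collapse = ", "), call. = FALSE)
    out <- out[!duplicated(out$word), ]
  }
  out
}

#' Load raw speechreading responses
#'
#' Reads a delimited table (comma or tab, auto-detected from the header
#' line) with one row per typed speechreading guess. Required columns:
#' `participant`, `target`, `response`; optional `study` labels the
#' collection round the row came from. Words are whitespace-trimmed and
#' folded to lowercase. Empty or NA response cells are kept as missing
#' (`NA`), to be dropped by [clean_responses()].
#'
#' @param path Path to the response file.
#' @return A [tibble::tibble] with columns `participant`, `target`,
#'   `response`, `study` (NA when absent from the file).
#' @export
load_responses <- function(path) {
  header <- readLines(path, n = 1L, encoding = "UTF-8")
  sep <- if (lengths(gregexpr("\t", header, fixed = TRUE)) >=
             lengths(gregexpr(",", header, fixed = TRUE))) "\t" else ","
  df <- utils::read.delim(path, sep = sep, fileEncoding = "UTF-8",
                          colClasses = "character")
  need <- c("participant", "target", "response")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("response file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"study" %in% names(df)) df$study <- NA_character_
  out <- tibble::tibble(
    participant = trimws(df$participant),
    target = tolower(trimws(df$target)),
    response = tolower(trimws(df$response)),
    study = trimws(df$study))
  out$response[!nzchar(out$response) | is.na(out$response)] <- NA_character_
  if (any(!nzchar(out$target) | is.na(out$target))) {
    stop("response file has empty target cells", call. = FALSE)
  }
  key <- paste(out$participant, out$target, out$study, sep = "\r")
  if (anyDuplicated(key)) {
    warning("duplicate (participant, target) rows; keeping first occurrence",
            call. = FALSE)
    out <- out[!duplicated(key), ]
  }
  out
}

#' Drop missing responses
#'
#' Removes rows whose response is missing (participants who typed nothing)
#' and reports the removed fraction. Typos are never auto-corrected; if a
#' hand-edited response column is wanted, edit the file before loading.
#'
#' @param records Response tibble from [load_responses()].
#' @return List with `kept` (tibble of complete rows) and
#'   `removed_fraction` (proportion of rows dropped, 0 when `records` is
#'   empty).
#' @export
clean_responses <- function(records) {
  n <- nrow(records)
  keep <- !is.na(records$response)
  frac <- if (n == 0L) 0 else 1 - sum(keep) / n
  if (n > 0L && !any(keep)) {
    warning("all responses are missing", call. = FALSE)
  }
  list(kept = records[keep, , drop = FALSE], removed_fraction = frac)
}

#' Transcribe a word through the lexicon
#'
#' Case-insensitive lexicon lookup followed by [tokenize_ipa()]. Multi-word
#' entries are handled by removing spaces from the stored IPA before
#' tokenizing.
#'
#' @param word Orthographic word.
#' @param lexicon Lexicon tibble from [load_lexicon()].
#' @param table A `feature_table`.
#' @return A `transcription`.
#' @export
transcribe <- function(word, lexicon, table) {
  w <- tolower(trimws(word))
  i <- match(w, lexicon$word)
  if (is.na(i)) {
    stop("word not in lexicon: ", dQuote(w), call. = FALSE)
  }
  tokenize_ipa(gsub(" ", "", lexicon$ipa[i], fixed = TRUE), table, word = w)
}

#' Score all responses against their targets
#'
#' Computes the per-response distance metrics ([score_pair()]) for every
#' cleaned (target, response) pair. Pairs whose target or response cannot be
#' transcribed (absent from the lexicon, or containing segments outside the
#' feature table) are excluded from scoring and collected in a skip report
#' attached as attribute `"skipped"`.
#'
#' @param records Cleaned response tibble (see [clean_responses()]).
#' @param lexicon Lexicon tibble.
#' @param table A `feature_table`.
#' @param indel_penalty See [weighted_feature_edit_distance()].
#' @return A tibble with the input columns plus `raw_cost`, `normalized`,
#'   `levenshtein`, `pct_phonemes`, `exact`; attribute `"skipped"` holds a
#'   tibble of unscorable rows with a `reason` column.
#' @export
score_responses <- function(records, lexicon, table, indel_penalty = NULL) {
  cache <- new.env(parent = emptyenv())
  get_tr <- function(w) {
    if (is.null(cache[[w]])) {
      cache[[w]] <- tryCatch(transcribe(w, lexicon, table),
                             error = function(e) conditionMessage(e))
    }
    cache[[w]]
  }
  rows <- vector("list", nrow(records))
  skipped <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    tt <- get_tr(records$target[i])
    rt <- get_tr(records$response[i])
    if (is.character(tt) || is.character(rt)) {
      skipped[[i]] <- dplyr::mutate(records[i, ],
        reason = if (is.character(tt)) tt else rt)
      next
    }
    rows[[i]] <- dplyr::bind_cols(records[i, ],
                                  score_pair(tt, rt, table, indel_penalty))
  }
  out <- dplyr::bind_rows(rows[!vapply(rows, is.null, logical(1L))])
  attr(out, "skipped") <-
    dplyr::bind_rows(skipped[!vapply(skipped, is.null, logical(1L))])
  out
}

#' Aggregate per-word MaFI norms
#'
#' Averages per-response metrics within each (word, study) cell and then
#' across studies, so a word collected in several studies contributes the
#' mean of its per-study means rather than pooling raw responses. The MaFI
#' score is the negated mean normalized distance: 0 means every guess was
#' the target (maximally informative mouth and facial movements) and more
#' negative values mean visually less informative words.
#'
#' @param scored Scored response tibble from [score_responses()].
#' @return A [tibble::tibble] with one row per word, sorted alphabetically:
#'   `word`, `mafi`, `mean_distance`, `mean_accuracy`, `mean_pct_phonemes`,
#'   `mean_levenshtein`, `n_responses`.
#' @export
aggregate_norms <- function(scored) {
  if (nrow(scored) == 0L) {
    return(tibble::tibble(word = character(0L), mafi = numeric(0L),
                          mean_distance = numeric(0L),
                          mean_accuracy = numeric(0L),
                          mean_pct_phonemes = numeric(0L),
                          mean_levenshtein = numeric(0L),
                          n_responses = integer(0L)))
  }
  by_study <- dplyr::summarise(
    dplyr::group_by(scored, .data$target, .data$study),
    mean_distance = mean(.data$normalized),
    mean_accuracy = mean(.data$exact),
    mean_pct_phonemes = mean(.data$pct_phonemes),
    mean_levenshtein = mean(.data$levenshtein),
    n_responses = dplyr::n(),
    .groups = "drop")
  out <- dplyr::summarise(
    dplyr::group_by(by_study, .data$target),
    mean_distance = mean(.data$mean_distance),
    mean_accuracy = mean(.data$mean_accuracy),
    mean_pct_phonemes = mean(.data$mean_pct_phonemes),
    mean_levenshtein = mean(.data$mean_levenshtein),
    n_responses = as.integer(sum(.data$n_responses)),
    .groups = "drop")
  out <- dplyr::mutate(out, mafi = -.data$mean_distance)
  out <- dplyr::rename(out, word = "target")
  out <- out[order(out$word), c("word", "mafi", "mean_distance",
                                "mean_accuracy", "mean_pct_phonemes",
                                "mean_levenshtein", "n_responses")]
  out
}

#' Write a norms table to CSV
#'
#' Serializes norms deterministically: alphabetical by word, numeric values
#' rounded to 4 decimals, UTF-8, no quoting. Re-running on the same input
#' produces a byte-identical file.
#'
#' @param norms Norms tibble from [aggregate_norms()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_norms <- function(norms, path) {
  out <- norms[order(norms$word), ]
  num <- vapply(out, is.numeric, logical(1L)) & names(out) != "n_responses"
  out[num] <- lapply(out[num], round, digits = 4L)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.csv(as.data.frame(out), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Full norming pipeline: responses file to norms table
#'
#' Convenience wrapper chaining [load_responses()], [clean_responses()],
#' [score_responses()] and [aggregate_norms()].
#'
#' @param responses Path to a response file, or a response tibble.
#' @param lexicon Path to a lexicon TSV, or a lexicon tibble.
#' @param table A `feature_table` (default the bundled one).
#' @param indel_penalty See [weighted_feature_edit_distance()].
#' @return Norms tibble (see [aggregate_norms()]) with attributes
#'   `"removed_fraction"` (missing-response share) and `"skipped"`
#'   (untranscribable rows).
#' @examples
#' ft <- default_feature_table()
#' lex <- load_lexicon(system.file("extdata", "english_lexicon.tsv",
#'                                 package = "mafi"))
#' resp <- tibble::tibble(participant = c("p1", "p2"), target = "bat",
#'                        response = c("pat", "cat"), study = NA)
#' mafi_norms(resp, lex, ft)  # mafi = -(0.0833 + 0.75) / 2
#' @export
mafi_norms <- function(responses, lexicon, table = default_feature_table(),
                       indel_penalty = NULL) {
  if (is.character(responses)) responses <- load_responses(responses)
  if (is.character(lexicon)) lexicon <- load_lexicon(lexicon)
  cleaned <- clean_responses(responses)
  scored <- score_responses(cleaned$kept, lexicon, table, indel_penalty)
  norms <- aggregate_norms(scored)
  attr(norms, "removed_fraction") <- cleaned$removed_fraction
  attr(norms, "skipped") <- attr(scored, "skipped")
  norms
}
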