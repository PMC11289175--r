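#' Viseme-confusion model for simulated speechreading
#'
#' Parameters of the per-segment noise process used to generate synthetic
#' speechreading guesses. Each target segment is independently perceived
#' veridically with probability `p_correct`, deleted with probability
#' `p_delete`, and otherwise substituted. A substituted segment that
#' belongs to a viseme class is replaced by another member of the same
#' class with probability `p_within_viseme` (visually similar phonemes are
#' confused with each other); otherwise -- and always for segments outside
#' any class -- the substitute is drawn uniformly from table segments of
#' the same broad category (consonant vs non-consonant, by the table's
#' `cons` feature). Optionally a random segment is inserted after each
#' position with probability `p_insert` (default 0).
#'
#' @param p_correct Probability a segment is perceived correctly.
#' @param p_within_viseme Probability a confused in-class segment stays
#'   within its viseme class.
#' @param p_delete Probability a segment is missed entirely;
#'   `p_correct + p_delete` must not exceed 1.
#' @param p_insert Per-position insertion probability.
#' @param seed Integer seed making corpus generation deterministic.
#' @return An object of class `confusion_model`.
#' @examples
#' confusion_model(p_correct = 0.5, p_within_viseme = 0.9)
#' @export
confusion_model <- function(p_correct = 0.5, p_within_viseme = 0.9,
                            p_delete = 0.1, p_insert = 0, seed = 1L) {
  for (p in c(p_correct, p_within_viseme, p_delete, p_insert)) {
    stopifnot(is.numeric(p), length(p) == 1L, p >= 0, p <= 1)
  }
  if (p_correct + p_delete > 1) {
    stop("p_correct + p_delete must be <= 1", call. = FALSE)
  }
  structure(list(p_correct = p_correct, p_within_viseme = p_within_viseme,
                 p_delete = p_delete, p_insert = p_insert,
                 seed = as.integer(seed)),
            class = "confusion_model")
}

#' @export
print.confusion_model <- function(x, ...) {
  cat(sprintf(paste0("<confusion_model: p_correct=%.2f p_within=%.2f ",
                     "p_delete=%.2f p_insert=%.2f seed=%d>\n"),
              x$p_correct, x$p_within_viseme, x$p_delete, x$p_insert,
              x$seed))
  invisible(x)
}

# uniform draw from table segments of the same broad category as `sym`,
# excluding `sym` itself (falls back to sym if it is the only member)
random_same_category <- function(sym, table) {
  cons <- table$values[, "cons"]
  pool <- rownames(table$values)[cons == cons[[seg_index(sym, table)]]]
  pool <- setdiff(pool, sym)
  if (length(pool) == 0L) return(sym)
  pool[sample.int(length(pool), 1L)]
}

#' Simulate one speechreading guess for a target word
#'
#' Applies the confusion process of a [confusion_model()] to each segment
#' of the target transcription. Uses the current RNG state; seed-setting is
#' handled by [simulate_corpus()].
#'
#' @param target Non-empty `transcription`.
#' @param model A `confusion_model`.
#' @param inv A `viseme_inventory`.
#' @param table A `feature_table`.
#' @return A `transcription` of the simulated guess (possibly empty).
#' @export
simulate_response <- function(target, model, inv = viseme_inventory(),
                              table = default_feature_table()) {
  if (length(target$segments) == 0L) {
    stop("cannot simulate a response to an empty target", call. = FALSE)
  }
  out <- character(0L)
  for (sym in target$segments) {
    u <- stats::runif(1L)
    if (u < model$p_correct) {
      out <- c(out, sym)
    } else if (u < model$p_correct + model$p_delete) {
      # segment missed
    } else {
      cls <- viseme_of(sym, inv)
      within <- !is.na(cls) && stats::runif(1L) < model$p_within_viseme
      sub <- if (within) {
        members <- setdiff(inv$classes[[cls]], sym)
        if (length(members) == 0L) sym else
          members[sample.int(length(members), 1L)]
      } else {
        random_same_category(sym, table)
      }
      out <- c(out, sub)
    }
    if (model$p_insert > 0 && stats::runif(1L) < model$p_insert) {
      all_syms <- rownames(table$values)
      out <- c(out, all_syms[sample.int(length(all_syms), 1L)])
    }
  }
  tokenize_ipa(paste(out, collapse = ""), table)
}

#' Simulate a speechreading response corpus
#'
#' Generates `n_participants` independent guesses for every target word,
#' mirroring a norming study in which each word is viewed by several
#' participants. Guesses are rendered back to IPA strings and registered as
#' pseudo-word entries in a working copy of the lexicon, so the returned
#' corpus can be fed straight into [mafi_norms()]. Deterministic given the
#' model's seed.
#'
#' @param targets Character vector of orthographic target words, all
#'   present in the lexicon.
#' @param lexicon Lexicon tibble from [load_lexicon()].
#' @param model A `confusion_model` (its `seed` fixes the RNG).
#' @param n_participants Number of simulated participants per word.
#' @param inv A `viseme_inventory`.
#' @param table A `feature_table`.
#' @param study Study label stored on the records.
#' @return List with `responses` (tibble: `participant`, `target`,
#'   `response`, `study`) and `lexicon` (input lexicon extended with
#'   pseudo-word entries for every simulated guess).
#' @examples
#' ft <- default_feature_table()
#' lex <- load_lexicon(system.file("extdata", "english_lexicon.tsv",
#'                                 package = "mafi"))
#' sim <- simulate_corpus(c("bat", "moon"), lex,
#'                        confusion_model(seed = 7L), n_participants = 5,
#'                        table = ft)
#' mafi_norms(sim$responses, sim$lexicon, ft)
#' @export
simulate_corpus <- function(targets, lexicon, model, n_participants = 10L,
                            inv = viseme_inventory(),
                            table = default_feature_table(),
                            study = "sim") {
  targets <- tolower(targets)
  absent <- setdiff(targets, lexicon$word)
  if (length(absent) > 0L) {
    stop("target(s) not in lexicon: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  trs <- lapply(targets, transcribe, lexicon = lexicon, table = table)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(model$seed)
  rows <- vector("list", n_participants * length(targets))
  k <- 0L
  new_ipa <- character(0L)
  for (p in seq_len(n_participants)) {
    pid <- sprintf("S%03d", p)
    for (i in seq_along(targets)) {
      guess <- simulate_response(trs[[i]], model, inv, table)
      ipa <- guess$ipa
      k <- k + 1L
      rows[[k]] <- tibble::tibble(
        participant = pid, target = targets[i],
        response = if (nchar(ipa) == 0L) NA_character_ else ipa,
        study = study)
      if (nchar(ipa) > 0L) new_ipa <- c(new_ipa, ipa)
    }
  }
  new_ipa <- setdiff(unique(new_ipa), lexicon$word)
  lex <- dplyr::bind_rows(lexicon,
                          tibble::tibble(word = new_ipa, ipa = new_ipa))
  lex <- lex[!duplicated(lex$word), ]
  list(responses = dplyr::bind_rows(rows), lexicon = lex)
}

#' Generate a pseudo-word lexicon
#'
#' Builds phonotactically simple pseudo-words (alternating consonants and
#' vowels from the feature table) for synthetic experiments, returned in
#' lexicon form with the IPA string doubling as the orthographic key. The
#' default length range of 1 to 12 segments matches the phoneme-count range
#' of the kind of word corpus these norms are collected for.
#'
#' @param n_words Number of pseudo-words.
#' @param table A `feature_table`.
#' @param min_len,max_len Segment-count range (uniform).
#' @param seed Integer seed.
#' @return Lexicon tibble with columns `word` and `ipa`.
#' @export
simulate_lexicon <- function(n_words, table = default_feature_table(),
                             min_len = 1L, max_len = 12L, seed = 1L) {
  stopifnot(n_words >= 1L, min_len >= 1L, max_len >= min_len)
  syms <- rownames(table$values)
  is_vowel <- table$values[, "syl"] == 1L
  vowels <- syms[is_vowel]
  consonants <- syms[!is_vowel]
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  words <- character(0L)
  while (length(words) < n_words) {
    len <- sample(seq(min_len, max_len), 1L)
    start_c <- stats::runif(1L) < 0.8
    segs <- vapply(seq_len(len), function(i) {
      pool <- if (xor(i %% 2L == 1L, !start_c)) consonants else vowels
      pool[sample.int(length(pool), 1L)]
    }, character(1L))
    words <- unique(c(words, paste(segs, collapse = "")))
  }
  tibble::tibble(word = words, ipa = words)
}
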