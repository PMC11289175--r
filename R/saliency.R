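#' Default viseme inventory with visual-saliency features
#'
#' Viseme classes group phonemes that are nearly indistinguishable on the
#' mouth; each class carries the visually salient articulatory features it
#' displays. The defaults are the classes relevant to word-level visual
#' saliency: \{f\} = /f, v/ (lower lip tuck), \{ch\} = /ʃ, tʃ, dʒ/
#' (protrusion), \{w\} = /w/ (protrusion and lip rounding), \{p\} =
#' /b, p, m/ (labial closure), \{j\} = /j/ (lip rounding) and \{r\} =
#' /r, ɹ/ (lip rounding). Phonemes outside these classes (most vowels,
#' velars, alveolars) carry none of the four features.
#'
#' @param path Optional CSV overriding the defaults, with columns
#'   `viseme,phoneme,features` (features semicolon-separated; empty allowed).
#'   Viseme class boundaries are fuzzy across speakers and studies, so the
#'   inventory is user-replaceable.
#' @return An object of class `viseme_inventory`: list with `classes`
#'   (named list: viseme label -> character vector of member phonemes) and
#'   `class_features` (named list: viseme label -> character vector drawn
#'   from lower_lip_tuck, protrusion, labial_closure, lip_rounding).
#' @examples
#' inv <- viseme_inventory()
#' inv$classes[["p"]]          # "b" "p" "m"
#' inv$class_features[["w"]]   # protrusion, lip_rounding
#' @export
viseme_inventory <- function(path = NULL) {
  if (is.null(path)) {
    classes <- list(
      f  = c("f", "v"),
      ch = c("ʃ", "tʃ", "dʒ"),   # ʃ tʃ dʒ
      w  = "w",
      p  = c("b", "p", "m"),
      j  = "j",
      r  = c("r", "ɹ"))                    # r ɹ
    class_features <- list(
      f  = "lower_lip_tuck",
      ch = "protrusion",
      w  = c("protrusion", "lip_rounding"),
      p  = "labial_closure",
      j  = "lip_rounding",
      r  = "lip_rounding")
  } else {
    df <- utils::read.csv(path, fileEncoding = "UTF-8",
                          colClasses = "character")
    if (!all(c("viseme", "phoneme", "features") %in% names(df))) {
      stop("viseme file needs columns `viseme`, `phoneme`, `features`",
           call. = FALSE)
    }
    df$phoneme <- nfc(df$phoneme)
    classes <- split(df$phoneme, df$viseme)
    class_features <- lapply(split(df$features, df$viseme), function(f) {
      unique(unlist(strsplit(f[nzchar(f)], ";", fixed = TRUE)))
    })
    known <- c("lower_lip_tuck", "protrusion", "labial_closure",
               "lip_rounding")
    bad <- setdiff(unlist(class_features), known)
    if (length(bad) > 0L) {
      stop("unknown saliency feature(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  members <- unlist(classes, use.names = FALSE)
  dup <- members[duplicated(members)]
  if (length(dup) > 0L) {
    stop("phoneme(s) assigned to more than one viseme class: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  structure(list(classes = classes, class_features = class_features),
            class = "viseme_inventory")
}

#' @export
print.viseme_inventory <- function(x, ...) {
  for (v in names(x$classes)) {
    cat(sprintf("{%s}: /%s/  [%s]\n", v,
                paste(x$classes[[v]], collapse = ", "),
                paste(x$class_features[[v]], collapse = ", ")))
  }
  invisible(x)
}

# phoneme-level saliency membership sets
FRONT_PHONEMES <- c("b", "p", "m", "f", "v")
ROUND_PHONEMES <- c("r", "ɹ", "w", "u", "o", "ɔ")  # r ɹ w u o ɔ

#' Phoneme-level visual saliency of a segment
#'
#' Codes the two phoneme features that make mouth movements visually
#' identifiable: frontness -- a front place of articulation, i.e. bilabials
#' /b, p, m/ and labio-dentals /f, v/ -- and roundness -- lip rounding as in
#' /r, w, u, o, ɔ/. Length-marked and diphthongized vowels inherit the
#' status of their base symbol ("uː" counts as /u/), and a segment also
#' counts as rounded if its feature-table `round` value is +1, so lexicons
#' that transcribe /o/-like vowels differently are still coded.
#'
#' @param seg An IPA symbol (need not be in the table; unknown symbols are
#'   neither front nor round).
#' @param table Optional `feature_table` consulted for the `round` feature.
#' @return Named logical vector with elements `front` and `round`.
#' @examples
#' phoneme_saliency("m")   # front
#' phoneme_saliency("uː")  # round
#' @export
phoneme_saliency <- function(seg, table = NULL) {
  seg <- nfc(seg)
  base <- sub("ː$", "", seg)  # strip length mark
  front <- seg %in% FRONT_PHONEMES || base %in% FRONT_PHONEMES
  round <- seg %in% ROUND_PHONEMES || base %in% ROUND_PHONEMES
  if (!round && !is.null(table)) {
    i <- match(seg, rownames(table$values))
    if (!is.na(i) && table$values[i, "round"] == 1L) round <- TRUE
  }
  c(front = front, round = round)
}

#' Viseme class of a segment
#'
#' @param seg An IPA symbol.
#' @param inv A `viseme_inventory`.
#' @return The viseme label (e.g. "p" for /m/) or `NA_character_` if the
#'   segment belongs to no class.
#' @export
viseme_of <- function(seg, inv) {
  seg <- nfc(seg)
  for (v in names(inv$classes)) {
    if (seg %in% inv$classes[[v]]) return(v)
  }
  NA_character_
}

#' Visual-saliency profile and informativeness loads of a word
#'
#' Codes a transcription for the presence of salient phoneme features
#' (frontness, roundness) and salient viseme features (lower lip tuck,
#' protrusion, labial closure, lip rounding), and computes the two
#' informativeness loads: the phoneme load is the count of front plus
#' rounded phonemes divided by the word's phoneme count, and the viseme load
#' is the count of segments belonging to a viseme class bearing any of the
#' four features divided by the phoneme count. A phoneme that were both
#' front and rounded would be counted once per property; loads are capped
#' at 1.
#'
#' @param t A non-empty `transcription`.
#' @param inv A `viseme_inventory` (default [viseme_inventory()]).
#' @param table Optional `feature_table` for roundness-by-feature lookups.
#' @return One-row [tibble::tibble] with columns `word`, `n_phonemes`,
#'   `has_frontness`, `has_roundness`, `has_lower_lip_tuck`,
#'   `has_protrusion`, `has_labial_closure`, `has_lip_rounding`,
#'   `load_phoneme`, `load_viseme`.
#' @examples
#' ft <- default_feature_table()
#' word_profile(tokenize_ipa("muːn", ft, word = "moon"), table = ft)
#' @export
word_profile <- function(t, inv = viseme_inventory(), table = NULL) {
  segs <- t$segments
  n <- length(segs)
  if (n == 0L) stop("cannot profile an empty transcription", call. = FALSE)
  sal <- vapply(segs, phoneme_saliency, logical(2L), table = table)
  vis <- vapply(segs, viseme_of, character(1L), inv = inv)
  feats <- lapply(vis, function(v) {
    if (is.na(v)) character(0L) else inv$class_features[[v]]
  })
  has <- function(f) any(vapply(feats, function(x) f %in% x, logical(1L)))
  tibble::tibble(
    word = if (is.na(t$word)) t$ipa else t$word,
    n_phonemes = n,
    has_frontness = any(sal["front", ]),
    has_roundness = any(sal["round", ]),
    has_lower_lip_tuck = has("lower_lip_tuck"),
    has_protrusion = has("protrusion"),
    has_labial_closure = has("labial_closure"),
    has_lip_rounding = has("lip_rounding"),
    load_phoneme = min(1, (sum(sal["front", ]) + sum(sal["round", ])) / n),
    load_viseme = min(1, sum(lengths(feats) > 0L) / n))
}

#' Saliency profiles for a set of words
#'
#' Vectorized [word_profile()] over a lexicon: transcribes each word and
#' stacks the per-word profiles.
#'
#' @param words Character vector of orthographic words.
#' @param lexicon A lexicon tibble from [load_lexicon()].
#' @param table A `feature_table`.
#' @param inv A `viseme_inventory`.
#' @return A tibble with one row per transcribable word (see
#'   [word_profile()]); words missing from the lexicon are dropped with a
#'   warning.
#' @export
word_profiles <- function(words, lexicon, table, inv = viseme_inventory()) {
  tr <- lapply(words, function(w) {
    tryCatch(transcribe(w, lexicon, table), error = function(e) NULL)
  })
  miss <- vapply(tr, is.null, logical(1L))
  if (any(miss)) {
    warning("dropped ", sum(miss), " word(s) missing from the lexicon: ",
            paste(utils::head(words[miss], 5L), collapse = ", "),
            if (sum(miss) > 5L) ", ..." else "", call. = FALSE)
  }
  dplyr::bind_rows(lapply(tr[!miss], word_profile, inv = inv, table = table))
}
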