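#' Load an articulatory feature table and its feature weights
#'
#' Reads a segment-by-feature table of articulatory (phonological) feature
#' values together with a per-feature cost weight file, and returns the
#' validated `feature_table` object used by all distance computations.
#'
#' The segment file is a UTF-8 CSV whose first column `ipa` holds the IPA
#' symbol (affricates such as "tʃ" and length-marked vowels such as "uː" are
#' single rows) and whose remaining columns hold one articulatory feature
#' each, coded `+` (present, +1), `-` (absent, -1) or `0` (not applicable).
#' The weight file is a CSV with columns `feature,weight`; weights are
#' non-negative substitution costs per unit of feature change, so a full
#' `+` to `-` flip on a feature costs twice its weight. Under the bundled
#' weights the voicing feature costs 0.125 per unit and place features such
#' as anterior, labial, high and back cost 0.25, which makes a /b/-/p/
#' substitution (voicing only) cost 0.25 and a /b/-/k/ substitution
#' (voicing plus four place features) cost 2.25.
#'
#' Feature columns may appear in any order in either file; they are
#' reconciled by name. Segment keys are Unicode-normalized (NFC) and must be
#' unique after normalization.
#'
#' @param path Path to the segment feature CSV.
#' @param weights_path Path to the feature weight CSV.
#' @return An object of class `feature_table`: a list with elements
#'   `features` (character vector of feature names), `values` (integer
#'   matrix of -1/0/+1, one row per segment, rownames are NFC IPA symbols),
#'   `weights` (named non-negative numeric), and precomputed `sub_cost`
#'   (segment-by-segment substitution cost matrix) and `indel` (per-segment
#'   feature-mass insertion/deletion cost).
#' @examples
#' ft <- load_feature_table(
#'   system.file("extdata", "english_features.csv", package = "mafi"),
#'   system.file("extdata", "feature_weights.csv", package = "mafi"))
#' ft$weights[["voi"]]  # 0.125
#' @seealso [tokenize_ipa()], [weighted_feature_edit_distance()]
#' @export
load_feature_table <- function(path, weights_path) {
  for (p in c(path, weights_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  raw <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8",
                         colClasses = "character")
  if (ncol(raw) < 2L || names(raw)[1L] != "ipa") {
    stop("segment file must have an `ipa` first column plus feature columns",
         call. = FALSE)
  }
  wt <- utils::read.csv(weights_path, fileEncoding = "UTF-8")
  if (!all(c("feature", "weight") %in% names(wt))) {
    stop("weight file must have columns `feature` and `weight`", call. = FALSE)
  }
  features <- setdiff(names(raw), "ipa")
  missing_w <- setdiff(features, wt$feature)
  if (length(missing_w) > 0L) {
    stop("missing weight for feature(s): ", paste(missing_w, collapse = ", "),
         call. = FALSE)
  }
  weights <- stats::setNames(as.numeric(wt$weight), wt$feature)[features]
  if (anyNA(weights) || any(weights < 0)) {
    stop("feature weights must be non-negative numbers", call. = FALSE)
  }

  keys <- nfc(trimws(raw$ipa))
  dup <- keys[duplicated(keys)]
  if (length(dup) > 0L) {
    stop("duplicate segment row(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  vals <- as.matrix(raw[, features, drop = FALSE])
  ok <- vals %in% c("+", "-", "0")
  if (!all(ok)) {
    bad <- which(!matrix(ok, nrow = nrow(vals)), arr.ind = TRUE)[1L, ]
    stop(sprintf("invalid feature value %s for segment %s, feature %s",
                 dQuote(vals[bad[1L], bad[2L]]), keys[bad[1L]],
                 features[bad[2L]]), call. = FALSE)
  }
  num <- matrix(c("+" = 1L, "-" = -1L, "0" = 0L)[vals], nrow = nrow(vals),
                dimnames = list(keys, features))

  tab <- structure(
    list(features = features, values = num, weights = weights),
    class = "feature_table")
  tab$sub_cost <- outer(seq_len(nrow(num)), seq_len(nrow(num)),
                        Vectorize(function(i, j) {
                          sum(weights * abs(num[i, ] - num[j, ]))
                        }))
  dimnames(tab$sub_cost) <- list(keys, keys)
  tab$indel <- apply(num, 1L, function(v) sum(weights * abs(v)))
  tab
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table: %d segments x %d features>\n",
              nrow(x$values), length(x$features)))
  cat("segments:", paste(utils::head(rownames(x$values), 12L),
                         collapse = " "),
      if (nrow(x$values) > 12L) "..." else "", "\n")
  invisible(x)
}

#' Default bundled feature system
#'
#' Convenience loader for the feature table and weights shipped with the
#' package (a ~57-segment English inventory over 21 articulatory features).
#'
#' @return A `feature_table`; see [load_feature_table()].
#' @export
default_feature_table <- function() {
  load_feature_table(
    system.file("extdata", "english_features.csv", package = "mafi"),
    system.file("extdata", "feature_weights.csv", package = "mafi"))
}

# NFC Unicode normalization; combining diacritics have several encodings and
# all lookups go through this.
nfc <- function(x) stringi::stri_trans_nfc(enc2utf8(x))

#' Tokenize an IPA string into feature-table segments
#'
#' Splits an IPA string into the segment inventory of a `feature_table`
#' using greedy longest-match scanning from left to right, so multi-character
#' entries present in the table (affricates "tʃ", "dʒ", length-marked vowels
#' "uː", diphthongs "aɪ") are kept as single segments. Input is
#' NFC-normalized before matching. The segment count of the result is the
#' word's phoneme count used for length normalization.
#'
#' @param ipa An IPA string (may be empty).
#' @param table A `feature_table`.
#' @param word Optional orthographic form carried along for reporting.
#' @return An object of class `transcription`: list with `word`, `ipa`, and
#'   `segments` (character vector of IPA symbols, in order). Concatenating
#'   `segments` reproduces the normalized input.
#' @examples
#' ft <- default_feature_table()
#' tokenize_ipa("bæt", ft)$segments   # "b" "æ" "t"
#' tokenize_ipa("tʃɪn", ft)$segments  # "tʃ" "ɪ" "n"
#' @export
tokenize_ipa <- function(ipa, table, word = NA_character_) {
  stopifnot(inherits(table, "feature_table"))
  s <- nfc(ipa)
  keys <- rownames(table$values)
  maxlen <- max(nchar(keys))
  n <- nchar(s)
  segments <- character(0L)
  i <- 1L
  while (i <= n) {
    hit <- NULL
    for (take in seq(min(maxlen, n - i + 1L), 1L)) {
      cand <- substr(s, i, i + take - 1L)
      if (cand %in% keys) {
        hit <- cand
        break
      }
    }
    if (is.null(hit)) {
      stop(sprintf("cannot tokenize %s: no segment matches %s at position %d",
                   dQuote(s), dQuote(substr(s, i, i)), i), call. = FALSE)
    }
    segments <- c(segments, hit)
    i <- i + nchar(hit)
  }
  structure(list(word = word, ipa = s, segments = segments),
            class = "transcription")
}

#' @export
print.transcription <- function(x, ...) {
  cat(sprintf("<transcription%s /%s/: %s>\n",
              if (is.na(x$word)) "" else paste0(" ", dQuote(x$word)),
              x$ipa, paste(x$segments, collapse = " ")))
  invisible(x)
}

#' @export
length.transcription <- function(x) length(x$segments)
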