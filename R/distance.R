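#' Substitution cost between two IPA segments
#'
#' The cost of replacing segment `a` with segment `b` is the weighted sum of
#' absolute feature-value differences: for each articulatory feature, the
#' number of units separating the two values in \{-1, 0, +1\} times that
#' feature's weight. A full flip (+1 to -1) on a feature therefore costs two
#' units, e.g. /b/ vs /p/ differ only in voicing (weight 0.125) and cost
#' 2 x 0.125 = 0.25, while /b/ vs /k/ also flip anterior, labial, high and
#' back (each 0.25) and cost 2.25.
#'
#' @param a,b IPA symbols present in the table.
#' @param table A `feature_table`.
#' @return Non-negative cost; 0 iff the two segments have identical vectors.
#' @examples
#' ft <- default_feature_table()
#' substitution_cost("b", "p", ft)  # 0.25
#' substitution_cost("b", "k", ft)  # 2.25
#' @export
substitution_cost <- function(a, b, table) {
  table$sub_cost[seg_index(a, table), seg_index(b, table)]
}

#' Insertion/deletion cost of a segment
#'
#' By default an indel is priced as a substitution against a silent null
#' segment whose features are all 0: the sum over features of
#' weight x |value|, i.e. the segment's weighted feature mass. A constant
#' penalty can be used instead via `penalty`.
#'
#' @param a IPA symbol present in the table.
#' @param table A `feature_table`.
#' @param penalty `NULL` (default, feature-mass cost) or a single
#'   non-negative number used as a flat per-segment indel penalty.
#' @return Non-negative cost.
#' @export
indel_cost <- function(a, table, penalty = NULL) {
  if (!is.null(penalty)) {
    stopifnot(is.numeric(penalty), length(penalty) == 1L, penalty >= 0)
    return(as.numeric(penalty))
  }
  unname(table$indel[seg_index(a, table)])
}

seg_index <- function(sym, table) {
  i <- match(nfc(sym), rownames(table$values))
  if (anyNA(i)) {
    stop("segment(s) not in feature table: ",
         paste(sym[is.na(i)], collapse = ", "), call. = FALSE)
  }
  i
}

#' Weighted feature edit distance between two transcriptions
#'
#' Minimum total cost of transforming one segment sequence into the other
#' by insertions, deletions and substitutions, found by standard dynamic
#' programming. Substitutions are priced by [substitution_cost()] (weighted
#' feature differences) and indels by [indel_cost()]. The distance is
#' symmetric; identical transcriptions score 0, and visually confusable
#' within-viseme substitutions (/b/-/p/) cost far less than cross-viseme
#' ones (/b/-/k/).
#'
#' @param t1,t2 `transcription` objects (see [tokenize_ipa()]).
#' @param table A `feature_table`.
#' @param indel_penalty `NULL` for feature-mass indel costs (default), or a
#'   flat non-negative per-segment penalty.
#' @return Non-negative total edit cost (0 for empty vs empty).
#' @examples
#' ft <- default_feature_table()
#' weighted_feature_edit_distance(tokenize_ipa("bæt", ft),
#'                                tokenize_ipa("pæt", ft), ft)  # 0.25
#' @export
weighted_feature_edit_distance <- function(t1, t2, table,
                                           indel_penalty = NULL) {
  a <- seg_index(t1$segments, table)
  b <- seg_index(t2$segments, table)
  n <- length(a)
  m <- length(b)
  del <- if (is.null(indel_penalty)) unname(table$indel[a]) else
    rep(as.numeric(indel_penalty), n)
  ins <- if (is.null(indel_penalty)) unname(table$indel[b]) else
    rep(as.numeric(indel_penalty), m)
  if (n == 0L) return(sum(ins))
  if (m == 0L) return(sum(del))
  sub <- table$sub_cost[a, b, drop = FALSE]
  prev <- c(0, cumsum(ins))
  for (i in seq_len(n)) {
    cur <- numeric(m + 1L)
    cur[1L] <- prev[1L] + del[i]
    for (j in seq_len(m)) {
      cur[j + 1L] <- min(prev[j] + sub[i, j],    # substitute / match
                         prev[j + 1L] + del[i],  # delete from t1
                         cur[j] + ins[j])        # insert from t2
    }
    prev <- cur
  }
  prev[m + 1L]
}

#' Length-normalized feature edit distance
#'
#' The weighted feature edit distance divided by the phoneme count of the
#' longer of the two words, the per-response phonological distance that is
#' averaged and negated into MaFI scores. For target "bat" /bæt/ the
#' response "pat" /pæt/ scores 0.25 / 3 = 0.083 and "cat" /kæt/ scores
#' 2.25 / 3 = 0.75.
#'
#' @inheritParams weighted_feature_edit_distance
#' @return Non-negative normalized distance.
#' @export
normalized_distance <- function(t1, t2, table, indel_penalty = NULL) {
  len <- max(length(t1$segments), length(t2$segments))
  if (len == 0L) {
    stop("normalized distance is undefined for two empty transcriptions",
         call. = FALSE)
  }
  weighted_feature_edit_distance(t1, t2, table, indel_penalty) / len
}

#' Segment-level Levenshtein distance
#'
#' Unit-cost edit distance (insertions, deletions, substitutions all cost 1)
#' over IPA segments, computed with the same alignment machinery as the
#' weighted distance but with flat costs.
#'
#' @param t1,t2 `transcription` objects.
#' @return Non-negative integer edit count.
#' @export
levenshtein_distance <- function(t1, t2) {
  as.integer(round(unit_dp(t1$segments, t2$segments)$cost))
}

# Unit-cost DP returning both the minimum edit count and, among minimum-cost
# alignments, the maximum number of identically matched positions
# (lexicographic optimization; the match count feeds pct_phonemes_correct).
unit_dp <- function(a, b) {
  n <- length(a)
  m <- length(b)
  cost <- matrix(0, n + 1L, m + 1L)
  mtch <- matrix(0L, n + 1L, m + 1L)
  cost[, 1L] <- 0:n
  cost[1L, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      eq <- a[i] == b[j]
      cd <- c(cost[i, j] + !eq,      # diagonal
              cost[i, j + 1L] + 1,   # delete
              cost[i + 1L, j] + 1)   # insert
      md <- c(mtch[i, j] + eq, mtch[i, j + 1L], mtch[i + 1L, j])
      best <- min(cd)
      cost[i + 1L, j + 1L] <- best
      mtch[i + 1L, j + 1L] <- max(md[cd == best])
    }
  }
  list(cost = cost[n + 1L, m + 1L], matches = mtch[n + 1L, m + 1L])
}

#' Proportion of target phonemes correctly identified
#'
#' Aligns response to target at minimum unit edit cost (breaking ties in
#' favor of the most identical matches) and returns the number of aligned
#' positions where the segments are identical, divided by the target's
#' phoneme count, capped at 1. Both "pat" and "cat" against target "bat"
#' share 2 of 3 phonemes, giving 0.67 -- the score cannot tell the two
#' responses apart, which is what motivates the feature-weighted distance.
#'
#' @param target,response `transcription` objects; `target` must be
#'   non-empty.
#' @return Proportion in \[0, 1\].
#' @export
pct_phonemes_correct <- function(target, response) {
  if (length(target$segments) == 0L) {
    stop("pct_phonemes_correct requires a non-empty target", call. = FALSE)
  }
  min(1, unit_dp(target$segments, response$segments)$matches /
        length(target$segments))
}

#' Exact speechreading match
#'
#' Whole-word accuracy: `TRUE` iff the two transcriptions have identical
#' segment sequences.
#'
#' @param target,response `transcription` objects.
#' @return Logical scalar.
#' @export
exact_match <- function(target, response) {
  identical(target$segments, response$segments)
}

#' Score one response against one target
#'
#' Bundles all per-response metrics for a (target, response) transcription
#' pair: raw and normalized weighted feature edit distance, segment
#' Levenshtein distance, percent phonemes correct and exact-match accuracy.
#'
#' @inheritParams pct_phonemes_correct
#' @param table A `feature_table`.
#' @param indel_penalty See [weighted_feature_edit_distance()].
#' @return A one-row [tibble::tibble] with columns `raw_cost`, `normalized`,
#'   `levenshtein`, `pct_phonemes`, `exact`.
#' @examples
#' ft <- default_feature_table()
#' score_pair(tokenize_ipa("bæt", ft), tokenize_ipa("kæt", ft), ft)
#' @export
score_pair <- function(target, response, table, indel_penalty = NULL) {
  tibble::tibble(
    raw_cost = weighted_feature_edit_distance(target, response, table,
                                              indel_penalty),
    normalized = normalized_distance(target, response, table, indel_penalty),
    levenshtein = levenshtein_distance(target, response),
    pct_phonemes = pct_phonemes_correct(target, response),
    exact = exact_match(target, response))
}
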