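# Shared fixtures: bundled feature system and lexicon, loaded once.
ft <- default_feature_table()
lex <- load_lexicon(system.file("extdata", "english_lexicon.tsv",
                                package = "mafi"))

tr <- function(ipa, word = NA_character_) tokenize_ipa(ipa, ft, word = word)

# Brute-force edit-distance oracle: exhaustive recursion over edit scripts,
# independent of the DP implementation. Costs come straight from the
# per-segment cost functions. Only usable for short transcriptions.
bf_distance <- function(a, b, table, indel_penalty = NULL) {
  rec <- function(i, j) {
    if (i > length(a) && j > length(b)) return(0)
    opts <- numeric(0L)
    if (i <= length(a)) {
      opts <- c(opts, indel_cost(a[i], table, indel_penalty) + rec(i + 1L, j))
    }
    if (j <= length(b)) {
      opts <- c(opts, indel_cost(b[j], table, indel_penalty) + rec(i, j + 1L))
    }
    if (i <= length(a) && j <= length(b)) {
      opts <- c(opts, substitution_cost(a[i], b[j], table) + rec(i + 1L, j + 1L))
    }
    min(opts)
  }
  rec(1L, 1L)
}

# Textbook Levenshtein recurrence (memo-free, unit costs) for cross-checks.
bf_levenshtein <- function(a, b) {
  rec <- function(i, j) {
    if (i > length(a)) return(length(b) - j + 1L)
    if (j > length(b)) return(length(a) - i + 1L)
    min(rec(i + 1L, j) + 1L, rec(i, j + 1L) + 1L,
        rec(i + 1L, j + 1L) + (a[i] != b[j]))
  }
  rec(1L, 1L)
}

# Random transcription of given length from the fixture inventory.
random_tr <- function(len, vowels_too = TRUE) {
  syms <- rownames(ft$values)
  picked <- syms[sample.int(length(syms), len, replace = TRUE)]
  tokenize_ipa(paste(picked, collapse = ""), ft)
}

# Small synthetic covariate table for regression tests. Neighborhood counts
# are Poisson draws by default: random pseudo-word lexicons have almost no
# one-edit neighbors, so exact counts there are degenerate (all zero).
# exact_neighbors = TRUE computes real one-edit counts, for use with the
# bundled English lexicon.
synth_covariates <- function(profiles, lexicon, seed = 42L,
                             exact_neighbors = FALSE) {
  withr::with_seed(seed, tibble::tibble(
    word = profiles$word,
    log_frequency = stats::rnorm(nrow(profiles), 8, 2),
    aoa = stats::runif(nrow(profiles), 3, 12),
    phon_neighborhood = if (exact_neighbors) {
      neighborhood_density(profiles$word, lexicon, ft)
    } else {
      stats::rpois(nrow(profiles), 4)
    },
    n_phonemes = profiles$n_phonemes))
}
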