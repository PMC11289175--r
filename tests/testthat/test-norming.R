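write_resp <- function(lines, sep = ",") {
  path <- tempfile(fileext = if (sep == ",") ".csv" else ".tsv")
  writeLines(lines, path, useBytes = TRUE)
  path
}

test_that("response loader parses, trims, folds and flags missing", {
  p <- write_resp(c("participant,target,response,study",
                    "P1, Bat ,PAT,B1",
                    "P2,bat,,B1",
                    "P3,bat,cat,B1"))
  r <- load_responses(p)
  expect_equal(nrow(r), 3L)
  expect_identical(r$target, rep("bat", 3L))
  expect_identical(r$response, c("pat", NA, "cat"))
  # tab-separated variant auto-detected
  pt <- write_resp(c("participant\ttarget\tresponse",
                     "P1\tbat\tpat"), sep = "\t")
  expect_identical(load_responses(pt)$response, "pat")
  # schema violations
  pbad <- write_resp(c("participant,word,response", "P1,bat,pat"))
  expect_error(load_responses(pbad), "target")
  pdup <- write_resp(c("participant,target,response",
                       "P1,bat,pat", "P1,bat,mat"))
  expect_warning(r2 <- load_responses(pdup), "duplicate")
  expect_identical(r2$response, "pat")
})

test_that("cleaning drops missing responses and reports the fraction", {
  rec <- tibble::tibble(participant = sprintf("P%d", 1:100),
                        target = "bat",
                        response = c(rep("pat", 99), NA),
                        study = NA_character_)
  cl <- clean_responses(rec)
  expect_equal(nrow(cl$kept), 99L)
  expect_equal(cl$removed_fraction, 0.01)
  none <- clean_responses(rec[1:99, ])
  expect_equal(none$removed_fraction, 0)
  expect_identical(none$kept, rec[1:99, ])
  expect_warning(all_na <- clean_responses(rec[100, ]), "all responses")
  expect_equal(nrow(all_na$kept), 0L)
  expect_equal(all_na$removed_fraction, 1)
})

test_that("lexicon transcription is case-insensitive and strict", {
  expect_identical(transcribe("bat", lex, ft)$segments, c("b", "æ", "t"))
  expect_identical(transcribe("BAT", lex, ft)$segments,
                   transcribe("bat", lex, ft)$segments)
  expect_error(transcribe("flurble", lex, ft), "not in lexicon")
})

test_that("scoring matches the printed per-response distances", {
  rec <- tibble::tibble(participant = c("P1", "P2", "P3"),
                        target = "bat",
                        response = c("pat", "cat", "flurble"),
                        study = NA_character_)
  sc <- score_responses(rec, lex, ft)
  expect_equal(nrow(sc), 2L)
  expect_equal(sc$normalized, c(0.25 / 3, 0.75))
  skipped <- attr(sc, "skipped")
  expect_equal(nrow(skipped), 1L)
  expect_match(skipped$reason, "flurble")
  # identity response scores zero
  self <- score_responses(
    tibble::tibble(participant = "P1", target = "bat", response = "bat",
                   study = NA_character_), lex, ft)
  expect_equal(self$normalized, 0)
})

test_that("aggregation negates the mean distance per word", {
  rec <- tibble::tibble(participant = c("P1", "P2"), target = "bat",
                        response = c("pat", "cat"), study = NA_character_)
  nm <- aggregate_norms(score_responses(rec, lex, ft))
  expect_equal(nm$mafi, -(0.25 / 3 + 0.75) / 2, tolerance = 1e-12)
  expect_equal(nm$mafi, -nm$mean_distance)
  expect_equal(nm$n_responses, 2L)
  # single response "pat": the -0.08 example
  one <- aggregate_norms(score_responses(rec[1L, ], lex, ft))
  expect_equal(round(one$mafi, 2), -0.08)
  # all-correct responses give exactly zero
  perfect <- aggregate_norms(score_responses(
    tibble::tibble(participant = c("P1", "P2"), target = "moon",
                   response = "moon", study = NA_character_), lex, ft))
  expect_equal(perfect$mafi, 0)
  expect_equal(perfect$mean_accuracy, 1)
})

test_that("duplicate words across studies average study-level means", {
  rec <- tibble::tibble(
    participant = c("P1", "P2", "P3"),
    target = "bat",
    response = c("pat", "pat", "cat"),
    study = c("B1", "B1", "A1"))
  nm <- aggregate_norms(score_responses(rec, lex, ft))
  # study means: B1 = 0.0833, A1 = 0.75; averaged, NOT pooled (0.3056)
  expect_equal(nm$mean_distance, (0.25 / 3 + 0.75) / 2, tolerance = 1e-12)
  expect_equal(nm$n_responses, 3L)
})

test_that("MaFI is bounded and zero only under perfect speechreading", {
  sim <- simulate_corpus(c("bat", "moon", "fish", "world"), lex,
                         confusion_model(p_correct = 0.4, seed = 21L),
                         n_participants = 8L, table = ft)
  nm <- mafi_norms(sim$responses, sim$lexicon, ft)
  expect_true(all(nm$mafi <= 0))
  # bound: worst case deletes the whole longer word
  max_indel <- max(ft$indel)
  expect_true(all(nm$mafi >= -2 * max_indel))
  expect_true(all((nm$mafi == 0) == (nm$mean_accuracy == 1)))
})

test_that("aggregating at once equals averaging per participant", {
  rec <- tibble::tibble(
    participant = rep(c("P1", "P2", "P3"), each = 2L),
    target = rep(c("bat", "moon"), 3L),
    response = c("pat", "moon", "cat", "noon", "bat", "mood"),
    study = NA_character_)
  sc <- score_responses(rec, lex, ft)
  pooled <- aggregate_norms(sc)
  per_part <- vapply(split(sc$normalized, sc$target), mean, numeric(1L))
  expect_equal(pooled$mean_distance, unname(per_part[pooled$word]))
})

test_that("norms files are deterministic and well-formed", {
  rec <- tibble::tibble(participant = c("P1", "P2"), target = c("bat", "moon"),
                        response = c("pat", "noon"), study = NA_character_)
  nm <- mafi_norms(rec, lex, ft)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_norms(nm, f1)
  write_norms(nm, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  back <- read.csv(f1, fileEncoding = "UTF-8")
  expect_identical(back$word, sort(back$word))
  expect_equal(back$mafi, round(nm$mafi[order(nm$word)], 4L))
  # empty norms -> header-only file
  f3 <- tempfile(fileext = ".csv")
  write_norms(aggregate_norms(tibble::tibble()[0, ]), f3)
  expect_equal(length(readLines(f3)), 1L)
})
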