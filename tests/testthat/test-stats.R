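make_design <- function(n_words = 40L, seed = 7L) {
  plex <- simulate_lexicon(n_words, ft, seed = seed)
  sim <- simulate_corpus(plex$word, plex,
                         confusion_model(p_correct = 0.5, seed = seed + 1L),
                         n_participants = 6L, table = ft)
  norms <- mafi_norms(sim$responses, sim$lexicon, ft)
  prof <- word_profiles(norms$word, plex, ft)
  cov <- synth_covariates(prof, plex, seed = seed + 2L)
  prepare_design(norms, prof, cov)
}

test_that("design preparation scales covariates and dummy-codes features", {
  d <- make_design()
  for (cn in c("log_frequency", "aoa", "phon_neighborhood", "n_phonemes")) {
    expect_equal(mean(d[[cn]]), 0, tolerance = 1e-10)
    expect_equal(sd(d[[cn]]), 1, tolerance = 1e-10)
  }
  expect_true(all(d$frontness %in% c(0L, 1L)))
  expect_true(all(d$lip_rounding %in% c(0L, 1L)))
})

test_that("design preparation rejects degenerate inputs", {
  d <- make_design(20L)
  prof <- word_profiles(d$word, simulate_lexicon(20L, ft, seed = 7L), ft)
  cov <- tibble::tibble(word = d$word, log_frequency = 1,
                        aoa = seq_len(nrow(d)),
                        phon_neighborhood = seq_len(nrow(d)),
                        n_phonemes = prof$n_phonemes)
  norms <- tibble::tibble(word = d$word, mafi = d$mafi)
  expect_error(prepare_design(norms, prof, cov), "log_frequency")
  expect_error(
    prepare_design(tibble::tibble(word = "zzz", mafi = -1), prof,
                   dplyr::mutate(cov, log_frequency = rnorm(nrow(cov)))),
    "no words shared")
  # words missing a covariate are dropped listwise, with a message
  cov2 <- dplyr::mutate(cov, log_frequency = rnorm(nrow(cov)))
  cov2$aoa[1L] <- NA
  expect_message(
    d2 <- prepare_design(norms, prof, cov2), "dropped")
  expect_equal(nrow(d2), nrow(d) - 1L)
  expect_identical(attr(d2, "dropped"), cov2$word[1L])
})

test_that("OLS fit matches the closed-form normal equations", {
  d <- make_design()
  preds <- c("frontness", "roundness", "log_frequency", "aoa",
             "phon_neighborhood", "n_phonemes")
  fit <- fit_ols(d, preds)
  X <- cbind(1, as.matrix(d[, preds]))
  beta_hat <- solve(t(X) %*% X, t(X) %*% d$mafi)
  expect_equal(fit$coefficients$beta, as.numeric(beta_hat),
               tolerance = 1e-8)
  # Gaussian log-likelihood against the closed form
  res <- d$mafi - X %*% beta_hat
  n <- nrow(X)
  ll <- -n / 2 * (log(2 * pi) + log(sum(res^2) / n) + 1)
  expect_equal(fit$log_likelihood, ll, tolerance = 1e-8)
  expect_equal(fit$n, n)
  expect_gte(fit$r_squared, 0); expect_lte(fit$r_squared, 1)
})

test_that("degenerate fits are caught", {
  d <- make_design(20L)
  # response equal to a predictor: perfect fit
  d$load_copy <- d$mafi
  # lm warns that the fit is perfect; that is the point of the check
  fit <- suppressWarnings(fit_ols(d, "load_copy"))
  expect_equal(fit$coefficients$beta[2L], 1, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  # intercept-only model on a centered response
  d$centered <- d$mafi - mean(d$mafi)
  fit0 <- fit_ols(d, character(0L), response = "centered")
  expect_equal(fit0$coefficients$beta, 0, tolerance = 1e-10)
  # collinear columns are named
  d$dup <- d$n_phonemes
  expect_error(fit_ols(d, c("n_phonemes", "dup")), "collinear")
  expect_error(fit_ols(d[1:3, ], c("frontness", "roundness", "aoa")),
               "more observations")
})

test_that("likelihood-ratio comparison agrees with lmtest::lrtest", {
  d <- make_design()
  base_preds <- c("log_frequency", "aoa", "phon_neighborhood", "n_phonemes")
  full_preds <- c("frontness", "roundness", base_preds)
  b <- fit_ols(d, base_preds)
  t_ <- fit_ols(d, full_preds)
  cmp <- compare_models(b, t_)
  expect_equal(cmp$df, 2L)
  expect_gte(cmp$chi2, 0)
  ref <- lmtest::lrtest(b$fit, t_$fit)
  expect_equal(cmp$chi2, ref$Chisq[2L], tolerance = 1e-8)
  expect_equal(cmp$p, ref$`Pr(>Chisq)`[2L], tolerance = 1e-8)
  # identical models compare as no improvement
  same <- compare_models(b, b)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  expect_error(compare_models(t_, b), "not nested")
})

test_that("injected frontness/roundness effects are recovered within 2 SE", {
  withr::with_seed(500L, {
    n <- 500L
    plex <- simulate_lexicon(n, ft, seed = 501L)
    prof <- word_profiles(plex$word, plex, ft)
    a_true <- 0.5; b_true <- 0.3
    y <- a_true * prof$has_frontness + b_true * prof$has_roundness +
      rnorm(nrow(prof), sd = 0.25)
    norms <- tibble::tibble(word = prof$word, mafi = y)
    cov <- synth_covariates(prof, plex, seed = 502L)
    d <- prepare_design(norms, prof, cov)
    fit <- fit_ols(d, c("frontness", "roundness", "log_frequency", "aoa",
                        "phon_neighborhood", "n_phonemes"))
    co <- fit$coefficients
    expect_lt(abs(co$beta[co$term == "frontness"] - a_true),
              2 * co$se[co$term == "frontness"])
    expect_lt(abs(co$beta[co$term == "roundness"] - b_true),
              2 * co$se[co$term == "roundness"])
  })
})

test_that("norm correlations and their Fisher-z interval are correct", {
  a <- tibble::tibble(word = letters[1:10], mafi = -(1:10) / 10)
  expect_equal(correlate_norms(a, a)$r, 1)
  neg <- dplyr::mutate(a, mafi = -mafi)
  expect_equal(correlate_norms(a, neg)$r, -1)
  expect_error(correlate_norms(a[1:2, ], a[1:2, ]), "at least 3")
  withr::with_seed(9L, {
    b <- dplyr::mutate(a, mafi = mafi + rnorm(10, sd = 0.2))
    ct <- correlate_norms(a, b)
    z <- atanh(ct$r)
    ci <- tanh(z + c(-1, 1) * qnorm(0.975) / sqrt(ct$n - 3))
    expect_equal(ct$ci95, ci, tolerance = 1e-8)
    expect_equal(ct$p,
                 cor.test(a$mafi, b$mafi)$p.value, tolerance = 1e-10)
  })
})

test_that("one-edit neighborhood counts match a direct check", {
  nd <- neighborhood_density(c("bat", "moon"), lex, ft)
  # bat /bæt/ neighbors in the bundled lexicon: pat, cat, mat (+ any others
  # exactly one segment edit away) -- verify against a brute-force count
  trs <- lapply(lex$word, transcribe, lexicon = lex, table = ft)
  direct <- function(w) {
    t0 <- transcribe(w, lex, ft)
    sum(vapply(seq_along(trs), function(i) {
      lex$word[i] != w &&
        bf_levenshtein(t0$segments, trs[[i]]$segments) == 1L
    }, logical(1L)))
  }
  expect_equal(nd, c(direct("bat"), direct("moon")))
  expect_gte(nd[1L], 3L)
})
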