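#' Build a regression design table from norms, profiles and covariates
#'
#' Joins per-word MaFI norms, saliency profiles and lexical covariates on
#' `word`, dummy-codes the logical saliency indicators to 0/1 (so
#' coefficients compare words with a feature to words without it) and
#' standardizes the continuous lexical covariates to mean 0, SD 1. Words
#' missing any covariate are dropped listwise and reported via the
#' `"dropped"` attribute.
#'
#' @param norms Norms tibble (see [aggregate_norms()]).
#' @param profiles Profiles tibble (see [word_profiles()]).
#' @param covariates Tibble or CSV path with columns `word`,
#'   `log_frequency`, `aoa`, `phon_neighborhood`, `n_phonemes`.
#' @return A tibble with `word`, `mafi`, dummy-coded feature columns
#'   (`frontness`, `roundness`, `lower_lip_tuck`, `protrusion`,
#'   `labial_closure`, `lip_rounding`), loads (`load_phoneme`,
#'   `load_viseme`) and scaled covariates (`log_frequency`, `aoa`,
#'   `phon_neighborhood`, `n_phonemes`). Attribute `"dropped"` lists words
#'   excluded for missing covariates.
#' @export
prepare_design <- function(norms, profiles, covariates) {
  if (is.character(covariates)) {
    covariates <- tibble::as_tibble(
      utils::read.csv(covariates, fileEncoding = "UTF-8"))
  }
  need <- c("word", "log_frequency", "aoa", "phon_neighborhood", "n_phonemes")
  miss <- setdiff(need, names(covariates))
  if (length(miss) > 0L) {
    stop("covariates missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  prof <- profiles[, setdiff(names(profiles), "n_phonemes")]
  d <- dplyr::inner_join(norms[, c("word", "mafi")], prof, by = "word")
  d <- dplyr::inner_join(d, covariates[, need], by = "word")
  if (nrow(d) == 0L) {
    stop("no words shared between norms, profiles and covariates",
         call. = FALSE)
  }
  cont <- c("log_frequency", "aoa", "phon_neighborhood", "n_phonemes")
  complete <- stats::complete.cases(d[, cont])
  dropped <- d$word[!complete]
  d <- d[complete, ]
  if (length(dropped) > 0L) {
    message(length(dropped), " word(s) dropped for missing covariates")
  }
  for (cn in cont) {
    s <- stats::sd(d[[cn]])
    if (!is.finite(s) || s == 0) {
      stop("covariate has zero variance, cannot scale: ", cn, call. = FALSE)
    }
    d[[cn]] <- as.numeric(scale(d[[cn]]))
  }
  dummies <- c(frontness = "has_frontness", roundness = "has_roundness",
               lower_lip_tuck = "has_lower_lip_tuck",
               protrusion = "has_protrusion",
               labial_closure = "has_labial_closure",
               lip_rounding = "has_lip_rounding")
  for (nm in names(dummies)) d[[nm]] <- as.integer(d[[dummies[nm]]])
  d <- d[, c("word", "mafi", names(dummies), "load_phoneme", "load_viseme",
             cont)]
  attr(d, "dropped") <- dropped
  d
}

#' Fit an OLS regression of MaFI on a predictor set
#'
#' Ordinary least squares via [stats::lm()], packaged with the quantities
#' used downstream: the coefficient table (estimate, SE, t, two-sided p),
#' multiple R-squared, Gaussian log-likelihood and n. Feature analyses fit
#' a baseline model with lexical covariates only and a target model adding
#' saliency predictors, compared by [compare_models()].
#'
#' @param design Design tibble from [prepare_design()].
#' @param predictors Character vector of design column names.
#' @param response Response column name (default `"mafi"`).
#' @return An object of class `mafi_fit`: list with `coefficients` (tibble:
#'   term, beta, se, t, p), `r_squared`, `log_likelihood`, `n`,
#'   `predictors`, and the underlying `lm` object as `fit`.
#' @export
fit_ols <- function(design, predictors, response = "mafi") {
  miss <- setdiff(c(response, predictors), names(design))
  if (length(miss) > 0L) {
    stop("design lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(design) <= length(predictors) + 1L) {
    stop("need more observations than predictors", call. = FALSE)
  }
  rhs <- if (length(predictors) == 0L) "1" else
    paste(sprintf("`%s`", predictors), collapse = " + ")
  fml <- stats::as.formula(paste(sprintf("`%s`", response), "~", rhs))
  fit <- stats::lm(fml, data = design)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)
  ct <- sm$coefficients
  structure(list(
    coefficients = tibble::tibble(term = rownames(ct),
                                  beta = unname(ct[, 1L]),
                                  se = unname(ct[, 2L]),
                                  t = unname(ct[, 3L]),
                                  p = unname(ct[, 4L])),
    r_squared = sm$r.squared,
    log_likelihood = as.numeric(stats::logLik(fit)),
    n = stats::nobs(fit),
    predictors = predictors,
    response = response,
    fit = fit), class = "mafi_fit")
}

#' @export
print.mafi_fit <- function(x, ...) {
  cat(sprintf("OLS fit: %s ~ %s\n", x$response,
              if (length(x$predictors) == 0L) "1" else
                paste(x$predictors, collapse = " + ")))
  cat(sprintf("n = %d, R-squared = %.3f, logLik = %.2f\n",
              x$n, x$r_squared, x$log_likelihood))
  print(as.data.frame(x$coefficients), digits = 3L)
  invisible(x)
}

#' Likelihood-ratio comparison of nested OLS models
#'
#' Compares a baseline fit (lexical covariates only) with a target fit that
#' adds predictors, using the Gaussian log-likelihood ratio statistic
#' 2 (LL_target - LL_baseline) referred to a chi-square distribution with
#' degrees of freedom equal to the number of added predictors -- the same
#' comparison `anova()` performs on nested `lm` fits with a likelihood-ratio
#' test. A significant improvement indicates that saliency features predict
#' MaFI beyond lexical variables.
#'
#' @param baseline,target `mafi_fit` objects on identical rows;
#'   `baseline$predictors` must be a subset of `target$predictors`.
#' @return List with `chi2`, `df` and `p`.
#' @export
compare_models <- function(baseline, target) {
  stopifnot(inherits(baseline, "mafi_fit"), inherits(target, "mafi_fit"))
  if (baseline$n != target$n) {
    stop("models were fitted on different numbers of rows", call. = FALSE)
  }
  if (!all(baseline$predictors %in% target$predictors)) {
    stop("models are not nested: baseline predictors must be a subset ",
         "of target predictors", call. = FALSE)
  }
  df <- length(target$predictors) - length(baseline$predictors)
  chi2 <- max(0, 2 * (target$log_likelihood - baseline$log_likelihood))
  p <- if (df == 0L) 1 else stats::pchisq(chi2, df = df, lower.tail = FALSE)
  list(chi2 = chi2, df = df, p = p)
}

#' Pearson correlation between two norm sets
#'
#' Correlates the MaFI scores of the words shared by two norm tables (e.g.
#' norms from speakers or perceivers of two English variants), with the
#' two-sided test and Fisher-z 95% confidence interval.
#'
#' @param norms_a,norms_b Norms tibbles with columns `word` and `mafi`.
#' @return List with `r`, `n` (shared words), `ci95` (length-2 vector) and
#'   `p`.
#' @export
correlate_norms <- function(norms_a, norms_b) {
  m <- dplyr::inner_join(norms_a[, c("word", "mafi")],
                         norms_b[, c("word", "mafi")],
                         by = "word", suffix = c("_a", "_b"))
  if (nrow(m) < 3L) {
    stop("need at least 3 shared words to correlate (got ", nrow(m), ")",
         call. = FALSE)
  }
  ct <- stats::cor.test(m$mafi_a, m$mafi_b, method = "pearson")
  list(r = unname(ct$estimate), n = nrow(m),
       ci95 = as.numeric(ct$conf.int), p = ct$p.value)
}

#' One-edit phonological neighborhood counts
#'
#' Helper for building synthetic covariates: counts, for each word, the
#' lexicon entries whose transcription is exactly one segment edit away
#' (substitution, insertion or deletion). Real analyses should supply
#' published neighborhood-density norms instead.
#'
#' @param words Character vector of orthographic words (all in the lexicon).
#' @param lexicon Lexicon tibble from [load_lexicon()].
#' @param table A `feature_table`.
#' @return Integer vector of neighbor counts, one per word.
#' @export
neighborhood_density <- function(words, lexicon, table) {
  trs <- lapply(lexicon$word, function(w) transcribe(w, lexicon, table))
  names(trs) <- lexicon$word
  vapply(tolower(words), function(w) {
    t0 <- trs[[w]]
    if (is.null(t0)) stop("word not in lexicon: ", dQuote(w), call. = FALSE)
    sum(vapply(lexicon$word, function(other) {
      other != w && levenshtein_distance(t0, trs[[other]]) == 1L
    }, logical(1L)))
  }, integer(1L), USE.NAMES = FALSE)
}
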