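# Builds inst/extdata fixture files: articulatory feature table + weights.
# Run from repo root: Rscript scratch/build_fixtures.R
features <- c("syl", "son", "cons", "cont", "delrel", "lat", "nas", "strid",
              "voi", "sg", "cg", "ant", "cor", "distr", "lab", "hi", "lo",
              "back", "round", "tense", "long")

weights <- c(syl = 1, son = 1, cons = 1, cont = 0.5, delrel = 0.5, lat = 0.5,
             nas = 0.5, strid = 0.25, voi = 0.125, sg = 0.125, cg = 0.125,
             ant = 0.25, cor = 0.25, distr = 0.125, lab = 0.25, hi = 0.25,
             lo = 0.25, back = 0.25, round = 0.25, tense = 0.25, long = 0.25)
stopifnot(identical(names(weights), features))

cons_base <- c(syl = -1, son = -1, cons = +1, cont = -1, delrel = -1, lat = -1,
               nas = -1, strid = -1, voi = -1, sg = -1, cg = -1, ant = -1,
               cor = -1, distr = -1, lab = -1, hi = -1, lo = -1, back = -1,
               round = -1, tense = 0, long = -1)
vowel_base <- c(syl = +1, son = +1, cons = -1, cont = +1, delrel = -1, lat = -1,
                nas = -1, strid = -1, voi = +1, sg = -1, cg = -1, ant = 0,
                cor = -1, distr = 0, lab = -1, hi = -1, lo = -1, back = -1,
                round = -1, tense = -1, long = -1)

seg <- function(base, ...) {
  ov <- c(...)
  v <- base
  v[names(ov)] <- ov
  v
}

C <- cons_base
V <- vowel_base
segments <- list(
  "p"  = seg(C, ant = 1, lab = 1),
  "b"  = seg(C, ant = 1, lab = 1, voi = 1),
  "t"  = seg(C, ant = 1, cor = 1),
  "d"  = seg(C, ant = 1, cor = 1, voi = 1),
  "k"  = seg(C, hi = 1, back = 1),
  "ɡ" = seg(C, hi = 1, back = 1, voi = 1),  # ɡ (IPA)
  "g"  = seg(C, hi = 1, back = 1, voi = 1),      # ASCII g, same sound
  "m"  = seg(C, son = 1, nas = 1, voi = 1, ant = 1, lab = 1),
  "n"  = seg(C, son = 1, nas = 1, voi = 1, ant = 1, cor = 1),
  "ŋ" = seg(C, son = 1, nas = 1, voi = 1, hi = 1, back = 1), # ŋ
  "f"  = seg(C, cont = 1, strid = 1, ant = 1, lab = 1),
  "v"  = seg(C, cont = 1, strid = 1, ant = 1, lab = 1, voi = 1),
  "θ" = seg(C, cont = 1, ant = 1, cor = 1, distr = 1),          # θ
  "ð" = seg(C, cont = 1, ant = 1, cor = 1, distr = 1, voi = 1), # ð
  "s"  = seg(C, cont = 1, strid = 1, ant = 1, cor = 1),
  "z"  = seg(C, cont = 1, strid = 1, ant = 1, cor = 1, voi = 1),
  "ʃ" = seg(C, cont = 1, strid = 1, cor = 1, distr = 1, hi = 1),          # ʃ
  "ʒ" = seg(C, cont = 1, strid = 1, cor = 1, distr = 1, hi = 1, voi = 1), # ʒ
  "tʃ" = seg(C, delrel = 1, strid = 1, cor = 1, distr = 1, hi = 1),           # tʃ
  "dʒ" = seg(C, delrel = 1, strid = 1, cor = 1, distr = 1, hi = 1, voi = 1),  # dʒ
  "h"  = seg(C, cons = -1, cont = 1, sg = 1),
  "l"  = seg(C, son = 1, cont = 1, lat = 1, voi = 1, ant = 1, cor = 1),
  "r"  = seg(C, son = 1, cont = 1, voi = 1, ant = 1, cor = 1),
  "ɹ" = seg(C, son = 1, cont = 1, voi = 1, ant = 1, cor = 1),   # ɹ
  "w"  = seg(C, cons = -1, son = 1, cont = 1, voi = 1, lab = 1, hi = 1,
             back = 1, round = 1),
  "j"  = seg(C, cons = -1, son = 1, cont = 1, voi = 1, hi = 1),
  "i"  = seg(V, hi = 1, tense = 1),
  "ɪ" = seg(V, hi = 1),                                    # ɪ
  "e"  = seg(V, tense = 1),
  "ɛ" = seg(V),                                            # ɛ
  "æ" = seg(V, lo = 1),                                    # æ
  "a"  = seg(V, lo = 1),
  "ʌ" = seg(V, back = 1),                                  # ʌ
  "ə" = seg(V),                                            # ə
  "ɜ" = seg(V),                                            # ɜ
  "ɑ" = seg(V, lo = 1, back = 1),                          # ɑ
  "ɒ" = seg(V, lo = 1, back = 1, round = 1, lab = 1),      # ɒ
  "ɔ" = seg(V, back = 1, round = 1, lab = 1),              # ɔ
  "o"  = seg(V, back = 1, round = 1, lab = 1, tense = 1),
  "ʊ" = seg(V, hi = 1, back = 1, round = 1, lab = 1),      # ʊ
  "u"  = seg(V, hi = 1, back = 1, round = 1, lab = 1, tense = 1)
)

# length-marked vowels: base vector with long = +1
long_of <- c("i", "u", "ɔ", "ɑ", "ɜ", "a", "e", "o",
             "ɛ", "æ")
for (b in long_of) {
  segments[[paste0(b, "ː")]] <- seg(segments[[b]], long = 1)
}
# diphthongs as single table entries: nucleus features, long = +1
diph <- c("eɪ" = "e", "aɪ" = "a", "ɔɪ" = "ɔ",
          "aʊ" = "a", "əʊ" = "ə", "oʊ" = "o")
for (d in names(diph)) {
  segments[[d]] <- seg(segments[[diph[[d]]]], long = 1)
}

M <- do.call(rbind, segments)
stopifnot(ncol(M) == length(features))

# sanity: the two worked examples
cost <- function(a, b) sum(weights * abs(M[a, ] - M[b, ]))
stopifnot(isTRUE(all.equal(cost("b", "p"), 0.25)))
stopifnot(isTRUE(all.equal(cost("b", "k"), 2.25)))

sym <- c("-1" = "-", "0" = "0", "1" = "+")
tab <- data.frame(ipa = rownames(M),
                  matrix(sym[as.character(M)], nrow = nrow(M)),
                  check.names = FALSE)
names(tab) <- c("ipa", features)
con <- file("inst/extdata/english_features.csv", open = "w", encoding = "UTF-8")
write.csv(tab, con, row.names = FALSE, quote = FALSE)
close(con)

wt <- data.frame(feature = names(weights), weight = unname(weights))
con <- file("inst/extdata/feature_weights.csv", open = "w", encoding = "UTF-8")
write.csv(wt, con, row.names = FALSE, quote = FALSE)
close(con)
cat("wrote", nrow(tab), "segments,", nrow(wt), "weights\n")
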