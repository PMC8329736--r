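test_that("the three worked examples score 6, 3 and 0", {
  s <- score_vocalization(parse_transcription("e.le.ˈfant"))
  expect_equal(s$total, 6L)
  expect_equal(s$breakdown[["polysyllabic"]], 1L)
  expect_equal(s$breakdown[["non-initial-stress"]], 1L)
  expect_equal(s$breakdown[["word-final-consonant"]], 1L)
  expect_equal(s$breakdown[["consonant-cluster"]], 1L)
  expect_equal(s$breakdown[["liquid"]], 1L)
  expect_equal(s$breakdown[["fricative"]], 1L)
  expect_equal(sum(s$breakdown), s$total)

  s <- score_vocalization(parse_transcription("ˈsku:"))
  expect_equal(s$total, 3L)
  expect_equal(s$breakdown[["consonant-cluster"]], 1L)
  expect_equal(s$breakdown[["velar"]], 1L)
  expect_equal(s$breakdown[["fricative"]], 1L)

  expect_equal(score_vocalization(parse_transcription("màma"))$total, 0L)
})

test_that("trills, long front rounded vowels and final consonants combine", {
  s <- score_vocalization(parse_transcription("ˈrøːd"))
  expect_equal(s$total, 5L)
  expect_equal(s$breakdown[["trill"]], 3L)
  expect_equal(s$breakdown[["long-front-rounded-vowel"]], 1L)
  expect_equal(s$breakdown[["word-final-consonant"]], 1L)
  # trill points always divisible by 3
  expect_equal(score_vocalization(parse_transcription("ra.ra"))$breakdown[["trill"]], 6L)
})

test_that("score is invariant to the stress-notation variant", {
  pairs <- list(c("màma", "ˈma.ma"), c("mamá", "ma.ˈma"),
                c("ele'fant", "e.le.ˈfant"))
  for (p in pairs) {
    expect_equal(score_vocalization(parse_transcription(p[1]))$breakdown,
                 score_vocalization(parse_transcription(p[2]))$breakdown)
  }
})

test_that("cover symbols score conservatively", {
  # C counts for structure (final consonant, clusters) but earns no classes
  s <- score_vocalization(parse_transcription("maC"))
  expect_equal(s$total, 1L)
  s <- score_vocalization(parse_transcription("aCka"))
  expect_equal(s$breakdown[["consonant-cluster"]], 1L)
  # the indeterminate square breaks a consonant run and earns nothing
  s <- score_vocalization(parse_transcription("ak□ka"))
  expect_equal(s$breakdown[["consonant-cluster"]], 0L)
  expect_equal(s$total, 2L)  # two velars only
})

test_that("cluster counting follows the configured scope", {
  v <- parse_transcription("mam.pa")  # heterosyllabic m.p run
  expect_equal(score_vocalization(v)$breakdown[["consonant-cluster"]], 1L)
  expect_equal(score_vocalization(v, cluster_scope = "syllable")$breakdown[["consonant-cluster"]],
               0L)
  # a maximal run counts once regardless of length
  expect_equal(score_vocalization(parse_transcription("a.mpst"))$breakdown[["consonant-cluster"]],
               1L)
})

test_that("sound-class points are additive under concatenation, word points are not", {
  withr::local_seed(99)
  class_params <- c("velar", "liquid", "fricative", "voiced-fricative",
                    "trill", "long-front-rounded-vowel")
  for (i in 1:40) {
    a <- random_transcription(); b <- random_transcription()
    sa <- score_vocalization(parse_transcription(a))$breakdown
    sb <- score_vocalization(parse_transcription(b))$breakdown
    joined <- parse_transcription(paste(gsub("ˈ", "", a), gsub("ˈ", "", b), sep = "."))
    sj <- score_vocalization(joined)$breakdown
    expect_equal(sj[class_params], sa[class_params] + sb[class_params])
  }
  # word-final-consonant is a property of the whole vocalization
  one <- score_vocalization(parse_transcription("mat"))$breakdown
  two <- score_vocalization(parse_transcription("mat.ma"))$breakdown
  expect_equal(one[["word-final-consonant"]], 1L)
  expect_equal(two[["word-final-consonant"]], 0L)
})

test_that("appending a trill syllable raises the total by exactly 3", {
  withr::local_seed(123)
  for (i in 1:30) {
    s <- gsub("ˈ", "", random_transcription())
    base <- score_vocalization(parse_transcription(s))
    ext <- score_vocalization(parse_transcription(paste0(s, ".ra")))
    # the appended open syllable never adds structure points beyond the
    # possible loss of a previous word-final consonant and possible
    # polysyllabicity gain; sound classes must rise by the trill alone
    class_params <- c("velar", "liquid", "fricative", "voiced-fricative",
                      "trill", "long-front-rounded-vowel")
    expect_equal(sum(ext$breakdown[class_params]),
                 sum(base$breakdown[class_params]) + 3L)
  }
})

test_that("scorer matches an independent flat recount on generated corpora", {
  withr::local_seed(2024)
  for (i in 1:300) {
    v <- parse_transcription(random_transcription())
    expect_equal(score_vocalization(v)$total, oracle_wcm_flat(format(v)),
                 info = format(v))
  }
})

test_that("score_corpus preserves order, handles strings and empties", {
  res <- score_corpus(c("e.le.ˈfant", "ˈsku:", "màma"))
  expect_equal(res$total, c(6L, 3L, 0L))
  expect_equal(nrow(score_corpus(character(0))), 0)
  expect_equal(score_corpus(rep("ˈma.ma", 100))$total, rep(0L, 100))
  # list-of-vocalization input agrees with string input
  vocs <- lapply(c("ˈrøːd", "màma"), parse_transcription)
  expect_equal(score_corpus(vocs)$total, c(5L, 0L))
})

test_that("subject means are plain arithmetic with guarded edge cases", {
  expect_equal(subject_mean("s1", c(6, 3, 0))$mean_score, 3)
  expect_equal(subject_mean("s1", c(0, 0))$mean_score, 0)
  expect_equal(subject_mean("s1", c(2, 1, 1, 1))$mean_score, 1.25)
  expect_error(subject_mean("s1", numeric(0)), "no scores")
  tab <- subject_wcm_table(tibble::tibble(
    subject_id = c("a", "a", "b"),
    transcription = c("e.le.ˈfant", "màma", "ˈsku:")))
  expect_equal(tab$mean_score[tab$subject_id == "a"], 3)
  expect_equal(tab$n_vocalizations, c(2L, 1L))
})
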