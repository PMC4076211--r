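test_that("the demo sentences reduce to 18 content tokens with the stated lemmas", {
  scored <- filter_and_lemmatize(demo_sentences())
  expect_identical(nrow(scored), 18L)
  expect_identical(
    scored$surface,
    c("sunny", "day", "friendly", "child", "travelled", "green", "yard",
      "suddenly", "heard", "frightening", "voice", "noticed", "vicious",
      "looking", "violent", "dog", "barking", "fence"))
  lem <- setNames(scored$lemma, scored$surface)
  expect_identical(unname(lem["travelled"]), "travel")
  expect_identical(unname(lem["heard"]), "hear")
  expect_identical(unname(lem["frightening"]), "frighten")
  expect_identical(unname(lem["barking"]), "bark")
  expect_true(all(scored$pos_tag %in%
                    c("noun", "verb", "adjective", "adverb")))
})

test_that("stopword-and-punctuation text retains nothing", {
  scored <- filter_and_lemmatize("and the, of!")
  expect_identical(nrow(scored), 0L)
})

test_that("lemmatisation is idempotent on base forms", {
  base <- c("travel", "hear", "frighten", "bark", "dog", "sunny")
  expect_identical(default_lemmatizer(base), base)
})

test_that("a failing tagger passes tokens through with a warning", {
  bad_tagger <- function(tokens) stop("boom")
  expect_warning(scored <- filter_and_lemmatize("sunny day", bad_tagger),
                 "tagger failed")
  expect_identical(nrow(scored), 2L)
})

test_that("semantic distance is the cosine of the model rows", {
  probs <- rbind(w1 = c(1, 1, 0), w2 = c(1, 0, 1), w3 = c(2, 2, 0),
                 w4 = c(0, 0, 1)) / 10
  m <- operand:::new_cooccurrence_model(probs, rownames(probs),
                                        c("c1", "c2", "c3"))
  expect_equal(semantic_distance("w1", "w2", m), 0.5)
  expect_equal(semantic_distance("w1", "w3", m), 1.0)
  expect_equal(semantic_distance("w1", "w4", m), 0.0)
  expect_error(semantic_distance("w1", "nope", m), "out-of-vocabulary")
})

test_that("semantic orientation is antisymmetric under paradigm swap", {
  toy <- make_toy_corpus(seed = 5)
  swapped <- paradigm_sets(toy$paradigms$negatives, toy$paradigms$positives)
  for (w in names(toy$labels)[1:4]) {
    expect_equal(semantic_orientation(w, toy$paradigms, toy$model),
                 -semantic_orientation(w, swapped, toy$model))
  }
})

test_that("semantic orientation is invariant to row rescaling", {
  toy <- make_toy_corpus(seed = 6)
  w <- names(toy$labels)[[1]]
  so1 <- semantic_orientation(w, toy$paradigms, toy$model)
  scaled <- toy$model
  scaled$probs[w, ] <- scaled$probs[w, ] * 7
  so2 <- semantic_orientation(w, toy$paradigms, scaled)
  expect_equal(so1, so2)
})

test_that("planted toy-corpus words get the correct orientation sign", {
  for (seed in c(1, 2, 3)) {
    toy <- make_toy_corpus(n_pos_words = 5, n_neg_words = 5, seed = seed)
    so <- sapply(names(toy$labels), semantic_orientation,
                 paradigms = toy$paradigms, model = toy$model)
    expect_true(all(sign(so) == toy$labels),
                info = paste("seed", seed))
  }
})

test_that("missing paradigm words are excluded with a warning", {
  toy <- make_toy_corpus(seed = 7)
  pars <- paradigm_sets(c(toy$paradigms$positives, "zzzunseen"),
                        toy$paradigms$negatives)
  expect_warning(
    so <- semantic_orientation(names(toy$labels)[[1]], pars, toy$model),
    "out of vocabulary")
  expect_true(is.finite(so))
})

test_that("text_to_series scores tokens in order with the demo model", {
  demo <- make_demo_polarity_model()
  series <- text_to_series(demo_sentences(), demo$paradigms, demo$model)
  expect_length(series, 18L)
  toks <- attr(series, "tokens")
  expect_identical(attr(series, "n_oov"), 0L)
  ord <- order(as.numeric(series), decreasing = TRUE)
  expect_setequal(toks$lemma[ord[1:2]], c("travel", "sunny"))
  ord_neg <- order(as.numeric(series))
  expect_setequal(toks$lemma[ord_neg[1:2]], c("vicious", "violent"))
})

test_that("single retained word yields a length-1 series of its SO", {
  demo <- make_demo_polarity_model()
  series <- text_to_series("the dog", demo$paradigms, demo$model)
  expect_length(series, 1L)
  expect_equal(as.numeric(series),
               semantic_orientation("dog", demo$paradigms, demo$model))
})

test_that("out-of-vocabulary tokens score zero or are dropped", {
  demo <- make_demo_polarity_model()
  txt <- "sunny zyzzyva dog"
  z <- text_to_series(txt, demo$paradigms, demo$model, oov = "zero")
  expect_length(z, 3L)
  expect_identical(attr(z, "n_oov"), 1L)
  expect_equal(as.numeric(z)[2], 0)
  d <- text_to_series(txt, demo$paradigms, demo$model, oov = "drop")
  expect_length(d, 2L)
})

test_that("series length equals retained-token count on toy corpora", {
  toy <- make_toy_corpus(seed = 9)
  txt <- paste(toy$corpus[1:3], collapse = " ")
  scored <- filter_and_lemmatize(txt)
  series <- text_to_series(txt, toy$paradigms, toy$model)
  expect_length(series, nrow(scored))
})

test_that("paradigm sets must be disjoint and non-empty", {
  expect_error(paradigm_sets(character(0), "bad"), "non-empty")
  expect_error(paradigm_sets(c("good", "bad"), c("bad")), "disjoint")
})

test_that("co-occurrence model TSV round-trips", {
  toy <- make_toy_corpus(seed = 10)
  path <- tempfile(fileext = ".tsv")
  write_cooccurrence_tsv(toy$model, path)
  back <- read_cooccurrence_tsv(path)
  expect_setequal(back$row_words, toy$model$row_words)
  w <- names(toy$labels)[[1]]
  expect_equal(semantic_orientation(w, toy$paradigms, back),
               semantic_orientation(w, toy$paradigms, toy$model))
})

test_that("co-occurrence counts respect the context window", {
  toks <- c("a", "b", "c", "d")
  m1 <- build_cooccurrence_model(toks, k = 1)
  # with k = 1 only adjacent pairs co-occur: (a,b),(b,c),(c,d) x2 directions
  expect_equal(sum(m1$probs > 0), 6L)
  expect_equal(sum(m1$probs), 1)
  m2 <- build_cooccurrence_model(toks, k = 3)
  expect_gt(sum(m2$probs > 0), 6L)
})
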