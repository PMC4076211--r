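# Text -> emotional-polarity series front end: POS filtering,
# lemmatisation, and semantic orientation against paradigm word sets.

closed_class_words <- c(
  # determiners / pronouns
  "a", "an", "the", "this", "that", "these", "those", "it", "its", "he",
  "she", "him", "her", "his", "hers", "they", "them", "their", "theirs",
  "i", "me", "my", "mine", "we", "us", "our", "ours", "you", "your",
  "yours", "who", "whom", "whose", "which", "what", "some", "any", "no",
  "every", "each", "either", "neither", "both", "all", "such",
  # conjunctions / complementisers
  "and", "or", "but", "nor", "so", "yet", "if", "because", "although",
  "while", "whereas", "than", "whether", "that",
  # prepositions
  "in", "on", "at", "by", "for", "with", "without", "about", "against",
  "between", "into", "through", "during", "before", "after", "above",
  "below", "to", "from", "up", "down", "of", "off", "over", "under",
  "behind", "beside", "near", "across", "along", "around", "upon",
  # auxiliaries / copulas / modals
  "is", "am", "are", "was", "were", "be", "been", "being", "do", "does",
  "did", "have", "has", "had", "will", "would", "shall", "should", "can",
  "could", "may", "might", "must",
  # misc function words
  "not", "as", "there", "here", "then", "when", "where", "why", "how",
  "also", "too", "very", "just", "only", "even", "still"
)

# adjectives in -ly that the suffix rule would otherwise tag as adverbs
ly_adjectives <- c("friendly", "lovely", "lonely", "ugly", "early",
                   "silly", "deadly", "likely", "unlikely", "daily",
                   "weekly", "monthly", "yearly", "elderly", "costly")

adjective_suffixes <- c("ous", "ful", "less", "ish", "ive", "able",
                        "ible", "al", "ic", "ent", "ant")

#' Tokenise raw text into lowercase word tokens
#'
#' Splits on anything that is not a letter or an internal apostrophe;
#' punctuation and digits are dropped.
#'
#' @param text a character scalar (UTF-8).
#' @return character vector of lowercase tokens in text order.
#' @export
tokenize_text <- function(text) {
  stopifnot(is.character(text))
  text <- tolower(paste(text, collapse = " "))
  toks <- regmatches(text, gregexpr("[a-z]+(?:'[a-z]+)*", text))[[1L]]
  toks
}

#' Rule-based part-of-speech tagger (bundled default)
#'
#' A deliberately small tagger sufficient for the bundled pipeline:
#' closed-class function words are tagged `other`; remaining open-class
#' tokens are tagged by suffix — `-ly` adverbs (with a short
#' adjective exception list), `-ing`/`-ed` verbs, common adjective
#' suffixes, everything else `noun`. Any function mapping a character
#' vector of tokens to a same-length character vector of tags drawn from
#' `noun`, `verb`, `adjective`, `adverb`, `other` can be used in its
#' place.
#'
#' @param tokens character vector of lowercase tokens.
#' @return character vector of tags.
#' @export
default_tagger <- function(tokens) {
  vapply(tokens, function(tk) {
    if (tk %in% closed_class_words) return("other")
    if (tk %in% ly_adjectives) return("adjective")
    if (endsWith(tk, "ly") && nchar(tk) > 3L) return("adverb")
    if (endsWith(tk, "ing") && nchar(tk) > 4L) return("verb")
    if (endsWith(tk, "ed") && nchar(tk) > 3L) return("verb")
    for (sfx in adjective_suffixes) {
      if (endsWith(tk, sfx) && nchar(tk) > nchar(sfx) + 1L) {
        return("adjective")
      }
    }
    if (endsWith(tk, "y") && nchar(tk) > 3L) return("adjective")
    "noun"
  }, character(1), USE.NAMES = FALSE)
}

irregular_lemmas <- c(
  heard = "hear", said = "say", went = "go", gone = "go", saw = "see",
  seen = "see", came = "come", told = "tell", took = "take",
  taken = "take", gave = "give", given = "give", made = "make",
  found = "find", thought = "think", felt = "feel", knew = "know",
  known = "know", left = "leave", kept = "keep", got = "get",
  men = "man", women = "woman", children = "child", people = "person",
  feet = "foot", teeth = "tooth", mice = "mouse", better = "good",
  best = "good", worse = "bad", worst = "bad"
)

vowels <- c("a", "e", "i", "o", "u")

strip_suffix <- function(tk, sfx) substr(tk, 1L, nchar(tk) - nchar(sfx))

# undo consonant doubling (travell -> travel) and restore a dropped -e
# after letters that commonly require it (notic -> notice)
repair_stem <- function(stem) {
  n <- nchar(stem)
  if (n >= 3L) {
    last <- substr(stem, n, n)
    prev <- substr(stem, n - 1L, n - 1L)
    # doubled final consonant: drop one (except -ss)
    if (last == prev && !(last %in% vowels) && last != "s") {
      stem <- substr(stem, 1L, n - 1L)
      n <- n - 1L
      last <- substr(stem, n, n)
    }
    if (last %in% c("c", "v", "u", "g", "z")) {
      stem <- paste0(stem, "e")
    }
  }
  stem
}

#' Rule-based English lemmatiser (bundled default)
#'
#' Strips regular inflection (`-ing`, `-ed`, plural `-s`/`-es`/`-ies`)
#' with consonant-doubling and final-e repair, plus a small table of
#' irregular forms (`heard -> hear`, ...). Pluggable: any function
#' mapping token vectors to lemma vectors can replace it.
#'
#' @param tokens character vector of lowercase tokens.
#' @return character vector of lemmas.
#' @export
default_lemmatizer <- function(tokens) {
  vapply(tokens, function(tk) {
    if (tk %in% names(irregular_lemmas)) {
      return(unname(irregular_lemmas[[tk]]))
    }
    n <- nchar(tk)
    if (endsWith(tk, "ing") && n > 5L) {
      return(repair_stem(strip_suffix(tk, "ing")))
    }
    if (endsWith(tk, "ied") && n > 4L) {
      return(paste0(strip_suffix(tk, "ied"), "y"))
    }
    if (endsWith(tk, "ed") && n > 4L) {
      return(repair_stem(strip_suffix(tk, "ed")))
    }
    if (endsWith(tk, "ies") && n > 4L) {
      return(paste0(strip_suffix(tk, "ies"), "y"))
    }
    if (endsWith(tk, "sses") && n > 5L) return(strip_suffix(tk, "es"))
    if ((endsWith(tk, "xes") || endsWith(tk, "ches") ||
         endsWith(tk, "shes")) && n > 4L) {
      return(strip_suffix(tk, "es"))
    }
    if (endsWith(tk, "s") && !endsWith(tk, "ss") && !endsWith(tk, "us") &&
        !endsWith(tk, "is") && n > 3L) {
      return(strip_suffix(tk, "s"))
    }
    tk
  }, character(1), USE.NAMES = FALSE)
}

#' Filter text to content words and lemmatise them
#'
#' Tokenises, keeps only tokens tagged noun / verb / adjective / adverb,
#' and lemmatises the survivors, preserving text order. If the tagger or
#' lemmatiser fails on a token, the token is passed through untouched
#' with a warning rather than dropped.
#'
#' @param text character scalar.
#' @param tagger function tokens -> tags (default [default_tagger()]).
#' @param lemmatizer function tokens -> lemmas
#'   (default [default_lemmatizer()]).
#' @return data frame with columns `surface`, `pos_tag`, `lemma`.
#' @export
filter_and_lemmatize <- function(text, tagger = default_tagger,
                                 lemmatizer = default_lemmatizer) {
  if (!is.character(text) || length(text) == 0L ||
      !nzchar(paste(text, collapse = ""))) {
    stop("text must be a non-empty character vector")
  }
  toks <- tokenize_text(text)
  if (length(toks) == 0L) {
    return(data.frame(surface = character(0), pos_tag = character(0),
                      lemma = character(0), stringsAsFactors = FALSE))
  }
  tags <- tryCatch(tagger(toks), error = function(e) {
    warning("tagger failed (", conditionMessage(e),
            "); passing tokens through as nouns")
    rep("noun", length(toks))
  })
  keep <- tags %in% c("noun", "verb", "adjective", "adverb")
  toks <- toks[keep]; tags <- tags[keep]
  lemmas <- tryCatch(lemmatizer(toks), error = function(e) {
    warning("lemmatizer failed (", conditionMessage(e),
            "); passing tokens through unlemmatised")
    toks
  })
  data.frame(surface = toks, pos_tag = tags, lemma = lemmas,
             stringsAsFactors = FALSE)
}

#' Build a word-context co-occurrence model from a corpus
#'
#' Counts, for every ordered word pair within a symmetric context window
#' of `k` tokens, the joint occurrence of the word and its
#' preceding/following context words, and normalises the counts to joint
#' probabilities. Rows are words, columns context words (the same
#' vocabulary unless `context_words` is given).
#'
#' @param tokens character vector of corpus tokens in order, or a list
#'   of such vectors (one per document; windows never cross documents).
#' @param k context half-width in tokens (default 2).
#' @param row_words,context_words optional vocabularies; default: all
#'   corpus types.
#' @return an object of class `cooccurrence_model`: list with `probs`
#'   (matrix), `row_words`, `context_words`.
#' @export
build_cooccurrence_model <- function(tokens, k = 2L, row_words = NULL,
                                     context_words = NULL) {
  if (!is.list(tokens)) tokens <- list(tokens)
  k <- as.integer(k)
  stopifnot(k >= 1L)
  all_types <- sort(unique(unlist(tokens)))
  if (is.null(row_words)) row_words <- all_types
  if (is.null(context_words)) context_words <- all_types
  counts <- matrix(0, length(row_words), length(context_words),
                   dimnames = list(row_words, context_words))
  for (doc in tokens) {
    n <- length(doc)
    for (i in seq_len(n)) {
      if (!(doc[[i]] %in% row_words)) next
      lo <- max(1L, i - k); hi <- min(n, i + k)
      for (j in seq.int(lo, hi)) {
        if (j == i) next
        if (doc[[j]] %in% context_words) {
          counts[doc[[i]], doc[[j]]] <- counts[doc[[i]], doc[[j]]] + 1
        }
      }
    }
  }
  total <- sum(counts)
  if (total == 0) stop("no co-occurrences found; corpus too small for k")
  new_cooccurrence_model(counts / total, row_words, context_words)
}

new_cooccurrence_model <- function(probs, row_words, context_words) {
  stopifnot(all(probs >= 0), nrow(probs) == length(row_words),
            ncol(probs) == length(context_words))
  if (sum(probs) > 1 + 1e-8) {
    stop("joint probabilities sum to more than 1")
  }
  structure(list(probs = probs, row_words = row_words,
                 context_words = context_words),
            class = "cooccurrence_model")
}

model_row <- function(model, word) {
  if (!(word %in% model$row_words)) {
    stop("out-of-vocabulary word: '", word, "'")
  }
  v <- model$probs[word, ]
  if (all(v == 0)) stop("word '", word, "' has an all-zero context row")
  v
}

#' Read / write a co-occurrence model as TSV
#'
#' Three columns: row word, context word, joint probability. Pairs not
#' listed are zero.
#'
#' @param path file path.
#' @return a `cooccurrence_model`.
#' @export
read_cooccurrence_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("word", "context", "prob"),
                          stringsAsFactors = FALSE, quote = "")
  row_words <- sort(unique(df$word))
  context_words <- sort(unique(df$context))
  probs <- matrix(0, length(row_words), length(context_words),
                  dimnames = list(row_words, context_words))
  probs[cbind(df$word, df$context)] <- df$prob
  new_cooccurrence_model(probs, row_words, context_words)
}

#' @rdname read_cooccurrence_tsv
#' @param model a `cooccurrence_model`.
#' @export
write_cooccurrence_tsv <- function(model, path) {
  idx <- which(model$probs > 0, arr.ind = TRUE)
  df <- data.frame(word = model$row_words[idx[, 1L]],
                   context = model$context_words[idx[, 2L]],
                   prob = model$probs[idx])
  df <- df[order(df$word, df$context), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Paradigm word sets anchoring the polarity scale
#'
#' Defaults to the conventional seven-plus-seven lists
#' (good, nice, excellent, positive, fortunate, correct, superior versus
#' bad, nasty, poor, negative, unfortunate, wrong, inferior).
#'
#' @param positives,negatives non-empty, disjoint character vectors.
#' @return an object of class `paradigm_sets`.
#' @export
paradigm_sets <- function(
    positives = c("good", "nice", "excellent", "positive", "fortunate",
                  "correct", "superior"),
    negatives = c("bad", "nasty", "poor", "negative", "unfortunate",
                  "wrong", "inferior")) {
  positives <- unique(tolower(positives))
  negatives <- unique(tolower(negatives))
  if (length(positives) == 0L || length(negatives) == 0L) {
    stop("both paradigm sets must be non-empty")
  }
  if (length(intersect(positives, negatives)) > 0L) {
    stop("paradigm sets must be disjoint")
  }
  structure(list(positives = positives, negatives = negatives),
            class = "paradigm_sets")
}

cosine <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine undefined for a zero vector")
  sum(u * v) / (nu * nv)
}

#' Semantic distance between two words
#'
#' The cosine of the angle between the words' context-probability row
#' vectors in the co-occurrence model.
#'
#' @param w1,w2 words (must be in the model vocabulary with nonzero rows).
#' @param model a `cooccurrence_model`.
#' @return cosine similarity in `[-1, 1]`.
#' @export
semantic_distance <- function(w1, w2, model) {
  cosine(model_row(model, w1), model_row(model, w2))
}

paradigm_sum <- function(model, words, label) {
  present <- words[words %in% model$row_words]
  present <- present[vapply(present,
                            function(w) any(model$probs[w, ] > 0),
                            logical(1))]
  if (length(present) < length(words)) {
    warning(sprintf("%d %s paradigm word(s) out of vocabulary; excluded",
                    length(words) - length(present), label))
  }
  if (length(present) == 0L) {
    stop("no ", label, " paradigm word present in the model vocabulary")
  }
  colSums(model$probs[present, , drop = FALSE])
}

#' Semantic orientation of a word
#'
#' `SO(w) = cos(v_w, sum of positive paradigm rows) -
#'  cos(v_w, sum of negative paradigm rows)`. Positive values indicate
#' association with the positive paradigm.
#'
#' @param word a word in the model vocabulary.
#' @param paradigms a [paradigm_sets()].
#' @param model a `cooccurrence_model`.
#' @return semantic-orientation score in `[-2, 2]`.
#' @export
semantic_orientation <- function(word, paradigms, model) {
  stopifnot(inherits(paradigms, "paradigm_sets"))
  v <- model_row(model, word)
  vp <- paradigm_sum(model, paradigms$positives, "positive")
  vn <- paradigm_sum(model, paradigms$negatives, "negative")
  cosine(v, vp) - cosine(v, vn)
}

#' Convert raw text to an emotional-polarity series
#'
#' Filters the text to content words, lemmatises them, and scores each
#' retained token by its lemma's semantic orientation, in text order.
#' Out-of-vocabulary lemmas score 0 by default (`oov = "zero"`,
#' preserving the alignment between series index and text position) or
#' are dropped (`oov = "drop"`).
#'
#' @param text character scalar.
#' @inheritParams semantic_orientation
#' @inheritParams filter_and_lemmatize
#' @param oov `"zero"` or `"drop"`.
#' @return numeric series, one score per retained token, with
#'   attributes `tokens` (the scored-token data frame) and `n_oov`.
#' @export
text_to_series <- function(text, paradigms, model,
                           tagger = default_tagger,
                           lemmatizer = default_lemmatizer,
                           oov = c("zero", "drop")) {
  oov <- match.arg(oov)
  scored <- filter_and_lemmatize(text, tagger, lemmatizer)
  if (nrow(scored) == 0L) {
    stop("no content tokens retained; cannot build a series")
  }
  so <- vapply(scored$lemma, function(lem) {
    tryCatch(semantic_orientation(lem, paradigms, model),
             error = function(e) NA_real_)
  }, numeric(1), USE.NAMES = FALSE)
  n_oov <- sum(is.na(so))
  if (oov == "zero") {
    so[is.na(so)] <- 0
  } else {
    scored <- scored[!is.na(so), , drop = FALSE]
    so <- so[!is.na(so)]
  }
  if (length(so) == 0L) stop("every retained token was out of vocabulary")
  scored$so_score <- so
  structure(so, tokens = scored, n_oov = n_oov)
}

#' Toy corpus with planted word polarity
#'
#' Generates short documents in which each planted positive-class word
#' co-occurs (within the model's context window) with positive paradigm
#' words, and likewise for the negative class, then builds the
#' co-occurrence model from the corpus. Ground-truth labels are
#' returned, so sign recovery of the semantic orientation is directly
#' checkable.
#'
#' @param n_pos_words,n_neg_words number of planted words per class.
#' @param docs number of generated documents (default 60).
#' @param seed integer RNG seed.
#' @param k context half-width used for the model (default 2).
#' @return list with `corpus` (character vector of documents), `model`,
#'   `paradigms`, `labels` (named +1/-1 vector over planted words).
#' @export
make_toy_corpus <- function(n_pos_words = 5L, n_neg_words = 5L,
                            docs = 60L, seed = 1L, k = 2L) {
  n_pos_words <- as.integer(n_pos_words)
  n_neg_words <- as.integer(n_neg_words)
  stopifnot(n_pos_words >= 1L, n_neg_words >= 1L, docs >= 1L)
  pars <- paradigm_sets()
  if (n_pos_words > 26L || n_neg_words > 26L) {
    stop("at most 26 planted words per class")
  }
  pos_class <- paste0("posword", letters[seq_len(n_pos_words)])
  neg_class <- paste0("negword", letters[seq_len(n_neg_words)])
  fillers <- c("thing", "time", "place", "way", "person")
  corpus <- with_seed(seed, {
    vapply(seq_len(docs), function(d) {
      wp <- sample(pos_class, 1L)
      wn <- sample(neg_class, 1L)
      # three fillers between the halves so a +/-k context window never
      # spans a positive-class and a negative-class word
      paste(
        wp, sample(pars$positives, 1L), sample(fillers, 1L),
        sample(pars$positives, 1L), wp,
        sample(fillers, 1L), sample(fillers, 1L), sample(fillers, 1L),
        wn, sample(pars$negatives, 1L), sample(fillers, 1L),
        sample(pars$negatives, 1L), wn
      )
    }, character(1))
  })
  model <- build_cooccurrence_model(lapply(corpus, tokenize_text), k = k)
  labels <- c(stats::setNames(rep(1, n_pos_words), pos_class),
              stats::setNames(rep(-1, n_neg_words), neg_class))
  list(corpus = corpus, model = model, paradigms = pars, labels = labels)
}
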