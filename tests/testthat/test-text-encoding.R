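test_that("tokenization applies the stated rules", {
  expect_identical(tokenize("")[[1]], character(0))
  expect_identical(tokenize("Sick of this!")[[1]],
                   c("sick", "of", "this", "!"))
  # case-insensitivity: both occurrences tokenize identically
  toks <- tokenize("I'm OK I'm ok")[[1]]
  expect_identical(toks[1], toks[3])
  expect_identical(toks[2], toks[4])
  expect_identical(toks[1], "i'm")
  # URLs and handles collapse to placeholders; emoticons survive
  expect_identical(tokenize("see http://x.co/a?b=1 @bob :-)")[[1]],
                   c("see", "<url>", "<user>", ":-)"))
  expect_identical(tokenize("luv it <3")[[1]], c("luv", "it", "<3"))
})

test_that("the word-count filter is inclusive and order-preserving", {
  cor3 <- make_corpus(list(
    a = list(rep("w", 499)), b = list(rep("w", 500)),
    c = list(rep("w", 501))))
  kept <- filter_min_words(cor3, 500)
  expect_identical(names(kept), c("b", "c"))
  expect_identical(filter_min_words(cor3, 0), cor3)
  expect_length(filter_min_words(make_corpus(list()), 500), 0)
})

test_that("n-gram extraction counts by hand and respects post boundaries", {
  cor1 <- make_corpus(list(p1 = list(c("a", "b", "a"))))
  ng <- extract_ngrams(cor1, max_vocab = 100)
  f <- as.matrix(ng$frequencies)
  expect_equal(f[1, "a"], 2 / 3)
  expect_equal(f[1, "b"], 1 / 3)
  expect_equal(f[1, "a b"], 1 / 2)
  expect_equal(f[1, "b a"], 1 / 2)

  # bigrams never span posts
  cor2 <- make_corpus(list(p1 = list(c("a", "b"), c("c", "d"))))
  ng2 <- extract_ngrams(cor2, max_vocab = 100)
  expect_setequal(ng2$vocabulary[ng2$order == 2], c("a b", "c d"))

  # max_vocab = 1 keeps the single most frequent gram
  ng3 <- extract_ngrams(cor1, max_vocab = 1)
  expect_identical(ng3$vocabulary, "a")

  expect_error(extract_ngrams(make_corpus(list()), 10),
               class = "langdx_empty_corpus")
})

test_that("per-order frequencies sum to one per participant before truncation", {
  coh <- small_cohort(n = 20, seed = 3, vocab = 40, words = 200)
  ng <- extract_ngrams(coh$corpus, max_vocab = 1e6)
  fu <- Matrix::rowSums(ng$frequencies[, ng$order == 1, drop = FALSE])
  fb <- Matrix::rowSums(ng$frequencies[, ng$order == 2, drop = FALSE])
  expect_equal(unname(fu), rep(1, 20), tolerance = 1e-9)
  expect_true(all(fb <= 1 + 1e-9))
})

test_that("gram ranking pools orders by corpus count with lexicographic ties", {
  cor1 <- make_corpus(list(p1 = list(c("b", "b", "a", "a", "c"))))
  ng <- extract_ngrams(cor1, max_vocab = 3)
  # counts: a=2, b=2, c=1, bigrams all 1; ties broken lexicographically
  expect_identical(ng$vocabulary, c("a", "b", "a a", "a c", "b a", "b b",
                                    "c")[1:3])
})

test_that("LDA degenerates correctly with a single topic", {
  coh <- small_cohort(n = 15, seed = 2, vocab = 30, words = 100,
                      n_topics = 2)
  tm <- fit_lda(coh$corpus, n_topics = 1, n_sweeps = 5, seed = 1)
  freq <- Matrix::colSums(unigram_frequencies(coh$corpus))
  freq <- freq / sum(freq)
  # phi is (a smoothed version of) the corpus unigram distribution
  counts <- freq * sum(total_words(coh$corpus))
  expect_equal(unname(tm$phi[1, names(freq)]),
               unname((counts + tm$eta) /
                        (sum(counts) + length(counts) * tm$eta)),
               tolerance = 1e-9)
  expect_true(all(tm$topic_given_word == 1))
})

test_that("LDA output satisfies its probability contracts and is reproducible", {
  coh <- small_cohort(n = 30, seed = 6, vocab = 50, words = 150)
  tm <- fit_lda(coh$corpus, n_topics = 4, n_sweeps = 30, seed = 9)
  expect_equal(unname(rowSums(tm$phi)), rep(1, 4), tolerance = 1e-9)
  expect_equal(unname(rowSums(tm$topic_given_word)),
               rep(1, length(tm$vocabulary)), tolerance = 1e-9)
  expect_equal(sum(tm$topic_prior), 1, tolerance = 1e-9)
  tm2 <- fit_lda(coh$corpus, n_topics = 4, n_sweeps = 30, seed = 9)
  expect_identical(tm$phi, tm2$phi)
  expect_error(fit_lda(coh$corpus, n_topics = 1000, seed = 1),
               class = "langdx_invalid_parameter")
})

test_that("LDA recovers well-separated planted topics", {
  cfg <- cohort_config(n_participants = 300, vocab_size = 250,
                       n_topics_true = 5, words_per_participant = 400,
                       posts_per_participant = 2,
                       topic_concentration = 0.01,
                       mixture_concentration = 0.3)
  coh <- simulate_cohort(cfg, seed = 31)
  tm <- fit_lda(coh$corpus, n_topics = 5, n_sweeps = 100, seed = 31)
  tw <- coh$ground_truth$topic_word[, tm$vocabulary, drop = FALSE]
  # greedy 1-to-1 matching by total-variation distance
  D <- outer(seq_len(5), seq_len(5), Vectorize(function(i, j)
    0.5 * sum(abs(tw[i, ] - tm$phi[j, ]))))
  tvs <- numeric(5)
  for (s in seq_len(5)) {
    best <- arrayInd(which.min(D), dim(D))
    tvs[s] <- D[best]
    D[best[1], ] <- Inf
    D[, best[2]] <- Inf
  }
  expect_lt(mean(tvs), 0.2)
})

test_that("topic scores match the brute-force double loop and edge cases", {
  # hand-checked arithmetic: p(t|w) rows [[0.9,0.1],[0.2,0.8]], freqs .5/.5
  tm <- structure(list(
    phi = matrix(c(0.6, 0.4, 0.3, 0.7), 2, byrow = TRUE,
                 dimnames = list(NULL, c("u", "v"))),
    topic_prior = c(0.5, 0.5),
    topic_given_word = matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE,
                              dimnames = list(c("u", "v"), NULL)),
    vocabulary = c("u", "v"), n_topics = 2L), class = "topic_model")
  freqs <- matrix(c(0.5, 0.5), 1, dimnames = list("p1", c("u", "v")))
  expect_equal(unname(score_topics(tm, freqs)[1, ]), c(0.55, 0.45))

  coh <- small_cohort(n = 12, seed = 8, vocab = 25, words = 60)
  tmr <- fit_lda(coh$corpus, n_topics = 3, n_sweeps = 20, seed = 2)
  uf <- unigram_frequencies(coh$corpus)
  got <- score_topics(tmr, uf)
  want <- score_topics_bruteforce(tmr$topic_given_word, as.matrix(uf))
  expect_equal(unname(got), unname(want), tolerance = 1e-12)

  # single-topic model: every score equals the in-vocabulary mass (1 here)
  tm1 <- fit_lda(coh$corpus, n_topics = 1, n_sweeps = 5, seed = 1)
  expect_equal(unname(score_topics(tm1, uf)[, 1]), rep(1, 12),
               tolerance = 1e-9)

  # zero-coverage participant: all-zero row plus warning
  freqs0 <- matrix(c(1, 0.5, 0.5), 1, 3,
                   dimnames = list("px", c("zzz", "u", "v")))[, 1,
                                                              drop = FALSE]
  expect_warning(s0 <- score_topics(tm, cbind(freqs0, u = 0, v = 0)),
                 "no in-vocabulary")
  expect_equal(unname(s0[1, ]), c(0, 0))
})

test_that("top words rank by p(word|topic) with lexicographic ties and clamping", {
  phi <- matrix(c(0.9, 0.05, 0.05,
                  1 / 3, 1 / 3, 1 / 3), 2, byrow = TRUE,
                dimnames = list(NULL, c("m", "z", "a")))
  tm <- structure(list(phi = phi, vocabulary = c("m", "z", "a"),
                       n_topics = 2L), class = "topic_model")
  expect_identical(top_words(tm, 1, 2)$word, c("m", "a"))
  # uniform row: lexicographic order
  expect_identical(top_words(tm, 2, 3)$word, c("a", "m", "z"))
  # n beyond vocabulary: clamped
  tw <- top_words(tm, 1, 15)
  expect_equal(nrow(tw), 3)
  expect_equal(tw$size, c(3, 2, 1) / 3)
})
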