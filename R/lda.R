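#' Fit a Latent Dirichlet Allocation topic model
#'
#' Groups words that co-occur into topics using a collapsed Gibbs sampler.
#' Only unigrams enter the topic model. The returned model carries the
#' topic-word distributions p(word|topic), the corpus-wide topic prior
#' p(topic) (expected topic proportions over all tokens), and the posterior
#' p(topic|word) obtained by Bayes' rule, which is what participant topic
#' scoring consumes.
#'
#' @param corpus a `participant_corpus`.
#' @param n_topics number of topics (default 200).
#' @param alpha document-topic concentration; default `50 / n_topics`.
#' @param eta topic-word concentration; default 0.01.
#' @param n_sweeps full Gibbs sweeps over all tokens (default 300; adequate
#'   for the corpus scales this package targets, and configurable upward
#'   for larger vocabularies).
#' @param seed integer seed; same corpus + seed reproduce the model.
#' @return an object of class `topic_model`: `phi` (n_topics x vocab,
#'   rows sum to 1), `topic_prior`, `topic_given_word` (vocab x n_topics,
#'   rows sum to 1), `vocabulary`, and the fitting parameters.
#' @export
fit_lda <- function(corpus, n_topics = 200, alpha = 50 / n_topics,
                    eta = 0.01, n_sweeps = 300, seed = 1) {
  if (!length(corpus))
    stop_langdx("corpus is empty", "langdx_empty_corpus")
  if (n_topics < 1 || alpha <= 0 || eta <= 0 || n_sweeps < 1)
    stop_langdx("invalid LDA hyperparameters", "langdx_invalid_parameter")
  toks <- lapply(corpus, function(p) unlist(p$posts, use.names = FALSE))
  lens <- lengths(toks)
  f <- factor(unlist(toks, use.names = FALSE))
  vocab <- levels(f)
  if (n_topics > length(vocab))
    stop_langdx("n_topics exceeds the distinct vocabulary size",
                "langdx_invalid_parameter")
  doc <- rep.int(seq_along(toks), lens) - 1L
  word <- as.integer(f) - 1L
  set.seed(seed)
  fit <- lda_gibbs_cpp(doc, word, length(toks), length(vocab),
                       as.integer(n_topics), alpha, eta,
                       as.integer(n_sweeps))
  nkw <- fit$topic_word
  phi <- (nkw + eta) / (fit$topic_totals + length(vocab) * eta)
  colnames(phi) <- vocab
  topic_prior <- (fit$topic_totals + alpha) /
    (sum(fit$topic_totals) + n_topics * alpha)
  tgw <- t(phi) * rep(topic_prior, each = ncol(phi))
  tgw <- tgw / rowSums(tgw)
  structure(list(phi = phi,
                 topic_prior = topic_prior,
                 topic_given_word = tgw,
                 vocabulary = vocab,
                 n_topics = as.integer(n_topics),
                 alpha = alpha, eta = eta,
                 n_sweeps = as.integer(n_sweeps), seed = seed),
            class = "topic_model")
}

#' @export
print.topic_model <- function(x, ...) {
  cat("LDA topic model:", x$n_topics, "topics over",
      length(x$vocabulary), "words",
      sprintf("(alpha=%.3g, eta=%.3g, %d sweeps)\n",
              x$alpha, x$eta, x$n_sweeps))
  invisible(x)
}

#' Participant topic-usage scores
#'
#' Gives each participant a topic probability score p(topic|participant) by
#' combining the model's posterior topic-given-word probabilities with the
#' participant's probability of mentioning each word:
#' `score[u, t] = sum_w p(t|w) * p(w|u)` over the participant's
#' in-vocabulary unigrams. With full vocabulary coverage each participant's
#' scores sum to 1; otherwise to the in-vocabulary probability mass.
#'
#' @param model a `topic_model`.
#' @param unigram_freqs participant x word relative-frequency matrix (see
#'   [unigram_frequencies()]); column names are matched against the model
#'   vocabulary.
#' @return participant x topic score matrix. Participants with zero
#'   in-vocabulary words get an all-zero row, with a warning.
#' @export
score_topics <- function(model, unigram_freqs) {
  stopifnot(inherits(model, "topic_model"))
  common <- intersect(colnames(unigram_freqs), model$vocabulary)
  if (!length(common))
    stop_langdx("no overlap between participant words and model vocabulary",
                "langdx_invalid_input")
  s <- as.matrix(unigram_freqs[, common, drop = FALSE] %*%
                   model$topic_given_word[common, , drop = FALSE])
  rownames(s) <- rownames(unigram_freqs)
  colnames(s) <- paste0("topic_", seq_len(model$n_topics))
  zero <- rowSums(s) == 0
  if (any(zero))
    warning(sum(zero), " participant(s) have no in-vocabulary words; ",
            "their topic scores are all zero")
  s
}

#' Top words of a topic
#'
#' Ranks a topic's words by p(word|topic) descending (ties broken
#' lexicographically) and attaches a rank-proportional display size
#' (largest = rank 1), the information a word-cloud rendering needs.
#'
#' @param model a `topic_model`.
#' @param topic topic index in `1..n_topics`.
#' @param n number of words (default 15); clamped to the vocabulary size.
#' @return data frame with `word`, `prob`, `rank`, `size` (in (0, 1],
#'   proportional to reversed rank).
#' @export
top_words <- function(model, topic, n = 15) {
  stopifnot(inherits(model, "topic_model"))
  if (topic < 1 || topic > model$n_topics)
    stop_langdx("topic index out of range", "langdx_invalid_parameter")
  p <- model$phi[topic, ]
  ord <- head(c_order(-p, model$vocabulary), n)
  k <- length(ord)
  data.frame(word = model$vocabulary[ord],
             prob = unname(p[ord]),
             rank = seq_len(k),
             size = (k - seq_len(k) + 1) / k,
             stringsAsFactors = FALSE)
}
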