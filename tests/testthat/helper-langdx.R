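# Shared fixtures and independent oracles for the test suite.

# Brute-force AUC over all case-control pairs (ties count 1/2).
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Brute-force BH step-up: largest k with p_(k) <= k*alpha/m; reject all
# p <= p_(k*).
bh_bruteforce <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  ks <- which(ps <= seq_len(m) * alpha / m)
  if (!length(ks)) return(rep(FALSE, m))
  p <- p <= ps[max(ks)]
  p
}

# Brute-force topic scoring: double loop over (topic, word).
score_topics_bruteforce <- function(tgw, freqs) {
  n <- nrow(freqs); K <- ncol(tgw)
  out <- matrix(0, n, K)
  words <- intersect(colnames(freqs), rownames(tgw))
  for (u in seq_len(n))
    for (t in seq_len(K))
      for (w in words)
        out[u, t] <- out[u, t] + tgw[w, t] * freqs[u, w]
  out
}

# Small deterministic corpus built directly from token lists.
make_corpus <- function(posts_by_participant) {
  participant_corpus(names(posts_by_participant), posts_by_participant)
}

# A quick planted-signal cohort for model-level tests.
small_cohort <- function(n = 150, seed = 1, effect = 4, topic = 1,
                         n_topics = 5, vocab = 100, words = 520,
                         demo_coefs = NULL) {
  cfg <- cohort_config(
    n_participants = n, vocab_size = vocab, n_topics_true = n_topics,
    words_per_participant = words, posts_per_participant = 5,
    condition_effects = list(condition_effect(
      "dx", intercept = -0.5,
      topic_coefs = stats::setNames(effect, topic),
      demo_coefs = demo_coefs, n_topics = n_topics)))
  simulate_cohort(cfg, seed = seed)
}
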