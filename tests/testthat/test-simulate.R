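test_that("topic-word matrices are stochastic, deterministic, and approach uniformity", {
  m <- generate_topic_word_matrix(1, 10, 5, seed = 1)
  expect_equal(dim(m), c(1, 10))
  expect_equal(sum(m), 1, tolerance = 1e-12)

  m2 <- generate_topic_word_matrix(7, 40, 0.3, seed = 42)
  expect_equal(unname(rowSums(m2)), rep(1, 7), tolerance = 1e-9)
  expect_identical(m2, generate_topic_word_matrix(7, 40, 0.3, seed = 42))

  # huge concentration: rows approach uniform 1/V
  mu <- generate_topic_word_matrix(5, 20, 1e6, seed = 3)
  expect_lt(max(abs(mu - 1 / 20)), 1e-2)

  expect_error(generate_topic_word_matrix(3, 10, 0, seed = 1),
               class = "langdx_invalid_parameter")
  expect_error(generate_topic_word_matrix(12, 10, 1, seed = 1),
               class = "langdx_invalid_parameter")
})

test_that("simulated corpora have the configured structure", {
  cfg <- cohort_config(n_participants = 12, vocab_size = 30,
                       n_topics_true = 3, words_per_participant = 600,
                       posts_per_participant = 4)
  coh <- simulate_cohort(cfg, seed = 5)
  expect_length(coh$corpus, 12)
  expect_true(all(total_words(coh$corpus) == 600))
  expect_true(all(vapply(coh$corpus, function(p) length(p$posts), 0L) == 4))
  # every participant passes the default word filter by construction
  expect_length(filter_min_words(coh$corpus, 500), 12)
  expect_equal(unname(rowSums(coh$ground_truth$theta)), rep(1, 12),
               tolerance = 1e-9)
  expect_equal(unname(rowSums(coh$ground_truth$topic_word)), rep(1, 3),
               tolerance = 1e-9)
})

test_that("a single-topic generator yields degenerate mixtures", {
  cfg <- cohort_config(n_participants = 5, vocab_size = 20,
                       n_topics_true = 1, words_per_participant = 50,
                       posts_per_participant = 2)
  coh <- simulate_cohort(cfg, seed = 1)
  expect_equal(unname(coh$ground_truth$theta[, 1]), rep(1, 5))
})

test_that("generation is byte-identical under the same config and seed", {
  cfg <- cohort_config(n_participants = 8, vocab_size = 25,
                       n_topics_true = 2, words_per_participant = 80,
                       posts_per_participant = 3,
                       condition_effects = list(
                         condition_effect("dx", 0, n_topics = 2)))
  a <- simulate_cohort(cfg, seed = 99)
  b <- simulate_cohort(cfg, seed = 99)
  expect_identical(a, b)
})

test_that("empirical word frequencies converge to the topic distribution", {
  # single topic, many words: LLN in total-variation distance
  cfg <- cohort_config(n_participants = 200, vocab_size = 50,
                       n_topics_true = 1, words_per_participant = 5000,
                       posts_per_participant = 1,
                       topic_concentration = 0.5)
  coh <- simulate_cohort(cfg, seed = 11)
  freq <- Matrix::colSums(unigram_frequencies(coh$corpus)) / 200
  tw <- coh$ground_truth$topic_word[1, names(freq)]
  expect_lt(0.5 * sum(abs(freq - tw)) + 0.5 * (1 - sum(tw)), 0.01)
})

test_that("condition assignment follows the logistic outcome model", {
  set.seed(2)
  n <- 2000
  theta <- matrix(stats::rgamma(n * 4, 0.5), n)
  theta <- theta / rowSums(theta)
  demo <- data.frame(participant_id = as.character(seq_len(n)),
                     age = sample(18:65, n, TRUE),
                     sex = sample(c("female", "male"), n, TRUE),
                     race = sample(c("black", "white", "asian", "other"),
                                   n, TRUE))
  eff0 <- list(condition_effect("null", 0, n_topics = 4))
  out0 <- assign_conditions(theta, demo, eff0, seed = 1)
  # all-zero effects: prevalence near 0.5 (binomial 99% CI)
  expect_lt(abs(mean(out0$labels) - 0.5), 2.58 * 0.5 / sqrt(n))

  effneg <- list(condition_effect("rare", -20, n_topics = 4))
  expect_equal(sum(assign_conditions(theta, demo, effneg, 1)$labels), 0)

  eff1 <- list(condition_effect("dx", -0.5, topic_coefs = c("1" = 3),
                                n_topics = 4))
  out1 <- assign_conditions(theta, demo, eff1, seed = 3)
  q <- stats::quantile(theta[, 1], c(0.25, 0.75))
  p_top <- mean(out1$probabilities[theta[, 1] >= q[2], 1])
  p_bot <- mean(out1$probabilities[theta[, 1] <= q[1], 1])
  expect_gt(p_top, p_bot)

  expect_error(assign_conditions(theta, demo,
                                 list(condition_effect("bad", 0,
                                                       n_topics = 7)),
                                 seed = 1),
               class = "langdx_invalid_parameter")
})

test_that("raising an intercept never loses cases at a fixed seed", {
  set.seed(4)
  n <- 400
  theta <- matrix(stats::rgamma(n * 3, 1), n)
  theta <- theta / rowSums(theta)
  demo <- data.frame(participant_id = as.character(seq_len(n)),
                     age = sample(18:65, n, TRUE),
                     sex = sample(c("female", "male"), n, TRUE),
                     race = sample(c("black", "white", "asian", "other"),
                                   n, TRUE))
  prev <- vapply(c(-2, -1, 0, 1), function(b0) {
    eff <- list(condition_effect("dx", b0, n_topics = 3))
    mean(assign_conditions(theta, demo, eff, seed = 7)$labels)
  }, numeric(1))
  expect_true(all(diff(prev) >= 0))
})

test_that("planted coefficients leave a recoverable signature in theta", {
  # log-odds of the condition regressed on true theta recovers the sign
  coh <- small_cohort(n = 800, seed = 21, effect = 3, vocab = 60,
                      words = 50)
  th1 <- coh$ground_truth$theta[, 1]
  fitcoef <- coef(glm(coh$labels[, 1] ~ th1, family = binomial()))["th1"]
  expect_gt(fitcoef, 0)
})

test_that("config validation rejects invalid parameters", {
  expect_error(cohort_config(vocab_size = 1),
               class = "langdx_invalid_parameter")
  expect_error(cohort_config(mixture_concentration = 0),
               class = "langdx_invalid_parameter")
  expect_error(cohort_config(demographics = list(
    age_range = c(18, 65), p_female = 0.5,
    race_levels = c("a", "b"), race_probs = c(0.7, 0.2))),
    class = "langdx_invalid_parameter")
  expect_error(cohort_config(condition_effects = list(
    list(name = "dx", intercept = 0, topic_coefs = 1:3,
         demo_coefs = numeric(5))), n_topics_true = 20),
    class = "langdx_invalid_parameter")
})
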