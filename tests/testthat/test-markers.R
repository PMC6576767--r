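demo_frame <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(participant_id = sprintf("P%03d", seq_len(n)),
             age = sample(18:65, n, TRUE),
             sex = sample(c("female", "male"), n, TRUE),
             race = sample(c("black", "white", "asian", "other"), n, TRUE))
}

test_that("marker scan hits the trivial anchors", {
  set.seed(51)
  n <- 120
  y <- rbinom(n, 1, 0.4)
  S <- cbind(as.numeric(y),          # topic identical to the label
             matrix(runif(n * 2), n),
             rep(0.3, n))            # degenerate constant topic
  res <- topic_marker_scan(S, demo_frame(n), y, k = 5, n_iter = 100,
                           seed = 3)
  expect_equal(res$auc_topic_alone[1], 1)
  expect_equal(res$auc_topic_alone[4], 0.5)
  expect_true(res$degenerate[4])
  expect_equal(res$p_value[4], 1)
  expect_false(res$significant[4])
  expect_true(all(res$direction %in% c(-1L, 1L)))
  # direction matches the sign of the case-control mean difference
  for (t in 1:3) {
    d <- mean(S[y == 1, t]) - mean(S[y == 0, t])
    expect_equal(res$direction[t], if (d < 0) -1L else 1L)
  }
  # its AUCs agree with auc() on identical inputs
  expect_equal(res$auc_topic_alone[2], auc(S[, 2], y))
})

test_that("null topics rarely pass BH across the scan", {
  set.seed(52)
  n <- 300
  y <- rbinom(n, 1, 0.3)
  S <- matrix(runif(n * 20), n)
  res <- topic_marker_scan(S, demo_frame(n, 7), y, k = 5, n_iter = 200,
                           seed = 9)
  expect_lte(sum(res$significant), 2)
})

test_that("quartile ratios match hand arithmetic", {
  # top quartile 6/10 cases, bottom 2/10 -> ratio 3.0
  s <- seq_len(40)
  y <- integer(40)
  y[1:10][1:2] <- 1L          # bottom quartile: 2 cases
  y[31:40][1:6] <- 1L         # top quartile: 6 cases
  y[15:20] <- 1L              # middle cases, irrelevant
  q <- quartile_ratio(s, y, n_boot = 500, seed = 1)
  expect_equal(q$ratio, 3.0)
  expect_equal(q$top_cases, 6)
  expect_equal(q$bottom_cases, 2)

  # identical case proportions: ratio 1, CI contains 1
  y2 <- rep(c(1, 0, 0, 0, 0), 8)
  q2 <- quartile_ratio(seq_len(40), y2, n_boot = 2000, seed = 2)
  expect_equal(q2$ratio, 1.0)
  expect_lte(q2$ci_low, 1)
  expect_gte(q2$ci_high, 1)

  # zero cases in the bottom quartile: ratio +Inf with finite lower bound
  y3 <- integer(40)
  y3[31:40] <- rep(c(1L, 0L), 5)
  q3 <- quartile_ratio(seq_len(40), y3, n_boot = 2000, seed = 3)
  expect_identical(q3$ratio, Inf)
  expect_true(is.finite(q3$ci_low))
  expect_identical(q3$ci_high, Inf)

  expect_error(quartile_ratio(seq_len(40), integer(40), 100, 1),
               class = "langdx_undefined_ratio")
  expect_error(quartile_ratio(1:4, c(1, 0, 1, 0), 100, 1),
               class = "langdx_invalid_input")
})

test_that("bootstrap CI covers a known generative quartile risk ratio", {
  # planted: top-quartile risk 0.45, bottom 0.15 -> true ratio 3.0
  set.seed(61)
  n <- 400
  covered <- logical(150)
  est <- numeric(150)
  for (i in seq_len(150)) {
    s <- runif(n)
    p <- ifelse(s >= 0.75, 0.45, ifelse(s < 0.25, 0.15, 0.3))
    y <- rbinom(n, 1, p)
    q <- quartile_ratio(s, y, n_boot = 1000, seed = i)
    covered[i] <- q$ci_low <= 3 && q$ci_high >= 3
    est[i] <- q$ratio
  }
  expect_gte(mean(covered), 0.9)
  expect_gt(stats::median(est), 2.5)
  expect_lt(stats::median(est), 3.5)
})

test_that("topic expression matrix is signed excess AUC with clustered rows", {
  set.seed(71)
  n <- 200
  y <- rbinom(n, 1, 0.4)
  S <- matrix(runif(n * 6), n)
  scans <- list(
    a = topic_marker_scan(S, demo_frame(n, 2), y, k = 4, n_iter = 50,
                          seed = 1),
    b = topic_marker_scan(S, demo_frame(n, 2), rev(y), k = 4, n_iter = 50,
                          seed = 1),
    c = topic_marker_scan(S, demo_frame(n, 2), sample(y), k = 4,
                          n_iter = 50, seed = 1))
  m <- topic_expression_matrix(scans)
  expect_equal(dim(m), c(3, 6))
  expect_true(all(abs(m) <= 0.5))
  # entries are direction * (topic-alone AUC - 0.5) by construction
  r <- scans$a
  expect_equal(unname(unclass(m)["a", ]),
               r$direction * (r$auc_topic_alone - 0.5))
  # permuting condition order leaves the dendrogram structure invariant
  m2 <- topic_expression_matrix(scans[c(3, 1, 2)])
  expect_equal(sort(attr(m, "hclust")$height),
               sort(attr(m2, "hclust")$height))
  expect_equal(unclass(m)["a", ], unclass(m2)["a", ])
  expect_error(topic_expression_matrix(list()),
               class = "langdx_invalid_input")
})

test_that("null scans give near-zero expression entries", {
  set.seed(81)
  n <- 1000
  y <- rbinom(n, 1, 0.3)
  S <- matrix(runif(n * 8), n)
  scans <- list(x = topic_marker_scan(S, demo_frame(n, 3), y, k = 4,
                                      n_iter = 20, seed = 2))
  m <- topic_expression_matrix(scans)
  expect_lt(max(abs(m)), 0.05)
})

test_that("word-cloud export honors significance, ranking, and k", {
  cfg <- cohort_config(n_participants = 40, vocab_size = 40,
                       n_topics_true = 3, words_per_participant = 100,
                       posts_per_participant = 5,
                       topic_concentration = 0.5)
  coh <- simulate_cohort(cfg, seed = 91)
  tm <- fit_lda(coh$corpus, n_topics = 3, n_sweeps = 20, seed = 4)
  scan <- data.frame(topic = 1:3,
                     auc_topic_alone = c(0.7, 0.6, 0.5),
                     auc_demo = 0.5,
                     auc_demo_plus_topic = c(0.65, 0.72, 0.5),
                     p_value = c(0.001, 0.002, 0.9),
                     adjusted_p = c(0.003, 0.003, 0.9),
                     significant = c(TRUE, TRUE, FALSE),
                     direction = c(1L, -1L, 1L), degenerate = FALSE)
  out <- export_wordclouds(tm, list(dx = scan), top_k_topics = 5)
  expect_length(out$dx, 2)                 # only significant topics
  expect_equal(out$dx[[1]]$topic, 2)       # ranked by added AUC
  expect_equal(nrow(out$dx[[1]]$words), 15)
  expect_length(export_wordclouds(tm, list(dx = scan), 0)$dx, 0)
})
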