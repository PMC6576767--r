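#' Area under the ROC curve
#'
#' Rank-based AUC: the probability that a randomly chosen case outscores a
#' randomly chosen control, with ties counting one half. Equivalent to the
#' Mann-Whitney U statistic normalized by the number of case-control pairs.
#'
#' @param scores numeric score vector.
#' @param labels binary 0/1 vector; both classes must be present.
#' @return AUC in \[0, 1\].
#' @examples
#' auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))  # 1
#' @export
auc <- function(scores, labels) {
  y <- check_binary_labels(labels)
  if (length(scores) != length(y))
    stop_langdx("scores and labels differ in length", "langdx_invalid_input")
  n1 <- sum(y)
  n0 <- length(y) - n1
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified k-fold assignment
#'
#' Partitions participants into `k` non-overlapping folds that cover the
#' sample, with fold sizes differing by at most one and each fold's case
#' count within one of proportional (cases and controls are each split as
#' evenly as possible, and the leftover cases/controls are placed so that
#' total fold sizes stay balanced). If either class has fewer than `k`
#' members, `k` is reduced to that class size with a warning.
#'
#' @param labels binary 0/1 vector.
#' @param k number of folds (default 10); must be >= 2.
#' @param seed integer seed.
#' @return integer vector of fold indices in `1..k`, with attribute
#'   `k` (the possibly reduced fold count).
#' @export
stratified_kfold <- function(labels, k = 10, seed = 1) {
  y <- check_binary_labels(labels)
  if (k < 2)
    stop_langdx("k must be >= 2", "langdx_invalid_parameter")
  k <- as.integer(k)
  n1 <- sum(y); n0 <- length(y) - n1
  if (min(n1, n0) < k) {
    k <- min(n1, n0)
    warning("reducing k to ", k, " (smallest class size)")
    if (k < 2)
      stop_langdx("need at least 2 members per class", "langdx_invalid_parameter")
  }
  set.seed(seed)
  r1 <- n1 %% k; r0 <- n0 %% k
  # folds receiving a leftover case / control: overlap only as forced
  fold_order <- sample.int(k)
  case_plus <- fold_order[seq_len(r1)]
  ctrl_pool <- c(setdiff(fold_order, case_plus), case_plus)
  ctrl_plus <- ctrl_pool[seq_len(r0)]
  counts1 <- rep(n1 %/% k, k); counts1[case_plus] <- counts1[case_plus] + 1L
  counts0 <- rep(n0 %/% k, k); counts0[ctrl_plus] <- counts0[ctrl_plus] + 1L
  fold <- integer(length(y))
  fold[sample(which(y == 1))] <- rep.int(seq_len(k), counts1)
  fold[sample(which(y == 0))] <- rep.int(seq_len(k), counts0)
  attr(fold, "k") <- k
  fold
}

#' Out-of-fold predictions for the three condition models
#'
#' Runs the full per-fold training protocol: gram selection on the training
#' rows only ([fwer_select()]), the extremely-randomized-trees language
#' model on topic scores plus selected grams, the ridge logistic
#' demographics model (age standardized with training-fold statistics), and
#' the AUC-weighted ensemble with weights taken from each model's training
#' AUC. Every participant receives exactly one held-out prediction per
#' model.
#'
#' @param grams an `ngram_features` object or frequency matrix.
#' @param topic_scores participant x topic score matrix.
#' @param demographics data frame with `age`, `sex`, `race` (aligned rows).
#' @param labels binary 0/1 vector.
#' @param folds fold assignment from [stratified_kfold()].
#' @param k_select grams to select per fold (default 500).
#' @param n_estimators trees in the language model (default 1000).
#' @param penalty ridge penalty for the demographics model (default 1).
#' @param seed integer seed (per-fold seeds are derived from it).
#' @return list with `p_lang`, `p_demo`, `p_combined` (held-out probability
#'   vectors), `train_auc` (fold x model matrix), `selections` (per-fold
#'   `fwer_selection`), and `skipped_folds`.
#' @export
cross_validated_scores <- function(grams, topic_scores, demographics, labels,
                                   folds, k_select = 500,
                                   n_estimators = 1000, penalty = 1,
                                   seed = 1) {
  if (inherits(grams, "ngram_features")) grams <- grams$frequencies
  y <- check_binary_labels(labels)
  n <- length(y)
  stopifnot(nrow(grams) == n, nrow(topic_scores) == n,
            nrow(demographics) == n, length(folds) == n)
  k <- max(folds)
  p_lang <- p_demo <- p_comb <- rep(NA_real_, n)
  train_auc <- matrix(NA_real_, k, 2,
                      dimnames = list(NULL, c("language", "demographics")))
  selections <- vector("list", k)
  skipped <- integer(0)
  race_lv <- unique(as.character(demographics$race))
  for (f in seq_len(k)) {
    tr <- folds != f
    te <- !tr
    if (length(unique(y[tr])) < 2) {
      skipped <- c(skipped, f)
      next
    }
    sel <- fwer_select(grams[tr, , drop = FALSE], y[tr], k_select)
    selections[[f]] <- sel
    X_lang_tr <- cbind(as.matrix(topic_scores[tr, , drop = FALSE]),
                       as.matrix(grams[tr, sel$indices, drop = FALSE]))
    X_lang_te <- cbind(as.matrix(topic_scores[te, , drop = FALSE]),
                       as.matrix(grams[te, sel$indices, drop = FALSE]))
    m_lang <- fit_language_trees(X_lang_tr, y[tr],
                                 n_estimators = n_estimators,
                                 seed = seed + f)
    xd_tr <- encode_demographics(demographics[tr, , drop = FALSE],
                                 race_levels = race_lv)
    xd_te <- encode_demographics(demographics[te, , drop = FALSE],
                                 race_levels = race_lv,
                                 age_center = attr(xd_tr, "age_center"),
                                 age_scale = attr(xd_tr, "age_scale"))
    m_demo <- fit_demographics_ridge(xd_tr, y[tr], penalty = penalty)
    p_lang[te] <- predict(m_lang, X_lang_te)
    p_demo[te] <- predict(m_demo, xd_te)
    train_auc[f, ] <- c(m_lang$train_auc, m_demo$train_auc)
    p_comb[te] <- ensemble_predict(p_lang[te], p_demo[te],
                                   m_lang$train_auc, m_demo$train_auc)
  }
  list(p_lang = p_lang, p_demo = p_demo, p_combined = p_comb,
       train_auc = train_auc, selections = selections,
       skipped_folds = skipped)
}

#' Permutation test for the difference of two paired AUCs
#'
#' Monte-Carlo paired sign-flip test: under the null that the two models
#' are exchangeable, each iteration independently swaps a participant's two
#' scores with probability one half and recomputes the AUC difference. The
#' two-sided p-value uses add-one smoothing,
#' `p = (#{|d_perm| >= |d_obs|} + 1) / (n_iter + 1)`, so it is never 0 and
#' never below `1 / (n_iter + 1)`.
#'
#' @param scores_a,scores_b aligned score vectors for the two models.
#' @param labels binary 0/1 vector.
#' @param n_iter Monte-Carlo iterations (default 100000).
#' @param seed integer seed.
#' @return two-sided p-value in (0, 1].
#' @export
perm_test_auc_diff <- function(scores_a, scores_b, labels, n_iter = 100000,
                               seed = 1) {
  y <- check_binary_labels(labels)
  if (length(scores_a) != length(y) || length(scores_b) != length(y))
    stop_langdx("score/label lengths differ", "langdx_invalid_input")
  if (n_iter < 1)
    stop_langdx("n_iter must be >= 1", "langdx_invalid_parameter")
  d_obs <- auc(scores_a, y) - auc(scores_b, y)
  set.seed(seed)
  cnt <- perm_auc_diff_count_cpp(as.numeric(scores_a), as.numeric(scores_b),
                                 y, d_obs, as.integer(n_iter))
  (cnt + 1) / (n_iter + 1)
}

#' Permutation test of an AUC against chance
#'
#' Label-permutation null: each iteration shuffles the labels and
#' recomputes the AUC; the one-sided (greater) p-value is the add-one
#' smoothed fraction of permuted AUCs at least as large as observed.
#'
#' @param scores score vector.
#' @param labels binary 0/1 vector.
#' @param n_iter Monte-Carlo iterations (>= 1).
#' @param seed integer seed.
#' @return one-sided p-value in (0, 1].
#' @export
perm_test_auc_vs_chance <- function(scores, labels, n_iter = 100000,
                                    seed = 1) {
  y <- check_binary_labels(labels)
  if (length(scores) != length(y))
    stop_langdx("score/label lengths differ", "langdx_invalid_input")
  if (n_iter < 1)
    stop_langdx("n_iter must be >= 1", "langdx_invalid_parameter")
  n <- length(y); n1 <- sum(y); n0 <- n - n1
  r <- rank(scores)
  const <- n1 * (n1 + 1) / 2
  a_obs <- (sum(r[y == 1]) - const) / (n1 * n0)
  set.seed(seed)
  cnt <- 0L
  for (i in seq_len(n_iter)) {
    a_perm <- (sum(r[sample.int(n, n1)]) - const) / (n1 * n0)
    if (a_perm >= a_obs - 1e-12) cnt <- cnt + 1L
  }
  (cnt + 1) / (n_iter + 1)
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' Step-up procedure: with ordered p-values `p_(1) <= ... <= p_(m)`, find
#' the largest `k` with `p_(k) <= k * alpha / m` and reject all hypotheses
#' with `p <= p_(k)`. Adjusted p-values are the standard monotone BH
#' values; a hypothesis is rejected exactly when its adjusted p-value is
#' at most `alpha`.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @param alpha target FDR level (default 0.05).
#' @return list with `rejected` (logical) and `adjusted_p`.
#' @export
bh_fdr <- function(p_values, alpha = 0.05) {
  if (!length(p_values)) return(list(rejected = logical(0),
                                     adjusted_p = numeric(0)))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop_langdx("p-values must lie in [0, 1]", "langdx_invalid_input")
  adj <- p.adjust(p_values, method = "BH")
  list(rejected = adj <= alpha, adjusted_p = adj)
}
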