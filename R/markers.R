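#' Per-topic marker scan for one condition
#'
#' Evaluates each topic one at a time as a potential condition marker by
#' comparing three AUCs: (1) from the raw topic usage scores alone, (2)
#' from out-of-sample ridge-logistic predictions over age, sex and race,
#' and (3) from out-of-sample ridge-logistic predictions over age, sex,
#' race plus the topic. Significance of each topic's incremental
#' contribution (model 3 vs model 2) comes from the paired sign-flip
#' permutation test, with Benjamini-Hochberg adjustment across topics.
#' Direction is +1 when cases use the topic more than controls.
#'
#' @param topic_scores participant x topic score matrix.
#' @param demographics data frame with `age`, `sex`, `race`.
#' @param labels binary 0/1 vector.
#' @param k folds for the out-of-sample AUCs (default 10).
#' @param n_iter permutation iterations per topic (default 10000).
#' @param penalty ridge penalty (default 1).
#' @param alpha BH level for the `significant` flag (default 0.05).
#' @param seed integer seed.
#' @return data frame of class `marker_scan` with one row per topic:
#'   `topic`, `auc_topic_alone`, `auc_demo`, `auc_demo_plus_topic`,
#'   `p_value`, `adjusted_p`, `significant`, `direction`, `degenerate`.
#' @export
topic_marker_scan <- function(topic_scores, demographics, labels, k = 10,
                              n_iter = 10000, penalty = 1, alpha = 0.05,
                              seed = 1) {
  y <- check_binary_labels(labels)
  S <- as.matrix(topic_scores)
  stopifnot(nrow(S) == length(y), nrow(demographics) == length(y))
  folds <- stratified_kfold(y, k = k, seed = seed)
  k <- attr(folds, "k")
  race_lv <- unique(as.character(demographics$race))

  # shared out-of-sample demographics predictions (identical for all topics)
  ridge_oof <- function(extra_col = NULL) {
    p <- rep(NA_real_, length(y))
    for (f in seq_len(k)) {
      tr <- folds != f
      xd_tr <- encode_demographics(demographics[tr, , drop = FALSE],
                                   race_levels = race_lv)
      xd_te <- encode_demographics(demographics[!tr, , drop = FALSE],
                                   race_levels = race_lv,
                                   age_center = attr(xd_tr, "age_center"),
                                   age_scale = attr(xd_tr, "age_scale"))
      if (!is.null(extra_col)) {
        mu <- mean(extra_col[tr]); sdv <- max(sd(extra_col[tr]), 1e-12)
        xd_tr <- cbind(xd_tr, topic = (extra_col[tr] - mu) / sdv)
        xd_te <- cbind(xd_te, topic = (extra_col[!tr] - mu) / sdv)
      }
      m <- fit_demographics_ridge(xd_tr, y[tr], penalty = penalty)
      p[!tr] <- predict(m, xd_te)
    }
    p
  }
  p_demo <- ridge_oof()
  auc_demo <- auc(p_demo, y)

  n_topics <- ncol(S)
  res <- data.frame(topic = seq_len(n_topics),
                    auc_topic_alone = NA_real_, auc_demo = auc_demo,
                    auc_demo_plus_topic = NA_real_, p_value = NA_real_,
                    adjusted_p = NA_real_, significant = FALSE,
                    direction = 1L, degenerate = FALSE)
  for (t in seq_len(n_topics)) {
    s <- S[, t]
    if (sd(s) == 0) {
      res$auc_topic_alone[t] <- 0.5
      res$auc_demo_plus_topic[t] <- auc_demo
      res$p_value[t] <- 1
      res$degenerate[t] <- TRUE
      next
    }
    res$auc_topic_alone[t] <- auc(s, y)
    p_full <- ridge_oof(s)
    res$auc_demo_plus_topic[t] <- auc(p_full, y)
    res$p_value[t] <- perm_test_auc_diff(p_full, p_demo, y,
                                         n_iter = n_iter, seed = seed + t)
    d <- mean(s[y == 1]) - mean(s[y == 0])
    res$direction[t] <- if (d < 0) -1L else 1L
  }
  bh <- bh_fdr(res$p_value, alpha = alpha)
  res$adjusted_p <- bh$adjusted_p
  res$significant <- bh$rejected & !res$degenerate
  class(res) <- c("marker_scan", "data.frame")
  res
}

#' Quartile likelihood ratio for a topic score
#'
#' Splits participants into quartiles of a topic usage score (ties broken
#' by stable participant order) and reports how many times more likely the
#' condition is in the top quartile than in the bottom quartile. The
#' per-quartile condition probabilities are maximum-likelihood estimates
#' (sample means); the 95% confidence interval comes from percentile
#' bootstrap resampling within each quartile. A bootstrap resample with
#' zero bottom-quartile cases contributes +Inf, so the upper bound is
#' reported as +Inf whenever the 97.5 percentile is infinite, and the point
#' estimate itself is +Inf when the observed bottom quartile has no cases.
#'
#' @param topic_scores_vector numeric topic usage scores.
#' @param labels binary 0/1 vector.
#' @param n_boot bootstrap iterations (default 10000).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @return an object of class `quartile_ratio`: `ratio`, `ci_low`,
#'   `ci_high`, `top_cases`, `top_n`, `bottom_cases`, `bottom_n`,
#'   `n_boot`.
#' @export
quartile_ratio <- function(topic_scores_vector, labels, n_boot = 10000,
                           seed = 1, conf = 0.95) {
  y <- check_binary_labels(labels, require_both = FALSE)
  s <- as.numeric(topic_scores_vector)
  n <- length(s)
  if (length(y) != n)
    stop_langdx("scores and labels differ in length", "langdx_invalid_input")
  if (n < 8)
    stop_langdx("need at least 8 participants for quartiles",
                "langdx_invalid_input")
  ord <- order(s)                      # stable: ties keep participant order
  bounds <- round(seq(0, n, length.out = 5))
  bottom <- ord[seq_len(bounds[2])]
  top <- ord[(bounds[4] + 1):n]
  nb <- length(bottom); nt <- length(top)
  cb <- sum(y[bottom]); ct <- sum(y[top])
  if (cb == 0 && ct == 0)
    stop_langdx("no cases in either extreme quartile",
                "langdx_undefined_ratio")
  pt_ <- ct / nt; pb <- cb / nb
  ratio <- if (pb == 0) Inf else pt_ / pb
  set.seed(seed)
  bt <- rbinom(n_boot, nt, pt_) / nt
  if (cb == 0) {
    # every within-quartile resample has an empty bottom cell; the lower
    # bound comes from a continuity-corrected denominator (0.5 cases),
    # the estimate and upper bound are +Inf
    r_low <- bt / (0.5 / nb)
    qs <- c(quantile(r_low, (1 - conf) / 2, type = 1, names = FALSE), Inf)
  } else {
    bb <- rbinom(n_boot, nb, pb) / nb
    r <- ifelse(bb == 0, ifelse(bt == 0, NaN, Inf), bt / bb)
    r <- r[!is.nan(r)]
    qs <- quantile(r, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                   type = 1, names = FALSE)
  }
  structure(list(ratio = ratio, ci_low = qs[1], ci_high = qs[2],
                 top_cases = ct, top_n = nt,
                 bottom_cases = cb, bottom_n = nb,
                 n_boot = n_boot, conf = conf),
            class = "quartile_ratio")
}

#' @export
print.quartile_ratio <- function(x, ...) {
  fmt <- function(v) if (is.infinite(v)) "inf" else sprintf("%.3g", v)
  cat(sprintf(
    "Top-vs-bottom quartile likelihood ratio: %s (%.0f%% CI [%s, %s])\n",
    fmt(x$ratio), 100 * x$conf, fmt(x$ci_low), fmt(x$ci_high)))
  cat(sprintf("  top quartile: %d/%d cases; bottom quartile: %d/%d cases\n",
              x$top_cases, x$top_n, x$bottom_cases, x$bottom_n))
  invisible(x)
}

#' Signed topic-expression matrix across conditions
#'
#' Builds the condition x topic matrix of signed predictive strengths,
#' `direction * (auc_topic_alone - 0.5)` (entries in \[-0.5, 0.5\];
#' positive when the topic is used more by cases), with rows ordered by
#' agglomerative hierarchical clustering (average linkage, Euclidean
#' distance), so conditions with similar marker patterns sit together.
#'
#' @param marker_results named list of `marker_scan` data frames, one per
#'   condition (all over the same topics).
#' @return matrix of class `topic_expression` with attributes `row_order`
#'   (clustering order) and `hclust`.
#' @export
topic_expression_matrix <- function(marker_results) {
  if (!length(marker_results) || is.null(names(marker_results)))
    stop_langdx("need a named list of marker scans", "langdx_invalid_input")
  nt <- nrow(marker_results[[1]])
  if (any(vapply(marker_results, nrow, 0L) != nt))
    stop_langdx("marker scans cover different topic sets",
                "langdx_invalid_input")
  m <- t(vapply(marker_results,
                function(r) r$direction * (r$auc_topic_alone - 0.5),
                numeric(nt)))
  colnames(m) <- paste0("topic_", seq_len(nt))
  if (nrow(m) > 2) {
    hc <- hclust(dist(m, method = "euclidean"), method = "average")
    attr(m, "row_order") <- hc$order
    attr(m, "hclust") <- hc
  } else {
    attr(m, "row_order") <- seq_len(nrow(m))
  }
  class(m) <- c("topic_expression", class(m))
  m
}

#' @export
plot.topic_expression <- function(x, ...) {
  ord <- attr(x, "row_order")
  m <- x[ord, , drop = FALSE]
  lim <- max(abs(range(m)), 1e-6)
  pal <- grDevices::colorRampPalette(c("#d95f02", "white", "#1f6fb4"))(101)
  graphics::image(t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                  col = pal, zlim = c(-lim, lim), axes = FALSE,
                  xlab = "topics", ylab = "", ...)
  graphics::axis(2, at = seq(1, 0, length.out = nrow(m)),
                 labels = rownames(m), las = 2, cex.axis = 0.7, tick = FALSE)
  invisible(x)
}

#' Export word lists for the most predictive topics per condition
#'
#' For each condition, selects the `top_k_topics` topics with the largest
#' `auc_demo_plus_topic` among those passing the BH threshold and returns
#' their top-15 word lists with rank-proportional sizes (the data behind a
#' word-cloud figure; rendering aesthetics are out of scope).
#'
#' @param model a `topic_model`.
#' @param marker_results named list of `marker_scan` data frames.
#' @param top_k_topics topics to export per condition.
#' @param n_words words per topic (default 15).
#' @return named list (per condition) of lists with `topic`,
#'   `auc_demo_plus_topic`, `adjusted_p`, `direction` and `words` (data
#'   frame from [top_words()]).
#' @export
export_wordclouds <- function(model, marker_results, top_k_topics,
                              n_words = 15) {
  stopifnot(inherits(model, "topic_model"))
  lapply(marker_results, function(r) {
    r <- r[r$significant, , drop = FALSE]
    r <- r[order(-r$auc_demo_plus_topic, r$topic), , drop = FALSE]
    r <- head(r, top_k_topics)
    lapply(seq_len(nrow(r)), function(i)
      list(topic = r$topic[i],
           auc_demo_plus_topic = r$auc_demo_plus_topic[i],
           adjusted_p = r$adjusted_p[i],
           direction = r$direction[i],
           words = top_words(model, r$topic[i], n_words)))
  })
}
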