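#' Fit language, demographics and ensemble condition models for a cohort
#'
#' The package's main fitting function. Encodes the cohort's language
#' (n-gram relative frequencies, an LDA topic model and participant topic
#' scores), then, for each retained condition, estimates out-of-sample
#' discrimination (AUC) of three models under stratified k-fold
#' cross-validation: (1) language only — extremely randomized trees over
#' topic scores plus per-fold FWER-selected grams; (2) demographics only —
#' ridge logistic over age, sex, race; (3) their AUC-weighted ensemble.
#' Differences between AUCs get Monte-Carlo permutation p-values (paired
#' sign-flip for model vs model, label permutation for model vs chance),
#' Benjamini-Hochberg adjusted across conditions within each comparison
#' family.
#'
#' @param corpus a `participant_corpus`.
#' @param demographics data frame with `participant_id`, `age`, `sex`,
#'   `race`.
#' @param conditions a `condition_panel`, or a binary labels matrix with
#'   participant row names.
#' @param n_topics LDA topics (default 200).
#' @param max_vocab candidate gram vocabulary size (default 20000).
#' @param k_select grams selected per training fold (default 500).
#' @param n_estimators trees in the language model (default 1000).
#' @param penalty ridge penalty (default 1).
#' @param k_folds cross-validation folds (default 10).
#' @param n_perm permutation iterations (default 100000).
#' @param min_words minimum words per participant (default 500).
#' @param min_cases minimum cases per evaluated condition (default 30).
#' @param lda_sweeps Gibbs sweeps for the topic model (default 300).
#' @param alpha BH level for the significance flags (default 0.05).
#' @param seed integer seed governing every random stage.
#' @param topic_model optionally, a pre-fitted `topic_model` to use instead
#'   of fitting LDA on this corpus.
#' @return an object of class `langdx`: list with `results` (one row per
#'   condition: the three AUCs, raw and adjusted p-values, case counts),
#'   `encoding` (`ngrams`, `topic_model`, `topic_scores`), `cv` (per
#'   condition: out-of-fold scores, fold assignment, row subset),
#'   `demographics`, `labels`, `params`, `seed`, `call`.
#' @seealso [scan_markers()], [simulate_cohort()], [run_pipeline()]
#' @export
langdx <- function(corpus, demographics, conditions,
                   n_topics = 200, max_vocab = 20000, k_select = 500,
                   n_estimators = 1000, penalty = 1, k_folds = 10,
                   n_perm = 100000, min_words = 500, min_cases = 30,
                   lda_sweeps = 300, alpha = 0.05, seed = 1,
                   topic_model = NULL) {
  cl <- match.call()
  corpus <- filter_min_words(corpus, min_words)
  if (!length(corpus))
    stop_langdx("no participants pass the word-count filter",
                "langdx_empty_corpus")
  ids <- names(corpus)
  demographics <- demographics[match(ids, demographics$participant_id), ,
                               drop = FALSE]
  if (anyNA(demographics$participant_id))
    stop_langdx("demographics missing for some participants",
                "langdx_invalid_input")
  if (inherits(conditions, "condition_panel")) {
    labels <- conditions$labels
    sex_restrictions <- conditions$sex_restrictions
  } else {
    labels <- as.matrix(conditions)
    sex_restrictions <- attr(conditions, "sex_restrictions") %||% character(0)
  }
  if (is.null(rownames(labels)))
    stop_langdx("condition labels need participant row names",
                "langdx_invalid_input")
  labels <- labels[match(ids, rownames(labels)), , drop = FALSE]

  ngrams <- extract_ngrams(corpus, max_vocab = max_vocab)
  ufreq <- unigram_frequencies(corpus)
  tm <- topic_model %||% fit_lda(corpus, n_topics = n_topics,
                                 n_sweeps = lda_sweeps, seed = seed)
  scores <- score_topics(tm, ufreq)

  res <- list(); cv_store <- list()
  for (cond in colnames(labels)) {
    keep <- rep(TRUE, length(ids))
    if (cond %in% names(sex_restrictions))
      keep <- demographics$sex == sex_restrictions[[cond]]
    y <- labels[keep, cond]
    n_cases <- sum(y)
    if (n_cases < min_cases || sum(1 - y) < min_cases) {
      message("skipping '", cond, "': fewer than ", min_cases,
              " cases or controls after filters")
      next
    }
    folds <- stratified_kfold(y, k = k_folds, seed = seed)
    cv <- cross_validated_scores(ngrams$frequencies[keep, , drop = FALSE],
                                 scores[keep, , drop = FALSE],
                                 demographics[keep, , drop = FALSE],
                                 y, folds, k_select = k_select,
                                 n_estimators = n_estimators,
                                 penalty = penalty, seed = seed)
    ok <- !is.na(cv$p_lang)
    row <- data.frame(
      condition = cond, n = sum(keep), n_cases = n_cases,
      auc_language = auc(cv$p_lang[ok], y[ok]),
      auc_demographics = auc(cv$p_demo[ok], y[ok]),
      auc_combined = auc(cv$p_combined[ok], y[ok]),
      p_lang_vs_demo = perm_test_auc_diff(cv$p_lang[ok], cv$p_demo[ok],
                                          y[ok], n_iter = n_perm,
                                          seed = seed + 11L),
      p_combined_vs_demo = perm_test_auc_diff(cv$p_combined[ok],
                                              cv$p_demo[ok], y[ok],
                                              n_iter = n_perm,
                                              seed = seed + 13L),
      p_lang_vs_chance = perm_test_auc_vs_chance(cv$p_lang[ok], y[ok],
                                                 n_iter = n_perm,
                                                 seed = seed + 17L),
      stringsAsFactors = FALSE)
    res[[cond]] <- row
    cv_store[[cond]] <- c(cv, list(folds = folds, keep = keep, labels = y))
  }
  if (!length(res))
    stop_langdx("no condition passed the case-count filter",
                "langdx_invalid_input")
  results <- do.call(rbind, res)
  rownames(results) <- NULL
  for (fam in c("p_lang_vs_demo", "p_combined_vs_demo", "p_lang_vs_chance")) {
    bh <- bh_fdr(results[[fam]], alpha = alpha)
    results[[paste0(fam, "_adj")]] <- bh$adjusted_p
    results[[paste0(sub("^p_", "sig_", fam))]] <- bh$rejected
  }
  results <- results[order(-(results$auc_language -
                               results$auc_demographics)), ]
  rownames(results) <- NULL
  structure(list(results = results,
                 encoding = list(ngrams = ngrams, topic_model = tm,
                                 topic_scores = scores,
                                 unigram_frequencies = ufreq),
                 cv = cv_store,
                 demographics = demographics, labels = labels,
                 sex_restrictions = sex_restrictions,
                 params = list(n_topics = tm$n_topics, max_vocab = max_vocab,
                               k_select = k_select,
                               n_estimators = n_estimators,
                               penalty = penalty, k_folds = k_folds,
                               n_perm = n_perm, min_words = min_words,
                               min_cases = min_cases,
                               lda_sweeps = lda_sweeps, alpha = alpha),
                 seed = seed, call = cl),
            class = "langdx")
}

#' @export
print.langdx <- function(x, ...) {
  cat("langdx fit:", nrow(x$results), "conditions,",
      nrow(x$demographics), "participants\n")
  cat(sprintf("Language encoding: %d topic scores + %d selected grams (of %d candidates)\n",
              x$params$n_topics, x$params$k_select,
              length(x$encoding$ngrams$vocabulary)))
  df <- x$results[, c("condition", "n_cases", "auc_language",
                      "auc_demographics", "auc_combined")]
  print(df, digits = 3, row.names = FALSE)
  invisible(x)
}

#' @param object,x a `langdx` fit.
#' @param ... unused.
#' @rdname langdx
#' @export
summary.langdx <- function(object, ...) {
  r <- object$results
  cat("Cross-validated AUCs (", object$params$k_folds, "-fold, seed ",
      object$seed, "):\n\n", sep = "")
  out <- data.frame(condition = r$condition, n_cases = r$n_cases,
                    language = round(r$auc_language, 3),
                    demographics = round(r$auc_demographics, 3),
                    combined = round(r$auc_combined, 3),
                    p_lang_vs_demo = signif(r$p_lang_vs_demo_adj, 3),
                    p_comb_vs_demo = signif(r$p_combined_vs_demo_adj, 3),
                    p_vs_chance = signif(r$p_lang_vs_chance_adj, 3))
  print(out, row.names = FALSE)
  cat("\n(p-values BH-adjusted across conditions within each comparison)\n")
  invisible(out)
}

#' @param type which out-of-fold predictions to return.
#' @param condition condition name (defaults to the first).
#' @param newdata unused (predictions are cross-validated, tied to the
#'   fitted cohort).
#' @rdname langdx
#' @export
predict.langdx <- function(object, condition = NULL,
                           type = c("combined", "language", "demographics"),
                           newdata = NULL, ...) {
  type <- match.arg(type)
  condition <- condition %||% names(object$cv)[1]
  cv <- object$cv[[condition]]
  if (is.null(cv))
    stop_langdx(paste("no fitted condition", condition),
                "langdx_invalid_input")
  switch(type, combined = cv$p_combined, language = cv$p_lang,
         demographics = cv$p_demo)
}

#' @rdname langdx
#' @export
plot.langdx <- function(x, ...) {
  r <- x$results
  m <- t(as.matrix(r[, c("auc_language", "auc_demographics",
                         "auc_combined")]))
  graphics::par(mar = c(9, 4, 2, 1))
  graphics::barplot(m, beside = TRUE, names.arg = r$condition, las = 2,
                    ylim = c(0, 1), ylab = "cross-validated AUC",
                    col = c("#1f6fb4", "#a6a6a6", "#33a02c"),
                    legend.text = c("language", "demographics", "combined"),
                    args.legend = list(x = "topright", bty = "n"), ...)
  graphics::abline(h = 0.5, lty = 2)
  invisible(x)
}

#' Scan every topic as a single-condition marker, for all fitted conditions
#'
#' Runs [topic_marker_scan()] per condition of a [langdx()] fit (honoring
#' sex restrictions), assembles the signed topic-expression matrix, and
#' computes top/bottom quartile likelihood ratios with bootstrap confidence
#' intervals for each condition's best significant topic.
#'
#' @param fit a `langdx` object.
#' @param n_iter permutation iterations per topic (default 10000).
#' @param n_boot bootstrap iterations for quartile ratios (default 10000).
#' @param top_k_topics topics per condition in the word-cloud export.
#' @param seed integer seed (defaults to the fit's seed).
#' @return an object of class `langdx_markers`: `scans` (named list of
#'   `marker_scan` frames), `expression` (from
#'   [topic_expression_matrix()]), `quartile_ratios` (named list of
#'   `quartile_ratio`), `wordclouds`.
#' @export
scan_markers <- function(fit, n_iter = 10000, n_boot = 10000,
                         top_k_topics = 5, seed = NULL) {
  stopifnot(inherits(fit, "langdx"))
  seed <- seed %||% fit$seed
  scans <- list(); ratios <- list()
  for (cond in names(fit$cv)) {
    keep <- fit$cv[[cond]]$keep
    y <- fit$cv[[cond]]$labels
    sc <- fit$encoding$topic_scores[keep, , drop = FALSE]
    scans[[cond]] <- topic_marker_scan(sc,
                                       fit$demographics[keep, , drop = FALSE],
                                       y, k = fit$params$k_folds,
                                       n_iter = n_iter,
                                       penalty = fit$params$penalty,
                                       alpha = fit$params$alpha, seed = seed)
    sig <- scans[[cond]][scans[[cond]]$significant, , drop = FALSE]
    if (nrow(sig)) {
      best <- sig$topic[which.max(sig$auc_demo_plus_topic)]
      ratios[[cond]] <- quartile_ratio(sc[, best], y, n_boot = n_boot,
                                       seed = seed)
      ratios[[cond]]$topic <- best
    }
  }
  structure(list(scans = scans,
                 expression = topic_expression_matrix(scans),
                 quartile_ratios = ratios,
                 wordclouds = export_wordclouds(fit$encoding$topic_model,
                                                scans, top_k_topics)),
            class = "langdx_markers")
}

#' @export
print.langdx_markers <- function(x, ...) {
  cat("Topic marker scan over", length(x$scans), "conditions x",
      nrow(x$scans[[1]]), "topics\n")
  for (cond in names(x$scans)) {
    s <- x$scans[[cond]]
    cat(sprintf("  %s: %d significant topics (best added AUC %.3f)\n",
                cond, sum(s$significant), max(s$auc_demo_plus_topic)))
  }
  invisible(x)
}

#' @export
plot.langdx_markers <- function(x, ...) {
  plot(x$expression, ...)
}
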