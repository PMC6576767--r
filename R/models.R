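#' Encode a demographics table as a numeric model matrix
#'
#' Age is standardized (optionally with supplied center/scale, so held-out
#' rows can be encoded with training-fold statistics), sex is binary
#' (female = 1), race is one-hot with the first level as the dropped
#' reference category.
#'
#' @param demographics data frame with `age`, `sex`, `race`.
#' @param race_levels race category levels; defaults to the observed
#'   levels in order of appearance. First level is the reference.
#' @param age_center,age_scale standardization constants; defaults to the
#'   sample mean / sd of `age`.
#' @return numeric matrix with columns `age`, `sex_female`, `race_*`, plus
#'   attributes `age_center`, `age_scale`, `race_levels`.
#' @export
encode_demographics <- function(demographics, race_levels = NULL,
                                age_center = NULL, age_scale = NULL) {
  race_levels <- race_levels %||% unique(as.character(demographics$race))
  age_center <- age_center %||% mean(demographics$age)
  age_scale <- age_scale %||% max(sd(demographics$age), 1e-12)
  race <- factor(demographics$race, levels = race_levels)
  oh <- outer(race, race_levels[-1], `==`) * 1
  colnames(oh) <- paste0("race_", race_levels[-1])
  x <- cbind(age = (demographics$age - age_center) / age_scale,
             sex_female = as.integer(demographics$sex == "female"), oh)
  rownames(x) <- demographics$participant_id
  attr(x, "age_center") <- age_center
  attr(x, "age_scale") <- age_scale
  attr(x, "race_levels") <- race_levels
  x
}

#' Select the grams most associated with a condition (FWER ranking)
#'
#' For each gram, tests the univariate association between its relative
#' frequency and the binary label with a point-biserial correlation test
#' (two-sided), Bonferroni-adjusts the p-values across all grams
#' (family-wise error rate), and returns the `k` grams with the smallest
#' adjusted p-values (ties broken by raw p, then lexicographic gram).
#' Intended to be run on training-fold rows only, inside cross-validation.
#'
#' @param gram_matrix matrix or sparse matrix of per-participant gram
#'   frequencies (training rows only), or an `ngram_features` object.
#' @param labels binary 0/1 vector for the training rows.
#' @param k number of grams to keep (default 500; clamped to the number of
#'   grams).
#' @return an object of class `fwer_selection`: `indices` (column indices
#'   into the candidate matrix, best first), `grams`, `adjusted_p`,
#'   `raw_p` for the selected grams.
#' @export
fwer_select <- function(gram_matrix, labels, k = 500) {
  if (inherits(gram_matrix, "ngram_features"))
    gram_matrix <- gram_matrix$frequencies
  y <- check_binary_labels(labels)
  n <- nrow(gram_matrix)
  if (length(y) != n)
    stop_langdx("labels length must match rows", "langdx_invalid_input")
  m <- ncol(gram_matrix)
  yc <- y - mean(y)
  cs <- as.numeric(Matrix::colSums(gram_matrix))
  cs2 <- as.numeric(Matrix::colSums(gram_matrix^2))
  sxx <- cs2 - cs^2 / n
  sxy <- as.numeric(Matrix::crossprod(gram_matrix, yc))
  syy <- sum(yc^2)
  r <- sxy / sqrt(pmax(sxx * syy, 1e-300))
  r[sxx <= 0] <- 0
  r <- pmin(pmax(r, -1), 1)
  tt <- r * sqrt(pmax(n - 2, 1) / pmax(1 - r^2, 1e-300))
  raw_p <- 2 * pt(-abs(tt), df = max(n - 2, 1))
  raw_p[sxx <= 0] <- 1
  adj_p <- pmin(raw_p * m, 1)
  grams <- colnames(gram_matrix) %||% as.character(seq_len(m))
  ord <- c_order(adj_p, raw_p, grams)
  idx <- head(ord, min(k, m))
  structure(list(indices = idx, grams = grams[idx],
                 adjusted_p = adj_p[idx], raw_p = raw_p[idx],
                 n_candidates = m),
            class = "fwer_selection")
}

#' Fit the language model: extremely randomized trees
#'
#' An extremely-randomized-trees (ERT) classifier over the participant
#' language encoding (topic scores plus selected gram frequencies): 1000
#' estimators grown on the full training sample (no bootstrap), one uniform
#' random threshold per candidate feature at each node, candidates scored
#' by Gini impurity decrease, sqrt(d) candidate features per split, trees
#' grown until pure. Predicted probability is the mean over trees of the
#' leaf positive frequency. The fitted object records its in-sample
#' training AUC, used downstream as the ensemble weight.
#'
#' @param X numeric feature matrix (training rows).
#' @param y binary 0/1 labels.
#' @param n_estimators number of trees (default 1000).
#' @param seed integer seed (reproducible fits and predictions).
#' @param mtry candidate features per split; default `ceiling(sqrt(ncol))`.
#' @param min_node_size stop splitting nodes at or below this size
#'   (default 1, fully grown trees).
#' @return an object of class `langdx_model` with `kind = "language-trees"`,
#'   the fitted forest, and `train_auc`.
#' @export
fit_language_trees <- function(X, y, n_estimators = 1000, seed = 1,
                               mtry = NULL, min_node_size = 1) {
  X <- as.matrix(X)
  if (!nrow(X) || !ncol(X))
    stop_langdx("empty feature matrix", "langdx_invalid_input")
  y <- check_binary_labels(y)
  storage.mode(X) <- "double"
  set.seed(seed)
  fit <- ert_fit_cpp(X, y, as.integer(n_estimators),
                     as.integer(mtry %||% ceiling(sqrt(ncol(X)))),
                     as.integer(min_node_size))
  p_train <- ert_predict_cpp(fit, X)
  structure(list(kind = "language-trees", fit = fit,
                 n_features = ncol(X),
                 train_auc = auc(p_train, y)),
            class = "langdx_model")
}

#' Fit the demographics model: ridge-penalized logistic regression
#'
#' An L2-penalized logistic regression, suited to the small demographic
#' predictor set (standardized age, sex, race indicators).
#'
#' @param X_demo numeric demographics matrix (see [encode_demographics()]).
#' @param y binary 0/1 labels.
#' @param penalty ridge penalty (glmnet `lambda`; default 1).
#' @return an object of class `langdx_model` with `kind =
#'   "demographics-ridge"` and `train_auc`.
#' @export
fit_demographics_ridge <- function(X_demo, y, penalty = 1) {
  y <- check_binary_labels(y)
  X_demo <- as.matrix(X_demo)
  if (!nrow(X_demo) || !ncol(X_demo))
    stop_langdx("empty demographics matrix", "langdx_invalid_input")
  if (penalty <= 0)
    stop_langdx("penalty must be > 0", "langdx_invalid_parameter")
  fit <- glmnet::glmnet(X_demo, factor(y, levels = c(0, 1)),
                        family = "binomial", alpha = 0,
                        lambda = penalty, standardize = FALSE)
  p_train <- drop(stats::predict(fit, X_demo, type = "response"))
  structure(list(kind = "demographics-ridge", fit = fit, penalty = penalty,
                 n_features = ncol(X_demo),
                 train_auc = auc(p_train, y)),
            class = "langdx_model")
}

#' @export
print.langdx_model <- function(x, ...) {
  cat(sprintf("langdx %s model: %d features, training AUC %.3f\n",
              x$kind, x$n_features, x$train_auc))
  invisible(x)
}

#' @param object a `langdx_model`.
#' @param newdata feature matrix to predict on.
#' @param ... unused.
#' @return vector of predicted probabilities in \[0, 1\].
#' @rdname fit_language_trees
#' @export
predict.langdx_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (object$kind == "language-trees") {
    storage.mode(newdata) <- "double"
    if (ncol(newdata) != object$n_features)
      stop_langdx("newdata has the wrong number of features",
                  "langdx_invalid_input")
    ert_predict_cpp(object$fit, newdata)
  } else {
    drop(stats::predict(object$fit, newdata, type = "response"))
  }
}

#' AUC-weighted ensemble of two probability vectors
#'
#' Combines the language-model and demographics-model predicted
#' probabilities as a weighted average, each model weighted by its AUC over
#' the training set:
#' `p = (auc_lang * p_lang + auc_demo * p_demo) / (auc_lang + auc_demo)`.
#'
#' @param p_lang,p_demo probability vectors of equal length.
#' @param auc_lang_train,auc_demo_train training-set AUCs in \[0, 1\]; must
#'   not both be zero.
#' @return the combined probability vector (a convex combination, so always
#'   within the elementwise range of the two inputs).
#' @examples
#' ensemble_predict(1.0, 0.5, 0.8, 0.6)  # (0.8*1 + 0.6*0.5) / 1.4
#' @export
ensemble_predict <- function(p_lang, p_demo, auc_lang_train, auc_demo_train) {
  if (length(p_lang) != length(p_demo))
    stop_langdx("probability vectors differ in length", "langdx_invalid_input")
  if (auc_lang_train < 0 || auc_lang_train > 1 ||
      auc_demo_train < 0 || auc_demo_train > 1)
    stop_langdx("training AUCs must lie in [0, 1]", "langdx_invalid_input")
  w <- auc_lang_train + auc_demo_train
  if (w == 0)
    stop_langdx("training AUC weights are both zero", "langdx_invalid_weights")
  (auc_lang_train * p_lang + auc_demo_train * p_demo) / w
}
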