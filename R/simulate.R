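#' Configuration for the synthetic cohort generator
#'
#' Builds a validated configuration object describing a synthetic study
#' cohort: a topic-mixture language model over a synthetic vocabulary,
#' demographics (age, sex, race), and binary condition labels drawn from a
#' logistic outcome model with planted topic and demographic effects. The
#' generator exists to give every downstream stage (encoding, prediction,
#' marker identification) a ground-truth recovery surface; it makes no
#' attempt to mimic real social-media style.
#'
#' @param n_participants number of participants.
#' @param vocab_size size of the synthetic vocabulary (tokens `w001`, ...).
#' @param n_topics_true number of true topics in the generative model.
#' @param words_per_participant fixed word count per participant, or a list
#'   `list(dist = "lognormal", meanlog =, sdlog =, min =)` for heavy-tailed
#'   verbosity. Default fixed, for determinism.
#' @param posts_per_participant number of posts each participant's words are
#'   partitioned into (uniformly at random; bigrams never cross posts).
#' @param topic_concentration symmetric Dirichlet parameter for topic-word
#'   rows; small values give well-separated topics.
#' @param mixture_concentration symmetric Dirichlet parameter for
#'   per-participant topic mixtures theta.
#' @param demographics list with `age_range` (two integers), `p_female`
#'   (proportion), `race_levels` and `race_probs` (categorical proportions
#'   summing to 1; first level is the reference category).
#' @param condition_effects list of conditions, each
#'   `list(name =, intercept =, topic_coefs = <length n_topics_true>,
#'   demo_coefs = <length of encoded demographics>)`. The encoded
#'   demographic vector is (age scaled to -1..1 over `age_range`,
#'   sex female = 1, race one-hot without the reference level).
#' @param realistic_text if `TRUE`, emitted posts capitalize the first word
#'   and end with punctuation so that the tokenizer is exercised; default
#'   `FALSE` emits bare tokens so tokenization is exact.
#'
#' @return an object of class `cohort_config`.
#' @seealso [simulate_cohort()]
#' @export
cohort_config <- function(n_participants = 1000,
                          vocab_size = 500,
                          n_topics_true = 20,
                          words_per_participant = 600,
                          posts_per_participant = 20,
                          topic_concentration = 0.01,
                          mixture_concentration = 0.1,
                          demographics = list(
                            age_range = c(18L, 65L),
                            p_female = 0.76,
                            race_levels = c("black", "white", "asian", "other"),
                            race_probs = c(0.71, 0.23, 0.02, 0.04)),
                          condition_effects = list(),
                          realistic_text = FALSE) {
  counts <- c(n_participants = n_participants, vocab_size = vocab_size,
              n_topics_true = n_topics_true,
              posts_per_participant = posts_per_participant)
  if (any(counts < 1))
    stop_langdx("all counts must be >= 1", "langdx_invalid_parameter")
  if (vocab_size < 2)
    stop_langdx("vocab_size must be >= 2", "langdx_invalid_parameter")
  if (topic_concentration <= 0 || mixture_concentration <= 0)
    stop_langdx("concentrations must be > 0", "langdx_invalid_parameter")
  if (is.numeric(words_per_participant)) {
    if (words_per_participant < 1)
      stop_langdx("words_per_participant must be >= 1",
                  "langdx_invalid_parameter")
  } else if (!is.list(words_per_participant) ||
             !identical(words_per_participant$dist, "lognormal")) {
    stop_langdx("words_per_participant must be a count or a lognormal spec",
                "langdx_invalid_parameter")
  }
  d <- demographics
  if (abs(sum(d$race_probs) - 1) > 1e-9 || any(d$race_probs < 0) ||
      d$p_female < 0 || d$p_female > 1)
    stop_langdx("demographic proportions must lie in [0,1] and sum to 1",
                "langdx_invalid_parameter")
  if (length(d$race_levels) != length(d$race_probs))
    stop_langdx("race_levels and race_probs lengths differ",
                "langdx_invalid_parameter")
  demo_dim <- 2L + length(d$race_levels) - 1L
  for (ce in condition_effects) {
    if (is.null(ce$name) || is.null(ce$intercept))
      stop_langdx("each condition effect needs a name and intercept",
                  "langdx_invalid_parameter")
    if (length(ce$topic_coefs %||% numeric(n_topics_true)) != n_topics_true)
      stop_langdx(sprintf("topic_coefs for '%s' must have length %d",
                          ce$name, n_topics_true), "langdx_invalid_parameter")
    if (length(ce$demo_coefs %||% numeric(demo_dim)) != demo_dim)
      stop_langdx(sprintf("demo_coefs for '%s' must have length %d",
                          ce$name, demo_dim), "langdx_invalid_parameter")
  }
  structure(list(n_participants = as.integer(n_participants),
                 vocab_size = as.integer(vocab_size),
                 n_topics_true = as.integer(n_topics_true),
                 words_per_participant = words_per_participant,
                 posts_per_participant = as.integer(posts_per_participant),
                 topic_concentration = topic_concentration,
                 mixture_concentration = mixture_concentration,
                 demographics = d,
                 condition_effects = condition_effects,
                 realistic_text = isTRUE(realistic_text)),
            class = "cohort_config")
}

#' Helper: a condition-effect entry for [cohort_config()]
#'
#' @param name condition name.
#' @param intercept logistic-model intercept (log-odds at mean covariates).
#' @param topic_coefs coefficients on the true topic mixture theta; a named
#'   assignment like `topic_coefs = c("3" = 3)` places a single coefficient
#'   on topic 3.
#' @param demo_coefs coefficients on the encoded demographics.
#' @param n_topics,demo_dim dimensions used to expand sparse assignments.
#' @return a list suitable for `condition_effects`.
#' @export
condition_effect <- function(name, intercept = 0, topic_coefs = NULL,
                             demo_coefs = NULL, n_topics = 20, demo_dim = 5) {
  if (is.list(topic_coefs)) topic_coefs <- unlist(topic_coefs)
  if (is.list(demo_coefs)) demo_coefs <- unlist(demo_coefs)
  tc <- numeric(n_topics)
  if (!is.null(topic_coefs)) {
    if (is.null(names(topic_coefs))) tc[seq_along(topic_coefs)] <- topic_coefs
    else tc[as.integer(names(topic_coefs))] <- topic_coefs
  }
  dc <- numeric(demo_dim)
  if (!is.null(demo_coefs)) {
    if (is.null(names(demo_coefs))) dc[seq_along(demo_coefs)] <- demo_coefs
    else dc[as.integer(names(demo_coefs))] <- demo_coefs
  }
  list(name = name, intercept = intercept, topic_coefs = tc, demo_coefs = dc)
}

#' Draw a topic-word probability matrix from a symmetric Dirichlet
#'
#' @param n_topics number of topics (rows).
#' @param vocab_size vocabulary size (columns); must be >= `n_topics`.
#' @param concentration symmetric Dirichlet concentration; must be > 0.
#' @param seed integer seed; same seed gives an identical matrix.
#' @return an `n_topics` x `vocab_size` stochastic matrix (rows sum to 1).
#' @export
generate_topic_word_matrix <- function(n_topics, vocab_size, concentration,
                                       seed) {
  if (concentration <= 0)
    stop_langdx("concentration must be > 0", "langdx_invalid_parameter")
  if (n_topics < 1 || vocab_size < n_topics)
    stop_langdx("need n_topics >= 1 and vocab_size >= n_topics",
                "langdx_invalid_parameter")
  set.seed(seed)
  m <- rdirichlet_sym(n_topics, vocab_size, concentration)
  dimnames(m) <- list(NULL, synthetic_vocab(vocab_size))
  m
}

#' @noRd
synthetic_vocab <- function(vocab_size) {
  sprintf(paste0("w%0", nchar(as.character(vocab_size)), "d"),
          seq_len(vocab_size))
}

#' Assign binary condition labels from a logistic outcome model
#'
#' For each configured condition, `P(y = 1) = plogis(intercept +
#' topic_coefs . theta + demo_coefs . x)` where `x` is the encoded
#' demographic vector; labels are Bernoulli draws. Draws use one uniform per
#' participant per condition compared against the probability, so raising an
#' intercept (same seed) can never lose a case.
#'
#' @param theta participant x topic mixture matrix (rows sum to 1).
#' @param demographics data frame with `age`, `sex`, `race`.
#' @param effects list of condition-effect entries (see [cohort_config()]).
#' @param seed integer seed.
#' @param age_range range used to scale age to \[-1, 1\].
#' @param race_levels category levels; first is the reference.
#' @return list with `labels` (n x n_conditions 0/1 matrix) and
#'   `probabilities` (matching matrix of realized P(y = 1)).
#' @export
assign_conditions <- function(theta, demographics, effects, seed,
                              age_range = c(18L, 65L),
                              race_levels = c("black", "white", "asian",
                                              "other")) {
  if (max(abs(rowSums(theta) - 1)) > 1e-6)
    stop_langdx("theta rows must sum to 1", "langdx_invalid_parameter")
  x <- encode_demographics_fixed(demographics, age_range, race_levels)
  n <- nrow(theta)
  probs <- labels <- matrix(0, n, length(effects),
                            dimnames = list(rownames(theta),
                                            vapply(effects, `[[`, "", "name")))
  set.seed(seed)
  u <- matrix(runif(n * length(effects)), n)
  for (j in seq_along(effects)) {
    ce <- effects[[j]]
    if (length(ce$topic_coefs) != ncol(theta) ||
        length(ce$demo_coefs) != ncol(x))
      stop_langdx(sprintf("effect vector length mismatch for '%s'", ce$name),
                  "langdx_invalid_parameter")
    eta <- ce$intercept + drop(theta %*% ce$topic_coefs + x %*% ce$demo_coefs)
    probs[, j] <- plogis(eta)
    labels[, j] <- as.integer(u[, j] < probs[, j])
  }
  list(labels = labels, probabilities = probs)
}

#' Fixed-range demographic encoding used by the generative outcome model
#' (deterministic, sample-independent: age scaled to -1..1 over the design
#' range; modelling code standardizes empirically instead).
#' @noRd
encode_demographics_fixed <- function(demographics, age_range, race_levels) {
  mid <- mean(age_range); half <- diff(range(age_range)) / 2
  race <- factor(demographics$race, levels = race_levels)
  oh <- outer(race, race_levels[-1], `==`) * 1
  colnames(oh) <- paste0("race_", race_levels[-1])
  cbind(age = (demographics$age - mid) / half,
        sex_female = as.integer(demographics$sex == "female"), oh)
}

#' Simulate a synthetic study cohort with known ground truth
#'
#' Draws a topic-word matrix, per-participant topic mixtures, word tokens,
#' demographics and condition labels under the configured generative model.
#' Each participant's words are drawn i.i.d. from their topic mixture
#' (topic ~ Categorical(theta), word ~ Categorical(topic row)) and
#' partitioned uniformly at random into posts.
#'
#' @param config a [cohort_config()] object.
#' @param seed integer seed; identical config + seed reproduce the cohort
#'   exactly.
#' @return an object of class `synthetic_cohort`: list with `corpus`
#'   (a `participant_corpus`), `demographics` (data frame), `labels`
#'   (matrix, possibly 0 columns), and `ground_truth` (list with
#'   `topic_word`, `theta`, `condition_effects`, `probabilities`).
#' @export
simulate_cohort <- function(config, seed) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_participants
  V <- config$vocab_size
  K <- config$n_topics_true
  vocab <- synthetic_vocab(V)
  topic_word <- generate_topic_word_matrix(K, V, config$topic_concentration,
                                           seed)
  set.seed(seed + 1L)
  theta <- rdirichlet_sym(n, K, config$mixture_concentration)
  ids <- sprintf(paste0("P%0", nchar(as.character(n)), "d"), seq_len(n))
  rownames(theta) <- ids

  wp <- config$words_per_participant
  if (is.numeric(wp)) {
    n_words <- rep(as.integer(wp), n)
  } else {
    n_words <- pmax(wp$min %||% 1,
                    as.integer(round(stats::rlnorm(n, wp$meanlog, wp$sdlog))))
  }

  posts <- vector("list", n)
  P <- config$posts_per_participant
  for (u in seq_len(n)) {
    zc <- drop(stats::rmultinom(1, n_words[u], theta[u, ]))
    words <- integer(n_words[u])
    pos <- 1L
    for (k in which(zc > 0)) {
      cnt <- drop(stats::rmultinom(1, zc[k], topic_word[k, ]))
      nz <- which(cnt > 0)
      ww <- rep.int(nz, cnt[nz])
      words[pos:(pos + zc[k] - 1L)] <- ww
      pos <- pos + zc[k]
    }
    words <- words[sample.int(n_words[u])]
    post_of <- sample.int(P, n_words[u], replace = TRUE)
    toks <- vocab[words]
    pl <- split(toks, factor(post_of, levels = seq_len(P)))
    names(pl) <- NULL
    posts[[u]] <- pl
  }

  d <- config$demographics
  demo <- data.frame(
    participant_id = ids,
    age = round(runif(n, d$age_range[1], d$age_range[2])),
    sex = ifelse(runif(n) < d$p_female, "female", "male"),
    race = sample(d$race_levels, n, replace = TRUE, prob = d$race_probs),
    stringsAsFactors = FALSE)

  if (length(config$condition_effects)) {
    cond <- assign_conditions(theta, demo, config$condition_effects,
                              seed = seed + 2L,
                              age_range = d$age_range,
                              race_levels = d$race_levels)
    labels <- cond$labels
    probabilities <- cond$probabilities
  } else {
    labels <- probabilities <- matrix(0, n, 0, dimnames = list(ids, NULL))
  }

  corpus <- participant_corpus(ids, posts,
                               realistic = config$realistic_text,
                               seed = seed + 3L)
  structure(list(corpus = corpus,
                 demographics = demo,
                 labels = labels,
                 ground_truth = list(topic_word = topic_word,
                                     theta = theta,
                                     condition_effects =
                                       config$condition_effects,
                                     probabilities = probabilities),
                 config = config, seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", length(x$corpus), "participants,",
      x$config$vocab_size, "word vocabulary,",
      x$config$n_topics_true, "true topics\n")
  if (ncol(x$labels))
    cat("Conditions:",
        paste(sprintf("%s (%d cases)", colnames(x$labels),
                      colSums(x$labels)), collapse = ", "), "\n")
  invisible(x)
}
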