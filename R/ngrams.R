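#' Extract unigram and bigram relative frequencies
#'
#' Counts all words (unigrams) and neighboring word pairs (bigrams; never
#' spanning a post boundary) per participant, keeps the `max_vocab` most
#' frequent grams corpus-wide (unigrams and bigrams pooled, ranked by total
#' count with ties broken lexicographically), and converts counts to
#' per-participant relative frequencies. Frequencies are normalized within
#' gram order: unigram counts over the participant's total unigrams, bigram
#' counts over total bigrams, so each order's (pre-truncation) frequencies
#' sum to 1 per participant.
#'
#' @param corpus a `participant_corpus`; must contain at least one word.
#' @param max_vocab maximum vocabulary size (default 20000).
#' @return an object of class `ngram_features`: list with `vocabulary`
#'   (character; bigrams are space-joined), `order` (1 or 2 per gram),
#'   `frequencies` (sparse participant x gram matrix),
#'   `participant_ids`, and `totals` (per-participant unigram and bigram
#'   token totals).
#' @export
extract_ngrams <- function(corpus, max_vocab = 20000) {
  if (!length(corpus))
    stop_langdx("corpus is empty", "langdx_empty_corpus")
  n <- length(corpus)
  ids <- names(corpus)
  uni <- vector("list", n)
  bi <- vector("list", n)
  for (u in seq_len(n)) {
    pl <- corpus[[u]]$posts
    uni[[u]] <- unlist(pl, use.names = FALSE)
    bi[[u]] <- unlist(lapply(pl, function(tok) {
      if (length(tok) < 2) character(0)
      else paste(tok[-length(tok)], tok[-1])
    }), use.names = FALSE)
  }
  n_uni <- lengths(uni)
  n_bi <- lengths(bi)
  if (sum(n_uni) == 0)
    stop_langdx("corpus contains zero words", "langdx_empty_corpus")

  count_matrix <- function(grams_by_user) {
    lens <- lengths(grams_by_user)
    all_g <- unlist(grams_by_user, use.names = FALSE)
    if (!length(all_g))
      return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                  dims = c(n, 0)))
    f <- factor(all_g)
    m <- Matrix::sparseMatrix(i = rep.int(seq_len(n), lens),
                              j = as.integer(f), x = 1,
                              dims = c(n, nlevels(f)))
    colnames(m) <- levels(f)
    m
  }
  cu <- count_matrix(uni)
  cb <- count_matrix(bi)

  vocab_all <- c(colnames(cu), colnames(cb))
  order_all <- rep(c(1L, 2L), c(ncol(cu), ncol(cb)))
  tot <- c(Matrix::colSums(cu), Matrix::colSums(cb))
  keep <- head(c_order(-tot, vocab_all), max_vocab)

  # per-order relative frequencies (guard empty-bigram participants)
  fu <- Matrix::Diagonal(x = 1 / pmax(n_uni, 1)) %*% cu
  fb <- Matrix::Diagonal(x = 1 / pmax(n_bi, 1)) %*% cb
  freq <- methods::as(cbind2(fu, fb)[, keep, drop = FALSE], "CsparseMatrix")
  dimnames(freq) <- list(ids, vocab_all[keep])

  structure(list(vocabulary = vocab_all[keep],
                 order = order_all[keep],
                 frequencies = freq,
                 participant_ids = ids,
                 totals = cbind(unigrams = n_uni, bigrams = n_bi)),
            class = "ngram_features")
}

#' @export
print.ngram_features <- function(x, ...) {
  cat("n-gram features:", length(x$participant_ids), "participants x",
      length(x$vocabulary), "grams (",
      sum(x$order == 1L), "unigrams,", sum(x$order == 2L), "bigrams )\n")
  invisible(x)
}

#' Per-participant unigram relative frequencies over the full vocabulary
#'
#' Utility used for topic scoring: p(word | participant) for every distinct
#' word in the corpus (no truncation), rows summing to 1.
#'
#' @param corpus a `participant_corpus`.
#' @return sparse participant x word matrix of relative frequencies.
#' @export
unigram_frequencies <- function(corpus) {
  if (!length(corpus))
    stop_langdx("corpus is empty", "langdx_empty_corpus")
  n <- length(corpus)
  toks <- lapply(corpus, function(p) unlist(p$posts, use.names = FALSE))
  lens <- lengths(toks)
  f <- factor(unlist(toks, use.names = FALSE))
  m <- Matrix::sparseMatrix(i = rep.int(seq_len(n), lens),
                            j = as.integer(f), x = 1,
                            dims = c(n, nlevels(f)))
  out <- methods::as(Matrix::Diagonal(x = 1 / pmax(lens, 1)) %*% m,
                     "CsparseMatrix")
  dimnames(out) <- list(names(corpus), levels(f))
  out
}
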