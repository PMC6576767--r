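#' Construct a participant corpus
#'
#' A `participant_corpus` is the package's container for per-participant
#' tokenized posts: a list with one element per participant, each holding
#' `participant_id`, `posts` (a list of character token vectors, one per
#' post) and `total_words`. Participant ids must be unique.
#'
#' @param ids character vector of unique participant ids.
#' @param posts list (one element per participant) of lists of token
#'   vectors, or of raw text strings when `realistic = TRUE`.
#' @param realistic if `TRUE`, posts are rendered as sentence-like text
#'   (first word capitalized, terminal punctuation) and re-tokenized with
#'   [tokenize()], so punctuation tokens appear in the corpus.
#' @param seed seed for the punctuation choice in realistic mode.
#' @return an object of class `participant_corpus`.
#' @export
participant_corpus <- function(ids, posts, realistic = FALSE, seed = NULL) {
  if (anyDuplicated(ids))
    stop_langdx("participant ids must be unique", "langdx_invalid_input")
  if (length(ids) != length(posts))
    stop_langdx("ids and posts lengths differ", "langdx_invalid_input")
  if (realistic) {
    if (!is.null(seed)) set.seed(seed)
    posts <- lapply(posts, function(pl) {
      lapply(pl, function(tok) {
        if (!length(tok)) return(character(0))
        txt <- paste(tok, collapse = " ")
        substr(txt, 1, 1) <- toupper(substr(txt, 1, 1))
        tokenize(paste0(txt, sample(c(".", "!", "?"), 1)))[[1]]
      })
    })
  }
  out <- mapply(function(id, pl) {
    pl <- lapply(pl, as.character)
    list(participant_id = id, posts = pl,
         total_words = sum(lengths(pl)))
  }, ids, posts, SIMPLIFY = FALSE)
  names(out) <- ids
  structure(out, class = "participant_corpus")
}

#' @export
print.participant_corpus <- function(x, ...) {
  tw <- total_words(x)
  cat("Participant corpus:", length(x), "participants,",
      sum(tw), "words total")
  if (length(x)) cat(" (median", stats::median(tw), "per participant)")
  cat("\n")
  invisible(x)
}

#' Total word count per participant
#' @param corpus a `participant_corpus`.
#' @return named integer vector.
#' @export
total_words <- function(corpus) {
  vapply(corpus, `[[`, numeric(1), "total_words")
}

#' @export
`[.participant_corpus` <- function(x, i) {
  structure(unclass(x)[i], class = "participant_corpus")
}

#' Drop participants with too few words
#'
#' Adequate language volume is required for a stable encoding; participants
#' whose posts total fewer than `min_words` words are removed. The
#' threshold is inclusive (a participant with exactly `min_words` words is
#' kept) and order is preserved.
#'
#' @param corpus a `participant_corpus`.
#' @param min_words minimum total word count (default 500).
#' @return the filtered `participant_corpus`.
#' @export
filter_min_words <- function(corpus, min_words = 500) {
  stopifnot(min_words >= 0)
  corpus[total_words(corpus) >= min_words]
}

#' Drop participants with too few posts
#'
#' Optional adequacy filter on the number of status updates; off by default
#' in the pipeline.
#'
#' @param corpus a `participant_corpus`.
#' @param min_posts minimum number of posts (inclusive).
#' @return the filtered `participant_corpus`.
#' @export
filter_min_posts <- function(corpus, min_posts = 20) {
  corpus[vapply(corpus, function(p) length(p$posts), numeric(1)) >= min_posts]
}
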