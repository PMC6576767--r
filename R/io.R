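#' Read posts from JSONL or CSV into a participant corpus
#'
#' JSONL input has one JSON object per line with fields `participant_id`
#' and `text`; CSV input has those columns. Posts are tokenized with
#' [tokenize()] and grouped by participant in order of first appearance.
#' Malformed JSONL lines are counted, reported with a message, and skipped.
#'
#' @param path file path (`.jsonl`/`.json` or `.csv`).
#' @return a `participant_corpus`.
#' @export
read_posts <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    df <- read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("participant_id", "text") %in% names(df)))
      stop_langdx("posts CSV needs participant_id and text columns",
                  "langdx_schema_error")
    pid <- as.character(df$participant_id)
    txt <- as.character(df$text)
  } else {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    parsed <- lapply(lines, function(l)
      tryCatch(jsonlite::fromJSON(l), error = function(e) NULL))
    bad <- vapply(parsed, function(p)
      is.null(p) || is.null(p$participant_id) || is.null(p$text),
      logical(1))
    if (any(bad))
      message(sum(bad), " malformed JSONL line(s) skipped")
    parsed <- parsed[!bad]
    pid <- vapply(parsed, function(p) as.character(p$participant_id), "")
    txt <- vapply(parsed, function(p) as.character(p$text), "")
  }
  if (!length(pid)) return(participant_corpus(character(0), list()))
  toks <- tokenize(txt)
  ids <- unique(pid)
  posts <- lapply(ids, function(id) toks[pid == id])
  participant_corpus(ids, posts)
}

#' Write a participant corpus as JSONL
#'
#' One JSON object per post (`participant_id`, `text`, tokens joined by
#' single spaces). Reading the file back with [read_posts()] recovers the
#' token sequences exactly for space-free tokens.
#'
#' @param corpus a `participant_corpus`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_posts <- function(corpus, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (p in corpus) {
    for (post in p$posts) {
      writeLines(jsonlite::toJSON(
        list(participant_id = p$participant_id,
             text = paste(post, collapse = " ")),
        auto_unbox = TRUE), con)
    }
  }
  invisible(path)
}

#' Read a demographics table
#'
#' @param path CSV with columns `participant_id`, `age`, `sex`, `race`.
#' @return data frame.
#' @export
read_demographics <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "age", "sex", "race")
  if (!all(need %in% names(df)))
    stop_langdx(paste("demographics CSV needs columns:",
                      paste(need, collapse = ", ")), "langdx_schema_error")
  df$participant_id <- as.character(df$participant_id)
  df
}

#' Write a synthetic cohort to a directory
#'
#' Emits `posts.jsonl`, `demographics.csv`, `labels.csv` and
#' `ground_truth.json` (topic-word matrix, theta, condition effects,
#' realized probabilities).
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_posts(cohort$corpus, file.path(dir, "posts.jsonl"))
  write.csv(cohort$demographics, file.path(dir, "demographics.csv"),
            row.names = FALSE)
  lab <- data.frame(participant_id = rownames(cohort$labels),
                    cohort$labels, check.names = FALSE)
  write.csv(lab, file.path(dir, "labels.csv"), row.names = FALSE)
  gt <- cohort$ground_truth
  jsonlite::write_json(
    list(topic_word = gt$topic_word, theta = gt$theta,
         condition_effects = gt$condition_effects,
         probabilities = gt$probabilities,
         seed = cohort$seed),
    file.path(dir, "ground_truth.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
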