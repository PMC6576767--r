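#' Tokenize raw post text
#'
#' Social-media-aware tokenization: text is lowercased; URLs and
#' user-handles are collapsed to the placeholder tokens `<url>` and
#' `<user>`; common emoticons (`:-)`, `:(`, `;)`, `<3`, ...) are kept as
#' single tokens; words keep internal apostrophes (`i'm`), so slang,
#' misspellings and contraction variants survive intact; runs of other
#' punctuation become their own tokens. No stop-word removal, stemming or
#' spelling correction is applied.
#'
#' @param text character vector of raw post texts.
#' @return a list of character token vectors, one per input string; empty
#'   strings give empty vectors.
#' @examples
#' tokenize("Sick of this!")          # "sick" "of" "this" "!"
#' tokenize("c u there :-) @bob")     # "c" "u" "there" ":-)" "<user>"
#' @export
tokenize <- function(text) {
  text <- tolower(as.character(text))
  text <- gsub("(https?://|www\\.)[^[:space:]]+", " <url> ", text)
  text <- gsub("(^|[[:space:]])@[[:alnum:]_]+", "\\1 <user> ", text)
  pat <- paste0(
    "<(?:url|user)>",                        # placeholders
    "|<3",                                   # heart
    "|[:;=8][-o^']?[)(\\]\\[dpc/\\\\|*]",    # emoticons like :-) ;d =(
    "|[)(\\]\\[dp][-o^']?[:;=8]",            # reversed emoticons
    "|[a-z0-9_]+(?:'[a-z0-9]+)*",            # words incl. contractions
    "|[^a-z0-9_[:space:]]+"                  # punctuation runs
  )
  m <- gregexpr(pat, text, perl = TRUE)
  out <- regmatches(text, m)
  lapply(out, function(x) x[nzchar(x)])
}
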