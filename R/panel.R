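#' Build a condition panel from diagnoses
#'
#' Turns per-participant diagnosis data into a binary condition-category
#' label matrix. Input is either a pre-grouped binary matrix (data frame
#' with `participant_id` plus one 0/1 column per category) or a long table
#' of raw ICD-9 codes (`participant_id`, `code`) together with a
#' code-to-category mapping (`code`, `category`; a mapping code ending in
#' `x` such as `250.x` matches by prefix). A participant is positive for a
#' category if any of their codes maps to it. Categories attributed to
#' fewer than `min_cases` participants are dropped (with a message), and
#' sex restrictions (e.g. pregnancy evaluated in females only) are carried
#' as metadata for the evaluation stage.
#'
#' @param diagnoses data frame: pre-grouped binary, or long codes.
#' @param mapping optional data frame with `code`, `category`.
#' @param participant_ids ids defining row order of the panel; defaults to
#'   the ids present in `diagnoses`.
#' @param min_cases minimum cases per retained category (default 30).
#' @param sex_restrictions named character vector, e.g.
#'   `c(pregnancy = "female")`.
#' @param strict if `TRUE`, a code with no mapping is an error; otherwise
#'   unmapped codes are counted and ignored with a message.
#'
#' @details An illustrative (synthetic, not clinically curated) mapping file
#'   ships with the package:
#'   `system.file("extdata", "example_code_mapping.csv", package = "langdx")`.
#'   Real analyses should supply a curated comorbidity-index mapping.
#' @return an object of class `condition_panel`: `participant_ids`,
#'   `labels` (0/1 matrix), `case_counts`, `dropped` (categories below
#'   `min_cases`), `sex_restrictions`, `n_unmapped`.
#' @export
build_condition_panel <- function(diagnoses, mapping = NULL,
                                  participant_ids = NULL, min_cases = 30,
                                  sex_restrictions = NULL, strict = FALSE) {
  if (!"participant_id" %in% names(diagnoses))
    stop_langdx("diagnoses must have a participant_id column",
                "langdx_schema_error")
  n_unmapped <- 0L
  if (!is.null(mapping) || "code" %in% names(diagnoses)) {
    if (is.null(mapping) || !all(c("code", "category") %in% names(mapping)))
      stop_langdx("code-level diagnoses need a mapping with code, category",
                  "langdx_schema_error")
    codes <- as.character(diagnoses$code)
    map_code <- as.character(mapping$code)
    is_prefix <- grepl("x$", map_code, ignore.case = TRUE)
    prefix <- sub("x$", "", map_code, ignore.case = TRUE)
    cat_of <- lapply(codes, function(cd) {
      hit <- map_code == cd | (is_prefix & startsWith(cd, prefix))
      unique(mapping$category[hit])
    })
    n_unmapped <- sum(lengths(cat_of) == 0)
    if (n_unmapped > 0) {
      if (strict)
        stop_langdx(sprintf("%d diagnosis codes have no mapping", n_unmapped),
                    "langdx_unmapped_code")
      message(n_unmapped, " diagnosis code(s) had no mapping and were ignored")
    }
    pid <- rep(diagnoses$participant_id, lengths(cat_of))
    cat <- unlist(cat_of, use.names = FALSE)
    ids <- participant_ids %||% unique(diagnoses$participant_id)
    cats <- sort(unique(as.character(mapping$category)))
    labels <- matrix(0L, length(ids), length(cats),
                     dimnames = list(ids, cats))
    if (length(pid)) {
      keep <- pid %in% ids
      labels[cbind(match(pid[keep], ids), match(cat[keep], cats))] <- 1L
    }
  } else {
    ids <- participant_ids %||% diagnoses$participant_id
    cats <- setdiff(names(diagnoses), "participant_id")
    labels <- as.matrix(diagnoses[match(ids, diagnoses$participant_id),
                                  cats, drop = FALSE])
    labels[is.na(labels)] <- 0L
    if (!all(labels %in% c(0, 1)))
      stop_langdx("pre-grouped diagnosis columns must be binary 0/1",
                  "langdx_schema_error")
    storage.mode(labels) <- "integer"
    rownames(labels) <- ids
  }
  counts <- colSums(labels)
  dropped <- colnames(labels)[counts < min_cases]
  if (length(dropped))
    message("dropping ", length(dropped), " categor",
            if (length(dropped) == 1) "y" else "ies",
            " below ", min_cases, " cases: ",
            paste(dropped, collapse = ", "))
  labels <- labels[, counts >= min_cases, drop = FALSE]
  structure(list(participant_ids = ids, labels = labels,
                 case_counts = colSums(labels), dropped = dropped,
                 sex_restrictions = sex_restrictions %||% character(0),
                 n_unmapped = n_unmapped, min_cases = min_cases),
            class = "condition_panel")
}

#' @export
print.condition_panel <- function(x, ...) {
  cat("Condition panel:", length(x$participant_ids), "participants,",
      ncol(x$labels), "retained categories (min", x$min_cases, "cases)\n")
  if (ncol(x$labels))
    print(x$case_counts)
  if (length(x$dropped))
    cat("Dropped:", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}
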