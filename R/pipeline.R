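#' Run the full analysis pipeline from a configuration
#'
#' Executes simulate/read -> filter -> encode -> evaluate -> markers and
#' writes all result artifacts plus a machine-readable run manifest to the
#' output directory. The configuration is a named list (or a path to a
#' JSON/YAML file) with:
#' \describe{
#'   \item{seed}{required integer; validated before any computation.}
#'   \item{simulate}{arguments for [cohort_config()] (with
#'     `condition_effects` entries as for [condition_effect()]); mutually
#'     exclusive with `input`.}
#'   \item{input}{list of paths: `posts`, `demographics`, `labels` (a
#'     pre-grouped binary CSV) or `diagnoses` + `mapping` (ICD-9 codes).}
#'   \item{params}{overrides for [langdx()] parameters (`n_topics`,
#'     `max_vocab`, `k_select`, `n_estimators`, `penalty`, `k_folds`,
#'     `n_perm`, `min_words`, `min_cases`, `lda_sweeps`, `alpha`) and for
#'     the marker stage (`markers` logical, `marker_n_iter`, `n_boot`,
#'     `top_k_topics`).}
#'   \item{sex_restrictions}{named list, e.g. `list(pregnancy = "female")`.}
#' }
#'
#' Outputs: `evaluation.csv` (per-condition AUCs and p-values),
#' `markers.csv` (condition x topic scan, long), `topic_expression.csv`,
#' `quartile_ratios.csv`, `wordclouds.json`, `topic_model.json`,
#' `manifest.json`.
#'
#' @param config named list or path to a JSON/YAML config file.
#' @param out_dir output directory.
#' @return invisibly, a list with the `langdx` fit, the `langdx_markers`
#'   object (or `NULL`), and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  if (is.null(config$seed))
    stop_langdx("config must declare a seed", "langdx_config_error")
  seed <- as.integer(config$seed)
  p <- config$params %||% list()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  checksums <- NULL

  stage <- "input"
  result <- tryCatch({
    if (!is.null(config$simulate)) {
      sim <- config$simulate
      nt <- sim$n_topics_true %||% formals(cohort_config)$n_topics_true
      ndemo <- 5L
      sim$condition_effects <- lapply(sim$condition_effects %||% list(),
        function(ce) do.call(condition_effect,
                             c(ce, list(n_topics = nt, demo_dim = ndemo))))
      cohort <- simulate_cohort(do.call(cohort_config, sim), seed = seed)
      corpus <- cohort$corpus
      demo <- cohort$demographics
      panel <- build_condition_panel(
        data.frame(participant_id = rownames(cohort$labels),
                   cohort$labels, check.names = FALSE),
        min_cases = p$min_cases %||% 30,
        sex_restrictions = unlist(config$sex_restrictions))
    } else {
      inp <- config$input
      if (is.null(inp))
        stop_langdx("config needs either simulate or input",
                    "langdx_config_error")
      paths <- unlist(inp)
      checksums <- tools::md5sum(paths)
      corpus <- read_posts(inp$posts)
      demo <- read_demographics(inp$demographics)
      if (!is.null(inp$labels)) {
        panel <- build_condition_panel(
          read.csv(inp$labels, check.names = FALSE,
                   stringsAsFactors = FALSE),
          min_cases = p$min_cases %||% 30,
          sex_restrictions = unlist(config$sex_restrictions))
      } else {
        panel <- build_condition_panel(
          read.csv(inp$diagnoses, stringsAsFactors = FALSE),
          mapping = read.csv(inp$mapping, stringsAsFactors = FALSE),
          min_cases = p$min_cases %||% 30,
          sex_restrictions = unlist(config$sex_restrictions))
      }
    }

    stage <- "evaluate"
    fit <- langdx(corpus, demo, panel,
                  n_topics = p$n_topics %||% 200,
                  max_vocab = p$max_vocab %||% 20000,
                  k_select = p$k_select %||% 500,
                  n_estimators = p$n_estimators %||% 1000,
                  penalty = p$penalty %||% 1,
                  k_folds = p$k_folds %||% 10,
                  n_perm = p$n_perm %||% 100000,
                  min_words = p$min_words %||% 500,
                  min_cases = p$min_cases %||% 30,
                  lda_sweeps = p$lda_sweeps %||% 300,
                  alpha = p$alpha %||% 0.05,
                  seed = seed)
    write.csv(fit$results, file.path(out_dir, "evaluation.csv"),
              row.names = FALSE)

    mk <- NULL
    if (isTRUE(p$markers %||% TRUE)) {
      stage <- "markers"
      mk <- scan_markers(fit, n_iter = p$marker_n_iter %||% 10000,
                         n_boot = p$n_boot %||% 10000,
                         top_k_topics = p$top_k_topics %||% 5, seed = seed)
      long <- do.call(rbind, lapply(names(mk$scans), function(cond)
        cbind(condition = cond, as.data.frame(mk$scans[[cond]]))))
      write.csv(long, file.path(out_dir, "markers.csv"), row.names = FALSE)
      em <- mk$expression
      write.csv(data.frame(condition = rownames(em),
                           as.data.frame(unclass(em)[, , drop = FALSE]),
                           check.names = FALSE),
                file.path(out_dir, "topic_expression.csv"),
                row.names = FALSE)
      if (length(mk$quartile_ratios)) {
        qr <- do.call(rbind, lapply(names(mk$quartile_ratios), function(cn) {
          q <- mk$quartile_ratios[[cn]]
          data.frame(condition = cn, topic = q$topic, ratio = q$ratio,
                     ci_low = q$ci_low, ci_high = q$ci_high,
                     top_cases = q$top_cases, top_n = q$top_n,
                     bottom_cases = q$bottom_cases, bottom_n = q$bottom_n)
        }))
        write.csv(qr, file.path(out_dir, "quartile_ratios.csv"),
                  row.names = FALSE)
      }
      jsonlite::write_json(mk$wordclouds,
                           file.path(out_dir, "wordclouds.json"),
                           digits = NA, dataframe = "columns")
    }

    tm <- fit$encoding$topic_model
    jsonlite::write_json(list(phi = tm$phi, topic_prior = tm$topic_prior,
                              vocabulary = tm$vocabulary,
                              alpha = tm$alpha, eta = tm$eta,
                              n_sweeps = tm$n_sweeps, seed = tm$seed),
                         file.path(out_dir, "topic_model.json"), digits = NA)
    list(fit = fit, markers = mk)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("langdx")),
    seed = seed, params = result$fit$params,
    conditions = result$fit$results$condition,
    n_participants = nrow(result$fit$demographics),
    input_checksums = as.list(checksums))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(result, list(manifest = manifest)))
}

#' @noRd
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_langdx("YAML configs need the yaml package", "langdx_config_error")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                        simplifyMatrix = FALSE)
  }
}
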