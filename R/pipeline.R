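#' Configure an end-to-end tagging pipeline run
#'
#' Bundles the file paths and options for [run_pipeline()]: the corpus, the
#' lexicon, the subreddit and irrelevant-term lists, the output directory,
#' the selection query, and the analysis options.
#'
#' @param corpus_path JSONL corpus (see [read_posts()]).
#' @param lexicon_path Lexicon YAML; `NULL` for the bundled default.
#' @param exclude_subreddits_path,include_subreddits_path Optional subreddit
#'   list files (exclude applied first, include second); `NULL` to skip.
#' @param exclude_terms_path Optional irrelevant-term list file.
#' @param out_dir Output directory (created if needed).
#' @param query A [proximity_query()]; default [default_query()].
#' @param top_n Topics per subreddit in the top-topic report.
#' @param interval_mode Interval convention for coverage summaries.
#' @param seed Integer seed recorded in the manifest (the pipeline itself is
#'   deterministic; the seed feeds review sampling done on its outputs).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(corpus_path,
                            lexicon_path = NULL,
                            exclude_subreddits_path = NULL,
                            include_subreddits_path = NULL,
                            exclude_terms_path = NULL,
                            out_dir = "httag_out",
                            query = default_query(),
                            top_n = 5,
                            interval_mode = "mean_pm_sd",
                            seed = 1) {
  paths <- c(corpus = corpus_path, lexicon = lexicon_path,
             exclude_subs = exclude_subreddits_path,
             include_subs = include_subreddits_path,
             exclude_terms = exclude_terms_path)
  for (p in paths) {
    if (!is.null(p) && !file.exists(p)) {
      stop("input file does not exist: ", p, call. = FALSE)
    }
  }
  structure(
    list(
      corpus_path = corpus_path,
      lexicon_path = lexicon_path,
      exclude_subreddits_path = exclude_subreddits_path,
      include_subreddits_path = include_subreddits_path,
      exclude_terms_path = exclude_terms_path,
      out_dir = out_dir,
      query = query,
      top_n = top_n,
      interval_mode = interval_mode,
      seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Run the select / assign / analyze pipeline
#'
#' Executes the full tagging pipeline: proximity-query selection, subreddit
#' exclusion and inclusion filters, lemmatized keyword topic assignment
#' with irrelevant-term exclusion, and frequency analytics. Writes
#' `assignments.csv`, `topic_frequency.csv`, `discipline_frequency.csv`,
#' `subreddit_frequency.csv`, `topic_cumulative.csv`, `top_topics.csv`, and
#' `manifest.json` under `config$out_dir`. The manifest records input file
#' digests, the seed, and the post count at every stage, so stage-count
#' conservation (`posts_in = kept + removed_by_query +
#' removed_by_subreddit`; `kept = assigned + excluded`) can be audited.
#' Any stage error aborts the run, removes partial outputs, and names the
#' failing stage.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage log lines.
#' @return The manifest, invisibly (a list; also written as JSON).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- file.path(config$out_dir, c(
    "assignments.csv", "topic_frequency.csv", "discipline_frequency.csv",
    "subreddit_frequency.csv", "topic_cumulative.csv", "top_topics.csv",
    "manifest.json"
  ))
  ok <- FALSE
  on.exit({
    if (!ok) {
      unlink(outputs)
    }
  })
  say <- function(...) {
    if (!quiet) message(sprintf(...))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline aborted at stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # -- select ---------------------------------------------------------------
  corpus <- stage("read", read_posts(config$corpus_path))
  posts_in <- nrow(corpus)
  say("read: %d posts", posts_in)

  sel <- stage("query", apply_query(corpus, config$query))
  removed_by_query <- sel$removed_count
  corpus <- sel$kept
  say("query: kept %d, removed %d", nrow(corpus), removed_by_query)

  removed_by_subreddit <- 0L
  if (!is.null(config$exclude_subreddits_path)) {
    flt <- stage("subreddit-exclude", apply_subreddit_filter(
      corpus, read_subreddit_list(config$exclude_subreddits_path, "exclude")
    ))
    removed_by_subreddit <- removed_by_subreddit + flt$removed_count
    corpus <- flt$kept
  }
  if (!is.null(config$include_subreddits_path)) {
    flt <- stage("subreddit-include", apply_subreddit_filter(
      corpus, read_subreddit_list(config$include_subreddits_path, "include")
    ))
    removed_by_subreddit <- removed_by_subreddit + flt$removed_count
    corpus <- flt$kept
  }
  say("subreddit filters: kept %d, removed %d (%.1f%% of query matches)",
      nrow(corpus), removed_by_subreddit,
      if (posts_in - removed_by_query > 0) {
        100 * removed_by_subreddit / (posts_in - removed_by_query)
      } else 0)
  kept <- nrow(corpus)

  # -- assign ---------------------------------------------------------------
  lex <- stage("lexicon", if (is.null(config$lexicon_path)) {
    default_lexicon()
  } else {
    load_lexicon(config$lexicon_path)
  })
  exclude_terms <- if (is.null(config$exclude_terms_path)) {
    character()
  } else {
    stage("terms", read_list_file(config$exclude_terms_path))
  }
  assignments <- stage("assign", assign_corpus(corpus, lex,
                                               exclude_terms = exclude_terms))
  excluded_n <- sum(assignments$excluded)
  assigned <- assignments[!assignments$excluded, , drop = FALSE]
  nonmedical_n <- sum(assigned$topic == "nonmedical")
  say("assign: %d assigned (%d nonmedical), %d excluded by terms",
      nrow(assigned), nonmedical_n, excluded_n)

  # -- analyze --------------------------------------------------------------
  topic_tab <- stage("analyze", frequency_table(assigned, "topic"))
  disc_tab <- stage("analyze", frequency_table(assigned, "discipline"))
  sub_tab <- stage("analyze", frequency_table(assigned, "subreddit"))
  top_rows <- stage("analyze", dplyr::bind_rows(lapply(
    sub_tab$label,
    function(s) {
      top <- top_n_topics(assigned, s, n = config$top_n, lex = lex)
      if (nrow(top) == 0) return(NULL)
      tibble::tibble(subreddit = s, rank = seq_len(nrow(top)),
                     topic = top$topic, count = top$count)
    }
  )))

  utils::write.csv(as.data.frame(assignments), outputs[1], row.names = FALSE)
  write_frequency_table(topic_tab, outputs[2])
  write_frequency_table(disc_tab, outputs[3])
  write_frequency_table(sub_tab, outputs[4])
  utils::write.csv(as.data.frame(cumulative_curve(topic_tab)), outputs[5],
                   row.names = FALSE)
  utils::write.csv(as.data.frame(top_rows), outputs[6], row.names = FALSE)

  manifest <- list(
    inputs = input_digests(config),
    seed = config$seed,
    counts = list(
      posts_in = posts_in,
      removed_by_query = removed_by_query,
      removed_by_subreddit = removed_by_subreddit,
      kept = kept,
      excluded = excluded_n,
      assigned = nrow(assigned),
      nonmedical = nonmedical_n
    ),
    outputs = basename(outputs)
  )
  jsonlite::write_json(manifest, outputs[7], auto_unbox = TRUE, pretty = TRUE)
  ok <- TRUE
  invisible(manifest)
}

input_digests <- function(config) {
  paths <- Filter(Negate(is.null), list(
    corpus = config$corpus_path,
    lexicon = config$lexicon_path,
    exclude_subreddits = config$exclude_subreddits_path,
    include_subreddits = config$include_subreddits_path,
    exclude_terms = config$exclude_terms_path
  ))
  lapply(paths, function(p) unname(tools::md5sum(p)))
}
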