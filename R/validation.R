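#' Draw a blinded review sample
#'
#' Uniform sample of assigned posts, without replacement, for manual topic
#' review. The sheet exposes the post text but *not* the script-assigned
#' topic; the key pairs each sampled post with its assigned topic and is
#' meant to be kept sealed until the reviewer has committed their own topic,
#' so the review is blinded. The same seed always produces the same sample.
#'
#' @param assignments Assignment tibble from [assign_corpus()].
#' @param corpus The corpus the assignments came from (supplies the text).
#' @param n Sample size (<= number of assignments).
#' @param seed Integer seed controlling the draw.
#' @return List with `sheet` (tibble: `post_id`, `subreddit`, `title`,
#'   `body`, empty `reviewer_topic`, empty `relevant`) and `key` (tibble:
#'   `post_id`, `assigned_topic`).
#' @export
draw_blinded_sample <- function(assignments, corpus, n, seed) {
  if (n > nrow(assignments)) {
    stop("sample size ", n, " exceeds the ", nrow(assignments),
         " available assignments", call. = FALSE)
  }
  idx <- local_sample(seed, nrow(assignments), n)
  picked <- assignments[idx, , drop = FALSE]
  pos <- match(picked$post_id, corpus$post_id)
  if (anyNA(pos)) {
    stop("assignment post_id '", picked$post_id[which(is.na(pos))[1]],
         "' not found in corpus", call. = FALSE)
  }
  sheet <- tibble::tibble(
    post_id = picked$post_id,
    subreddit = picked$subreddit,
    title = corpus$title[pos],
    body = corpus$body[pos],
    reviewer_topic = "",
    relevant = NA
  )
  key <- tibble::tibble(
    post_id = picked$post_id,
    assigned_topic = picked$topic
  )
  list(sheet = sheet, key = key)
}

# Seeded sample without replacement that does not disturb the caller's RNG.
local_sample <- function(seed, n_total, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  sample.int(n_total, n)
}

#' Write a review sheet and its sealed key
#'
#' The sheet and key are separate CSV files (rather than hidden columns in
#' one file) so blinding survives casually opening the sheet in a
#' spreadsheet.
#'
#' @param sample A list from [draw_blinded_sample()].
#' @param sheet_path,key_path Output CSV paths.
#' @return Invisibly, `c(sheet_path, key_path)`.
#' @export
write_review_sheet <- function(sample, sheet_path, key_path) {
  utils::write.csv(as.data.frame(sample$sheet), sheet_path, row.names = FALSE)
  utils::write.csv(as.data.frame(sample$key), key_path, row.names = FALSE)
  invisible(c(sheet_path, key_path))
}

#' Score a completed review against the sealed key
#'
#' Joins the reviewer's topics back to the assigned topics and computes the
#' accuracy rate (fraction of posts where the reviewer's topic equals the
#' script's) and the relevance rate.
#'
#' @param sheet Completed review sheet (tibble or path to CSV) with
#'   `reviewer_topic` and `relevant` filled in.
#' @param key Sealed key (tibble or path to CSV).
#' @return List with `records` (per-post tibble incl. `correct`),
#'   `accuracy`, `relevance`, and `false_positive_rate` (1 - relevance).
#' @export
score_review <- function(sheet, key) {
  if (is.character(sheet)) sheet <- utils::read.csv(sheet)
  if (is.character(key)) key <- utils::read.csv(key)
  sheet <- tibble::as_tibble(sheet)
  key <- tibble::as_tibble(key)
  pos <- match(sheet$post_id, key$post_id)
  if (anyNA(pos)) {
    stop("sheet contains post_id absent from the key", call. = FALSE)
  }
  records <- tibble::tibble(
    post_id = sheet$post_id,
    assigned_topic = key$assigned_topic[pos],
    reviewer_topic = as.character(sheet$reviewer_topic),
    relevant = as.logical(sheet$relevant)
  )
  records$correct <- records$assigned_topic == records$reviewer_topic
  list(
    records = records,
    accuracy = mean(records$correct),
    relevance = relevance_rate(records),
    false_positive_rate = 1 - relevance_rate(records)
  )
}

#' Accuracy statistics over repeated review runs
#'
#' Each run contributes one accuracy value (correct/size); the runs are
#' summarised by their mean, sample (n-1) standard deviation, and standard
#' error of the mean (SD/sqrt(number of runs)). With a single run the SD and
#' SEM are undefined and reported as `NA`.
#'
#' @param correct Integer vector: correctly assigned posts per run.
#' @param size Integer vector: posts reviewed per run (each >= 1).
#' @return List with `accuracies`, `mean`, `sd`, `sem`, `runs`.
#' @examples
#' accuracy_stats(c(50, 70), c(100, 100)) # mean 0.6, SD ~0.141, SEM ~0.1
#' @export
accuracy_stats <- function(correct, size) {
  if (length(correct) == 0 || length(correct) != length(size)) {
    stop("need one (correct, size) pair per run", call. = FALSE)
  }
  if (any(size < 1) || any(correct < 0) || any(correct > size)) {
    stop("each run needs 0 <= correct <= size and size >= 1", call. = FALSE)
  }
  acc <- correct / size
  k <- length(acc)
  s <- if (k > 1) stats::sd(acc) else NA_real_
  list(
    accuracies = acc,
    mean = mean(acc),
    sd = s,
    sem = if (k > 1) s / sqrt(k) else NA_real_,
    runs = k
  )
}

#' Fraction of reviewed posts judged relevant
#'
#' One minus this rate is the sample's false-positive rate (see
#' [false_positive_rate()]).
#'
#' @param records Tibble with a logical `relevant` column, every value set.
#' @return Fraction in \[0, 1\].
#' @export
relevance_rate <- function(records) {
  if (nrow(records) == 0) {
    stop("no review records", call. = FALSE)
  }
  if (anyNA(records$relevant)) {
    stop("every record must have 'relevant' set", call. = FALSE)
  }
  mean(records$relevant)
}
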