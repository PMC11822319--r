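#' Tabulate topic, discipline, or subreddit frequencies
#'
#' Counts non-excluded assignments grouped by the requested label and
#' divides by the number of assignments, giving the relative frequency of
#' each topic (or discipline, or subreddit) in the analysed post set. Rows
#' are sorted by count descending, ties by label ascending, so the table
#' reads like a ranked frequency report. An exhaustive table's relative
#' frequencies sum to 1.
#'
#' @param assignments Assignment tibble from [assign_corpus()]; must contain
#'   no excluded rows.
#' @param level One of `"topic"`, `"discipline"`, `"subreddit"`.
#' @param scope Label recorded on the table (default `"corpus"`).
#' @return A `frequency_table`: tibble with columns `label`, `count`,
#'   `relative_frequency`, plus attributes `scope`, `level`, `denominator`.
#' @examples
#' # 5876 STI posts of 78,980 -> relative frequency 0.0744 (7.44%)
#' @export
frequency_table <- function(assignments,
                            level = c("topic", "discipline", "subreddit"),
                            scope = "corpus") {
  level <- match.arg(level)
  if (nrow(assignments) == 0) {
    stop("cannot tabulate an empty assignment set (empty denominator)",
         call. = FALSE)
  }
  if (any(assignments$excluded)) {
    stop("assignments passed to frequency_table must be non-excluded",
         call. = FALSE)
  }
  labels <- assignments[[level]]
  counts <- table(labels)
  out <- tibble::tibble(
    label = names(counts),
    count = as.integer(counts)
  )
  out <- out[order(-out$count, out$label), , drop = FALSE]
  denom <- nrow(assignments)
  out$relative_frequency <- out$count / denom
  structure(out,
            scope = scope, level = level, denominator = denom,
            class = c("frequency_table", class(out)))
}

#' Cumulative frequency curve of a ranked table
#'
#' Partial sums of the relative frequencies of a descending-sorted
#' frequency table: the value at rank k is the fraction of posts covered by
#' the k most frequent labels. Monotone nondecreasing; reaches 1 at the last
#' rank of an exhaustive table.
#'
#' @param table A [frequency_table()].
#' @return Tibble with columns `rank`, `label`, `cumulative_fraction`.
#' @export
cumulative_curve <- function(table) {
  stopifnot(inherits(table, "frequency_table"))
  tibble::tibble(
    rank = seq_len(nrow(table)),
    label = table$label,
    cumulative_fraction = cumsum(table$relative_frequency)
  )
}

#' Top topics within one subreddit
#'
#' Ranks the topics assigned within a subreddit by post count and keeps the
#' top `n`. Ties are broken by lexicon order when a lexicon is supplied
#' (earlier topics first), otherwise alphabetically.
#'
#' @param assignments Assignment tibble (non-excluded rows).
#' @param subreddit Normalized subreddit name.
#' @param n Number of topics to keep (>= 1).
#' @param lex Optional [keyword_lexicon()] providing the tie-break order.
#' @return Tibble with columns `topic`, `count`, at most `n` rows; zero rows
#'   when the subreddit has no assignments.
#' @export
top_n_topics <- function(assignments, subreddit, n = 5, lex = NULL) {
  stopifnot(n >= 1)
  sub <- assignments[!assignments$excluded &
                       assignments$subreddit == subreddit, , drop = FALSE]
  if (nrow(sub) == 0) {
    return(tibble::tibble(topic = character(), count = integer()))
  }
  counts <- table(sub$topic)
  out <- tibble::tibble(topic = names(counts), count = as.integer(counts))
  tie_rank <- if (is.null(lex)) {
    rank(out$topic)
  } else {
    match(out$topic, lex$topic)
  }
  out <- out[order(-out$count, tie_rank), , drop = FALSE]
  utils::head(out, n)
}

# Interval conventions for coverage summaries. mean_pm_sd reproduces the
# reporting convention of the source taxonomy study (mean +/- 1 SD, capped
# to [0, 1]); normal_sem is the conventional mean +/- 1.96 SD/sqrt(k).
coverage_interval <- function(mean, sd, k,
                              interval_mode = c("mean_pm_sd", "normal_sem")) {
  interval_mode <- match.arg(interval_mode)
  half <- switch(interval_mode,
    mean_pm_sd = sd,
    normal_sem = 1.96 * sd / sqrt(k)
  )
  c(lower = max(0, mean - half), upper = min(1, mean + half))
}

#' Top-n coverage statistics for a group of subreddits
#'
#' For each subreddit in the group, coverage is the fraction of its posts
#' that fall in its own top-`n` topics; the group is then summarised by the
#' mean, the sample standard deviation, and an interval. General-interest
#' subreddits typically have low coverage (no topic dominates); condition-
#' specific subreddits typically have high coverage (their own topic
#' dominates).
#'
#' @param assignments Assignment tibble (non-excluded rows).
#' @param subreddit_group Character vector of normalized subreddit names;
#'   every one must have at least one assignment, and the group must have at
#'   least two members for the SD to exist.
#' @param n Topics counted as "top" per subreddit (default 5).
#' @param interval_mode `"mean_pm_sd"` (default; mean +/- 1 SD capped to
#'   \[0, 1\], the convention used in the source study's reporting) or
#'   `"normal_sem"` (mean +/- 1.96 SD/sqrt(group size), capped).
#' @param lex Optional lexicon for top-topic tie-breaking.
#' @return A list of class `coverage_stats`: `group` (per-subreddit coverage
#'   tibble), `mean`, `sd`, `interval` (named lower/upper), `n`,
#'   `interval_mode`.
#' @export
coverage_stats <- function(assignments, subreddit_group, n = 5,
                           interval_mode = c("mean_pm_sd", "normal_sem"),
                           lex = NULL) {
  interval_mode <- match.arg(interval_mode)
  subreddit_group <- unique(normalize_subreddit(subreddit_group))
  if (length(subreddit_group) < 2) {
    stop("coverage_stats needs at least 2 subreddits (SD undefined otherwise)",
         call. = FALSE)
  }
  coverage <- vapply(subreddit_group, function(s) {
    sub <- assignments[!assignments$excluded &
                         assignments$subreddit == s, , drop = FALSE]
    if (nrow(sub) == 0) {
      stop("subreddit '", s, "' has no assignments", call. = FALSE)
    }
    top <- top_n_topics(assignments, s, n = n, lex = lex)
    sum(top$count) / nrow(sub)
  }, numeric(1))
  m <- mean(coverage)
  s <- stats::sd(coverage)
  structure(
    list(
      group = tibble::tibble(subreddit = subreddit_group, coverage = coverage),
      mean = m,
      sd = s,
      interval = coverage_interval(m, s, length(coverage), interval_mode),
      n = n,
      interval_mode = interval_mode
    ),
    class = "coverage_stats"
  )
}

#' @export
print.coverage_stats <- function(x, ...) {
  cat("<coverage_stats> top-", x$n, " coverage over ", nrow(x$group),
      " subreddits\n", sep = "")
  cat(sprintf("  mean %.3f, SD %.3f, interval [%s] %.3f-%.3f\n",
              x$mean, x$sd, x$interval_mode,
              x$interval["lower"], x$interval["upper"]))
  invisible(x)
}

#' Write a frequency table (with cumulative fractions) to CSV
#'
#' @param table A [frequency_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frequency_table <- function(table, path) {
  out <- as.data.frame(table)
  out$cumulative_fraction <- cumsum(out$relative_frequency)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
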