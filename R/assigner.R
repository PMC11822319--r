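#' Count keyword hits per topic
#'
#' A keyword phrase hits when its lemma sequence occurs as a contiguous run
#' in the post's lemma sequence. For each topic, `distinct` is the number of
#' its phrases with at least one occurrence and `total` is the summed
#' occurrence count (overlapping occurrences of the same phrase count once
#' per start position). Topics with zero hits are omitted.
#'
#' @param lemmas Character vector of lemma tokens (see [normalize_tokens()]).
#' @param lex A [keyword_lexicon()].
#' @return A tibble with columns `topic`, `distinct`, `total`.
#' @export
count_keyword_hits <- function(lemmas, lex) {
  stopifnot(inherits(lex, "keyword_lexicon"))
  matcher <- lexicon_matcher(lex)
  hits <- matcher_hits(matcher, lemmas)
  hits[hits$distinct > 0, c("topic", "distinct", "total")]
}

# Precompile the lexicon into a flat phrase table; reused across posts so a
# corpus-level run does not re-lemmatize keywords per post.
lexicon_matcher <- function(lex) {
  rows <- list()
  for (i in seq_len(nrow(lex))) {
    for (ph in lex$lemmas[[i]]) {
      if (length(ph) == 0) next
      rows[[length(rows) + 1]] <- list(topic_idx = i, first = ph[1],
                                       len = length(ph), lemmas = ph)
    }
  }
  list(
    lex = lex,
    topic = lex$topic,
    n_topics = nrow(lex),
    first = vapply(rows, `[[`, character(1), "first"),
    len = vapply(rows, `[[`, integer(1), "len"),
    topic_idx = vapply(rows, `[[`, integer(1), "topic_idx"),
    lemmas = lapply(rows, `[[`, "lemmas")
  )
}

# Occurrence counts of every phrase in one lemma sequence, aggregated to
# (distinct, total) per topic. Returns a tibble over all topics (zeros kept).
matcher_hits <- function(matcher, lemmas) {
  distinct <- integer(matcher$n_topics)
  total <- integer(matcher$n_topics)
  if (length(lemmas) > 0 && length(matcher$first) > 0) {
    starts_of <- function(word) which(lemmas == word)
    for (p in seq_along(matcher$first)) {
      starts <- starts_of(matcher$first[p])
      if (length(starts) == 0) next
      np <- matcher$len[p]
      if (np > 1) {
        ph <- matcher$lemmas[[p]]
        starts <- starts[starts + np - 1 <= length(lemmas)]
        ok <- vapply(starts, function(s) {
          all(lemmas[s:(s + np - 1)] == ph)
        }, logical(1))
        starts <- starts[ok]
      }
      occ <- length(starts)
      if (occ > 0) {
        ti <- matcher$topic_idx[p]
        distinct[ti] <- distinct[ti] + 1L
        total[ti] <- total[ti] + occ
      }
    }
  }
  tibble::tibble(topic = matcher$topic, distinct = distinct, total = total)
}

# Winner under the tie-break cascade: most distinct phrases, then most total
# occurrences, then earliest lexicon position. Returns the lexicon row index,
# or NA when nothing hit.
pick_winner <- function(distinct, total) {
  if (all(distinct == 0)) {
    return(NA_integer_)
  }
  best <- which(distinct == max(distinct))
  best <- best[total[best] == max(total[best])]
  best[1]
}

#' Assign a topic to one post
#'
#' Applies the exclusion checks (subreddit list, irrelevant terms) and, for
#' non-excluded posts, counts lemmatized keyword hits on the matchable text
#' and picks exactly one topic: the one with the most distinct phrase hits,
#' ties broken by total occurrences, then by lexicon order. Posts with no
#' hits receive the reserved `"nonmedical"` topic.
#'
#' @param post A one-row corpus (or list with `subreddit`, `title`, `body`,
#'   `post_id`).
#' @param lex A [keyword_lexicon()].
#' @param exclude_terms Character vector of irrelevant phrases (may be
#'   empty).
#' @param exclude_subs A [subreddit_list()] or `NULL`.
#' @return A one-row tibble with columns `post_id`, `subreddit`, `topic`,
#'   `discipline`, `distinct_hits`, `total_hits`, `excluded`. For excluded
#'   posts `topic`/`discipline` are `NA`.
#' @export
assign_topic <- function(post, lex, exclude_terms = character(),
                         exclude_subs = NULL) {
  assign_corpus(tibble::as_tibble(post), lex,
                exclude_terms = exclude_terms, exclude_subs = exclude_subs)
}

#' Assign topics to every post in a corpus
#'
#' Vectorized form of [assign_topic()]; the lexicon is compiled once and
#' applied to each post. Assignment is deterministic: the same corpus,
#' lexicon and exclusions always give the same table.
#'
#' @param corpus A corpus (or tibble of posts).
#' @param lex A [keyword_lexicon()].
#' @inheritParams assign_topic
#' @param hit_report If `TRUE`, attach the full per-post topic hit table as
#'   attribute `"hits"` (a tibble with `post_id`, `topic`, `distinct`,
#'   `total`) for inspection; the assignment itself is unchanged.
#' @return Tibble with one row per post: `post_id`, `subreddit`, `topic`,
#'   `discipline`, `distinct_hits`, `total_hits`, `excluded`.
#' @export
assign_corpus <- function(corpus, lex, exclude_terms = character(),
                          exclude_subs = NULL, hit_report = FALSE) {
  stopifnot(inherits(lex, "keyword_lexicon"))
  n <- nrow(corpus)
  matcher <- lexicon_matcher(lex)
  term_tokens <- lapply(exclude_terms[nzchar(exclude_terms)], tokenize)
  nonmed_i <- match("nonmedical", lex$topic)

  topic <- character(n)
  discipline <- character(n)
  distinct_hits <- integer(n)
  total_hits <- integer(n)
  excluded <- logical(n)
  report <- if (hit_report) vector("list", n) else NULL

  texts <- matchable_text(corpus$title, corpus$body)
  for (i in seq_len(n)) {
    if (!is.null(exclude_subs)) {
      in_list <- corpus$subreddit[i] %in% exclude_subs$names
      drop <- if (exclude_subs$mode == "exclude") in_list else !in_list
      if (drop) {
        excluded[i] <- TRUE
        topic[i] <- NA_character_
        discipline[i] <- NA_character_
        next
      }
    }
    raw <- tokenize(texts[i])
    if (length(term_tokens) > 0 &&
        any(vapply(term_tokens, function(p) contains_phrase(raw, p),
                   logical(1)))) {
      excluded[i] <- TRUE
      topic[i] <- NA_character_
      discipline[i] <- NA_character_
      next
    }
    lemmas <- lemmatize(raw)
    hits <- matcher_hits(matcher, lemmas)
    if (hit_report) {
      nz <- hits[hits$distinct > 0, , drop = FALSE]
      if (nrow(nz) > 0) {
        nz$post_id <- corpus$post_id[i]
        report[[i]] <- nz[, c("post_id", "topic", "distinct", "total")]
      }
    }
    win <- pick_winner(hits$distinct, hits$total)
    if (is.na(win)) {
      win <- nonmed_i
    }
    topic[i] <- lex$topic[win]
    discipline[i] <- lex$discipline[win]
    distinct_hits[i] <- hits$distinct[win]
    total_hits[i] <- hits$total[win]
  }

  out <- tibble::tibble(
    post_id = corpus$post_id,
    subreddit = corpus$subreddit,
    topic = topic,
    discipline = discipline,
    distinct_hits = distinct_hits,
    total_hits = total_hits,
    excluded = excluded
  )
  if (hit_report) {
    attr(out, "hits") <- dplyr::bind_rows(report)
  }
  out
}
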