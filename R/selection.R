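#' Tokenize text into lowercase word tokens
#'
#' Splits on any run of non-alphanumeric characters, lowercases, and drops
#' empty tokens. Token positions (0-based) are the coordinate system for the
#' proximity query: "within 4 words" means a positional span of at most 4 in
#' this sequence.
#'
#' @param text A single character string.
#' @return Character vector of tokens (possibly empty).
#' @examples
#' tokenize("Get it checked.") # "get" "it" "checked"
#' @export
tokenize <- function(text) {
  stopifnot(length(text) == 1)
  if (is.na(text) || !nzchar(text)) {
    return(character())
  }
  toks <- strsplit(tolower(text), "[^[:alnum:]]+")[[1]]
  toks[nzchar(toks)]
}

#' Define a proximity query
#'
#' A proximity query is a list of term groups plus a window. A token
#' sequence matches when one occurrence can be chosen from every group such
#' that the chosen positions all lie within `window` of each other
#' (`max(position) - min(position) <= window`).
#'
#' @param groups List of character vectors; each vector is one group of
#'   alternative lowercase word forms, and every group must be represented.
#' @param window Positive integer; maximum positional span.
#' @return A `proximity_query` object.
#' @seealso [default_query()] for the get/got ... test/check ... for query.
#' @export
proximity_query <- function(groups, window) {
  if (!is.list(groups) || length(groups) < 1) {
    stop("groups must be a non-empty list of character vectors", call. = FALSE)
  }
  groups <- lapply(groups, function(g) {
    g <- tolower(as.character(g))
    if (length(g) == 0) stop("every query group must be non-empty", call. = FALSE)
    g
  })
  window <- as.integer(window)
  if (is.na(window) || window < 1) {
    stop("window must be a positive integer", call. = FALSE)
  }
  structure(list(groups = groups, window = window), class = "proximity_query")
}

#' The default post-selection query
#'
#' Selects posts about getting tested or checked: either "get" or "got",
#' together with one of "test"/"tested"/"check"/"checked", together with
#' "for", all within 4 words of each other.
#'
#' @return A [proximity_query()].
#' @export
default_query <- function() {
  proximity_query(
    groups = list(
      c("get", "got"),
      c("test", "tested", "check", "checked"),
      "for"
    ),
    window = 4
  )
}

#' Evaluate a proximity query on a token sequence
#'
#' @param tokens Character vector of lowercase tokens (see [tokenize()]).
#' @param query A [proximity_query()].
#' @return `TRUE` iff some choice of one occurrence per group spans at most
#'   `query$window` positions.
#' @details Implemented as a minimum-window cover over the merged, sorted
#'   occurrence positions of all groups (two-pointer sweep), so it is linear
#'   in the number of occurrences rather than exponential in the number of
#'   groups.
#' @examples
#' evaluate_proximity_query(tokenize("should i get tested for chlamydia"),
#'                          default_query())
#' @export
evaluate_proximity_query <- function(tokens, query) {
  stopifnot(inherits(query, "proximity_query"))
  k <- length(query$groups)
  pos <- lapply(query$groups, function(g) which(tokens %in% g))
  if (any(lengths(pos) == 0)) {
    return(FALSE)
  }
  if (k == 1) {
    return(TRUE)
  }
  ev_pos <- unlist(pos, use.names = FALSE)
  ev_grp <- rep.int(seq_len(k), lengths(pos))
  o <- order(ev_pos)
  ev_pos <- ev_pos[o]
  ev_grp <- ev_grp[o]
  count <- integer(k)
  have <- 0L
  left <- 1L
  best <- Inf
  for (right in seq_along(ev_pos)) {
    g <- ev_grp[right]
    count[g] <- count[g] + 1L
    if (count[g] == 1L) have <- have + 1L
    while (have == k) {
      best <- min(best, ev_pos[right] - ev_pos[left])
      gl <- ev_grp[left]
      count[gl] <- count[gl] - 1L
      if (count[gl] == 0L) have <- have - 1L
      left <- left + 1L
    }
  }
  best <= query$window
}

#' Select corpus posts matching a proximity query
#'
#' @param corpus A corpus.
#' @param query A [proximity_query()]; defaults to [default_query()].
#' @return List with `kept` (matching posts, order preserved) and
#'   `removed_count`.
#' @export
apply_query <- function(corpus, query = default_query()) {
  texts <- matchable_text(corpus$title, corpus$body)
  keep <- vapply(texts, function(t) {
    evaluate_proximity_query(tokenize(t), query)
  }, logical(1), USE.NAMES = FALSE)
  list(
    kept = as_corpus(corpus[keep, , drop = FALSE],
                     provenance = attr(corpus, "provenance")),
    removed_count = sum(!keep)
  )
}

#' Define a subreddit filter list
#'
#' @param names Character vector of subreddit names (normalized on
#'   construction).
#' @param mode `"exclude"` (drop listed subreddits) or `"include"` (keep
#'   only listed subreddits).
#' @return A `subreddit_list` object.
#' @export
subreddit_list <- function(names, mode = c("exclude", "include")) {
  mode <- match.arg(mode)
  structure(
    list(names = unique(normalize_subreddit(as.character(names))), mode = mode),
    class = "subreddit_list"
  )
}

#' Read a subreddit list file
#'
#' One subreddit per line; `#` starts a comment; names are normalized.
#'
#' @param path Path to the list file.
#' @inheritParams subreddit_list
#' @return A [subreddit_list()].
#' @export
read_subreddit_list <- function(path, mode = c("exclude", "include")) {
  subreddit_list(read_list_file(path), mode = match.arg(mode))
}

#' Filter a corpus by subreddit
#'
#' In exclude mode, posts from listed subreddits are dropped (the coarse
#' first-pass filter that removes clearly off-topic forums). In include
#' mode, only posts from listed subreddits are kept (the final restriction
#' to health-relevant forums).
#'
#' @param corpus A corpus.
#' @param list A [subreddit_list()].
#' @return List with `kept` (order-preserving corpus) and `removed_count`.
#' @export
apply_subreddit_filter <- function(corpus, list) {
  stopifnot(inherits(list, "subreddit_list"))
  in_list <- corpus$subreddit %in% list$names
  keep <- if (list$mode == "exclude") !in_list else in_list
  list(
    kept = as_corpus(corpus[keep, , drop = FALSE],
                     provenance = attr(corpus, "provenance")),
    removed_count = sum(!keep)
  )
}

# TRUE iff `phrase_tokens` occurs as a contiguous subsequence of `tokens`.
contains_phrase <- function(tokens, phrase_tokens) {
  np <- length(phrase_tokens)
  nt <- length(tokens)
  if (np == 0 || nt < np) {
    return(FALSE)
  }
  starts <- which(tokens == phrase_tokens[1])
  if (np == 1) {
    return(length(starts) > 0)
  }
  starts <- starts[starts + np - 1 <= nt]
  for (s in starts) {
    if (all(tokens[s:(s + np - 1)] == phrase_tokens)) {
      return(TRUE)
    }
  }
  FALSE
}

#' Drop posts containing irrelevant terms
#'
#' Removes any post whose tokenized matchable text contains one of the
#' given phrases as a contiguous token run. Matching is on raw (not
#' lemmatized) tokens so that term exclusion stays independent of the
#' lexicon's lemmatizer.
#'
#' @param corpus A corpus.
#' @param terms Character vector of lowercase phrases (one or more words
#'   each).
#' @return List with `kept` and `removed_count`.
#' @export
apply_term_exclusion <- function(corpus, terms) {
  terms <- terms[nzchar(terms)]
  if (length(terms) == 0) {
    return(list(kept = corpus, removed_count = 0L))
  }
  phrase_tokens <- lapply(terms, tokenize)
  texts <- matchable_text(corpus$title, corpus$body)
  hit <- vapply(texts, function(t) {
    toks <- tokenize(t)
    any(vapply(phrase_tokens, function(p) contains_phrase(toks, p), logical(1)))
  }, logical(1), USE.NAMES = FALSE)
  list(
    kept = as_corpus(corpus[!hit, , drop = FALSE],
                     provenance = attr(corpus, "provenance")),
    removed_count = sum(hit)
  )
}

#' False-positive rate of a reviewed sample
#'
#' One minus the number of relevant posts divided by the total number of
#' posts in the sample.
#'
#' @param relevant_count Number of posts judged relevant.
#' @param total_count Total number of reviewed posts (must be >= 1).
#' @return Fraction in \[0, 1\].
#' @examples
#' false_positive_rate(71, 100) # 0.29
#' @export
false_positive_rate <- function(relevant_count, total_count) {
  if (length(total_count) != 1 || is.na(total_count) || total_count < 1) {
    stop("total_count must be a positive integer", call. = FALSE)
  }
  if (relevant_count < 0 || relevant_count > total_count) {
    stop("relevant_count must be between 0 and total_count", call. = FALSE)
  }
  1 - relevant_count / total_count
}
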