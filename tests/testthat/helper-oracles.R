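# Independent oracles and fixture builders shared across the suite.

# Exhaustive proximity-query oracle: enumerate every tuple of one occurrence
# per group and test the span directly. Exponential, only for small inputs.
oracle_proximity <- function(tokens, query) {
  pos <- lapply(query$groups, function(g) which(tokens %in% g))
  if (any(lengths(pos) == 0)) {
    return(FALSE)
  }
  grid <- as.matrix(expand.grid(pos))
  any(apply(grid, 1, function(r) max(r) - min(r) <= query$window))
}

# Brute-force keyword hit counter: slide every phrase over every start
# position. Independent of the package's first-token-indexed matcher.
oracle_hits <- function(lemmas, lex) {
  out <- list()
  for (i in seq_len(nrow(lex))) {
    distinct <- 0L
    total <- 0L
    for (ph in lex$lemmas[[i]]) {
      np <- length(ph)
      if (np == 0 || np > length(lemmas)) next
      occ <- 0L
      for (s in seq_len(length(lemmas) - np + 1)) {
        if (all(lemmas[s:(s + np - 1)] == ph)) occ <- occ + 1L
      }
      if (occ > 0) {
        distinct <- distinct + 1L
        total <- total + occ
      }
    }
    if (distinct > 0) {
      out[[length(out) + 1]] <- data.frame(topic = lex$topic[i],
                                           distinct = distinct, total = total)
    }
  }
  if (length(out) == 0) {
    return(data.frame(topic = character(), distinct = integer(),
                      total = integer()))
  }
  do.call(rbind, out)
}

# Brute-force single-post assignment using oracle_hits plus the documented
# tie-break cascade (distinct, total, lexicon order).
oracle_assign <- function(text, lex) {
  hits <- oracle_hits(normalize_tokens(text), lex)
  if (nrow(hits) == 0) {
    return("nonmedical")
  }
  hits$order <- match(hits$topic, lex$topic)
  hits <- hits[order(-hits$distinct, -hits$total, hits$order), , drop = FALSE]
  hits$topic[1]
}

# Compact corpus builder for tests.
make_corpus <- function(bodies, subreddits = "askdocs", titles = "",
                        ids = NULL) {
  n <- length(bodies)
  as_corpus(tibble::tibble(
    post_id = ids %||% sprintf("t%03d", seq_len(n)),
    subreddit = rep_len(subreddits, n),
    created_date = as.Date("2019-06-15"),
    title = rep_len(titles, n),
    body = bodies,
    is_comment = FALSE
  ), provenance = "test")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A tiny fixed lexicon used across assigner/analytics tests.
tiny_lexicon <- function() {
  keyword_lexicon(tibble::tibble(
    topic = c("alpha", "beta", "gamma"),
    discipline = c("d1", "d1", "d2"),
    keywords = list(
      c("foo", "foo bar"),
      c("bar", "bazz"),
      c("quux", "deep quux")
    )
  ))
}
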