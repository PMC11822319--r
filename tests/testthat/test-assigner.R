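test_that("lemmatization collapses regular inflections", {
  expect_equal(lemmatize(c("tests", "tested", "testing")), rep("test", 3))
  expect_equal(lemmatize("checked"), "check")
  expect_equal(normalize_tokens("tested positive"), c("test", "positive"))
  expect_equal(normalize_tokens(""), character())
  expect_equal(normalize_tokens("bacterial vaginosis"),
               c("bacterial", "vaginosis"))
  # short words, digits, and -ss/-us/-is endings pass through
  expect_equal(lemmatize(c("is", "a1c", "virus", "class", "news")),
               c("is", "a1c", "virus", "class", "news"))
  # doubled consonants undouble; -ies becomes -y
  expect_equal(lemmatize(c("stopped", "running", "bodies", "carried")),
               c("stop", "run", "body", "carry"))
})

test_that("count_keyword_hits counts distinct phrases and total occurrences", {
  lex <- tiny_lexicon()
  hits <- count_keyword_hits(normalize_tokens("foo x foo bar y quux"), lex)
  hits <- hits[order(hits$topic), ]
  # alpha: "foo" occurs twice, "foo bar" once; beta: "bar" once; gamma: quux
  expect_equal(hits$topic, c("alpha", "beta", "gamma"))
  expect_equal(hits$distinct, c(2L, 1L, 1L))
  expect_equal(hits$total, c(3L, 1L, 1L))

  expect_equal(nrow(count_keyword_hits(character(), lex)), 0)
  expect_equal(nrow(count_keyword_hits(normalize_tokens("zzz yyy"), lex)), 0)
})

test_that("multi-word phrase occurrences count once per start position", {
  lex <- keyword_lexicon(tibble::tibble(
    topic = "rep", discipline = "d", keywords = list("ha ha")
  ))
  hits <- count_keyword_hits(c("ha", "ha", "ha"), lex)
  expect_equal(hits$total, 2L) # starts at 1 and 2
})

test_that("assignment follows the tie-break cascade", {
  lex <- tiny_lexicon()
  # distinct wins over total: alpha 2 distinct beats beta 1 distinct
  a <- assign_topic(make_corpus("foo bar bazz")[1, ], lex)
  expect_equal(a$topic, "alpha")
  # equal distinct, higher total wins
  b <- assign_topic(make_corpus("foo quux quux")[1, ], lex)
  expect_equal(b$topic, "gamma")
  # full tie: earlier lexicon topic wins
  c_ <- assign_topic(make_corpus("foo quux")[1, ], lex)
  expect_equal(c_$topic, "alpha")
  # no hits: nonmedical fallback with zero hit counts
  d <- assign_topic(make_corpus("nothing matches here")[1, ], lex)
  expect_equal(d$topic, "nonmedical")
  expect_equal(d$distinct_hits, 0L)
})

test_that("the worked anxiety example assigns to anxiety", {
  body <- paste(
    "I find that when I go through bouts of anxiety the mornings are",
    "usually the hardest, no appetite, tired etc, but as the day goes on I",
    "find I feel better, even to the extent by evening time I feel \"normal.\""
  )
  a <- assign_topic(make_corpus(body)[1, ], default_lexicon())
  expect_equal(a$topic, "anxiety")
  expect_equal(a$discipline, "psychiatry and mental health")
})

test_that("exclusions mark posts excluded with empty topic", {
  lex <- tiny_lexicon()
  corpus <- make_corpus(
    bodies = c("foo here", "check my video game foo", "bar there"),
    subreddits = c("askdocs", "askdocs", "gaming")
  )
  a <- assign_corpus(corpus, lex,
                     exclude_terms = "video game",
                     exclude_subs = subreddit_list("gaming", "exclude"))
  expect_equal(a$excluded, c(FALSE, TRUE, TRUE))
  expect_true(all(is.na(a$topic[a$excluded])))
  expect_true(all(!is.na(a$topic[!a$excluded])))
})

test_that("assignment agrees with the brute-force oracle on random posts", {
  set.seed(31)
  lex <- generate_toy_lexicon(9, 4, seed = 8)
  kw_tokens <- unique(unlist(lapply(unlist(lex$keywords), tokenize)))
  vocab <- c(kw_tokens, sprintf("zq%dx", 1:10))
  for (i in 1:60) {
    text <- paste(sample(vocab, sample(1:100, 1), replace = TRUE),
                  collapse = " ")
    a <- assign_topic(make_corpus(text)[1, ], lex)
    expect_equal(a$topic, oracle_assign(text, lex), info = text)
  }
})

test_that("hit counting agrees with the sliding-window oracle", {
  set.seed(77)
  lex <- tiny_lexicon()
  vocab <- c("foo", "bar", "bazz", "quux", "deep", "x", "y")
  for (i in 1:40) {
    lemmas <- sample(vocab, sample(0:30, 1), replace = TRUE)
    got <- as.data.frame(count_keyword_hits(lemmas, lex))
    want <- oracle_hits(lemmas, lex)
    got <- got[order(got$topic), ]
    want <- want[order(want$topic), ]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("assignment is deterministic and total over non-excluded posts", {
  lex <- default_lexicon()
  sim <- generate_corpus(generator_config(n_posts = 120, seed = 55), lex)
  a1 <- assign_corpus(sim$corpus, lex)
  a2 <- assign_corpus(sim$corpus, lex)
  expect_identical(a1, a2)
  expect_false(anyNA(a1$topic[!a1$excluded]))
  expect_equal(nrow(a1), nrow(sim$corpus))
})

test_that("permuting lexicon order only moves tied posts", {
  lex <- tiny_lexicon()
  rev_lex <- keyword_lexicon(tibble::tibble(
    topic = rev(lex$topic[lex$topic != "nonmedical"]),
    discipline = rev(lex$discipline[lex$topic != "nonmedical"]),
    keywords = rev(lex$keywords[lex$topic != "nonmedical"])
  ))
  set.seed(13)
  vocab <- c("foo", "bar", "bazz", "quux", "deep", "x")
  n_tied <- 0
  n_moved <- 0
  for (i in 1:80) {
    text <- paste(sample(vocab, sample(1:12, 1), replace = TRUE),
                  collapse = " ")
    hits <- count_keyword_hits(normalize_tokens(text), lex)
    top <- hits[order(-hits$distinct, -hits$total), , drop = FALSE]
    tied <- nrow(top) > 1 &&
      sum(top$distinct == top$distinct[1] & top$total == top$total[1]) > 1
    a <- assign_topic(make_corpus(text)[1, ], lex)$topic
    b <- assign_topic(make_corpus(text)[1, ], rev_lex)$topic
    if (a != b) {
      n_moved <- n_moved + 1
      expect_true(tied, info = text)
    }
    if (tied) n_tied <- n_tied + 1
  }
  expect_lte(n_moved, n_tied)
})

test_that("hit_report exposes the full hit mapping without changing assignment", {
  lex <- tiny_lexicon()
  corpus <- make_corpus("foo bar quux")
  plain <- assign_corpus(corpus, lex)
  reported <- assign_corpus(corpus, lex, hit_report = TRUE)
  expect_equal(as.data.frame(plain), as.data.frame(reported),
               ignore_attr = TRUE)
  hits <- attr(reported, "hits")
  expect_setequal(hits$topic, c("alpha", "beta", "gamma"))
})
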