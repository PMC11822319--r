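test_that("tokenize splits on non-alphanumeric runs and lowercases", {
  expect_equal(tokenize("Get it checked."), c("get", "it", "checked"))
  expect_equal(tokenize(""), character())
  expect_equal(tokenize("HIV/AIDS test"), c("hiv", "aids", "test"))
  expect_equal(tokenize("  --  "), character())
  expect_equal(tokenize("a1c, checked!"), c("a1c", "checked"))
})

test_that("proximity query matches the documented examples", {
  q <- default_query()
  expect_true(evaluate_proximity_query(
    tokenize("should i get tested for chlamydia"), q))
  expect_false(evaluate_proximity_query(
    tokenize("get a new phone today"), q))
  # all three groups occur, but no joint placement spans <= 4
  expect_false(evaluate_proximity_query(
    tokenize("checked the oven then later on we asked for help i got"), q))
  # span exactly equal to the window still matches
  expect_true(evaluate_proximity_query(
    c("get", "x", "x", "x", "checked", "for"), proximity_query(
      list(c("get", "got"), c("check", "checked"), "for"), 5)))
})

test_that("proximity matcher agrees with the exhaustive oracle on random sequences", {
  q <- default_query()
  vocab <- c(unlist(q$groups), letters[1:8])
  set.seed(2024)
  mismatches <- 0
  for (i in 1:300) {
    toks <- sample(vocab, sample(1:60, 1), replace = TRUE,
                   prob = c(rep(1, 7), rep(6, 8)))
    if (evaluate_proximity_query(toks, q) != oracle_proximity(toks, q)) {
      mismatches <- mismatches + 1
    }
  }
  expect_equal(mismatches, 0)
})

test_that("appending tokens never turns a proximity match false", {
  q <- default_query()
  vocab <- c(unlist(q$groups), letters[1:6])
  set.seed(99)
  checked <- 0
  for (i in 1:200) {
    toks <- sample(vocab, sample(3:40, 1), replace = TRUE)
    if (evaluate_proximity_query(toks, q)) {
      extra <- sample(vocab, sample(1:10, 1), replace = TRUE)
      expect_true(evaluate_proximity_query(c(toks, extra), q))
      checked <- checked + 1
    }
  }
  expect_gt(checked, 10)
})

test_that("subreddit filters keep order and count removals in both modes", {
  corpus <- make_corpus(
    bodies = sprintf("body %d", 1:10),
    subreddits = c("gaming", "askdocs", "gaming", "std", "gaming",
                   "askdocs", "gaming", "anxiety", "movies", "askdocs")
  )
  ex <- apply_subreddit_filter(corpus, subreddit_list("gaming", "exclude"))
  expect_equal(ex$removed_count, 4)
  expect_equal(nrow(ex$kept), 6)
  expect_equal(ex$kept$post_id, corpus$post_id[corpus$subreddit != "gaming"])

  none <- apply_subreddit_filter(corpus, subreddit_list(character(), "exclude"))
  expect_equal(none$removed_count, 0)
  expect_equal(nrow(none$kept), 10)

  inc <- apply_subreddit_filter(corpus, subreddit_list("nosuch", "include"))
  expect_equal(nrow(inc$kept), 0)
  expect_equal(inc$removed_count, 10)
})

test_that("excluding A then B equals excluding their union", {
  set.seed(5)
  corpus <- make_corpus(
    bodies = sprintf("b%d", 1:40),
    subreddits = sample(c("s1", "s2", "s3", "s4", "s5"), 40, replace = TRUE)
  )
  a <- c("s1", "s3")
  b <- c("s3", "s5")
  seq_kept <- apply_subreddit_filter(
    apply_subreddit_filter(corpus, subreddit_list(a, "exclude"))$kept,
    subreddit_list(b, "exclude")
  )$kept
  union_kept <- apply_subreddit_filter(
    corpus, subreddit_list(union(a, b), "exclude")
  )$kept
  expect_equal(as.data.frame(seq_kept), as.data.frame(union_kept))
})

test_that("term exclusion matches contiguous token runs, not substrings", {
  corpus <- make_corpus(bodies = c(
    "check out my video game build",
    "the videogame was fine",
    "get tested for chlamydia",
    "a Video GAME, again"
  ))
  res <- apply_term_exclusion(corpus, "video game")
  expect_equal(res$removed_count, 2) # tokenization is case/punct-insensitive
  expect_equal(res$kept$post_id, corpus$post_id[c(2, 3)])

  # single-token term does not match the two-token phrase
  res2 <- apply_term_exclusion(corpus, "videogame")
  expect_equal(res2$removed_count, 1)
  expect_equal(res2$kept$post_id, corpus$post_id[c(1, 3, 4)])

  ident <- apply_term_exclusion(corpus, character())
  expect_equal(ident$removed_count, 0)
  expect_equal(nrow(ident$kept), 4)
})

test_that("false_positive_rate is 1 - relevant/total and strictly decreasing", {
  expect_equal(false_positive_rate(100, 100), 0)
  expect_equal(false_positive_rate(0, 50), 1)
  expect_equal(false_positive_rate(71, 100), 0.29)
  expect_error(false_positive_rate(1, 0), "total_count")
  expect_error(false_positive_rate(6, 5), "between 0 and total_count")
  rates <- vapply(0:100, false_positive_rate, numeric(1), total_count = 100)
  expect_true(all(diff(rates) < 0))
})

test_that("apply_query selects matching posts and uses the title for context", {
  corpus <- make_corpus(
    bodies = c(
      "should i get tested for chlamydia",
      "nothing to see here",
      "i got checked for strep last week",
      "does this look normal to you"
    ),
    titles = c("", "", "", "Get tested for HPV?")
  )
  res <- apply_query(corpus)
  expect_equal(res$kept$post_id, corpus$post_id[c(1, 3, 4)])
  expect_equal(res$removed_count, 1)
})
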