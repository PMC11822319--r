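# Build an assignment tibble directly from topic/discipline/subreddit labels.
fake_assignments <- function(topics, disciplines = "d", subreddits = "s") {
  n <- length(topics)
  tibble::tibble(
    post_id = sprintf("f%05d", seq_len(n)),
    subreddit = rep_len(subreddits, n),
    topic = topics,
    discipline = rep_len(disciplines, n),
    distinct_hits = 1L,
    total_hits = 1L,
    excluded = FALSE
  )
}

test_that("frequency_table computes counts, frequencies, and ordering", {
  a <- fake_assignments(
    c(rep("sti", 5), rep("anxiety", 3), rep("flu", 2)),
    disciplines = c(rep("inf", 5), rep("psych", 3), rep("inf", 2))
  )
  tab <- frequency_table(a, "topic")
  expect_equal(tab$label, c("sti", "anxiety", "flu"))
  expect_equal(tab$count, c(5L, 3L, 2L))
  expect_equal(tab$relative_frequency, c(0.5, 0.3, 0.2))
  expect_equal(attr(tab, "denominator"), 10)

  one <- frequency_table(fake_assignments("x"), "topic")
  expect_equal(one$relative_frequency, 1)

  expect_error(frequency_table(fake_assignments(character()), "topic"),
               "empty")
  excl <- fake_assignments("x")
  excl$excluded <- TRUE
  expect_error(frequency_table(excl, "topic"), "non-excluded")
})

test_that("ties in count are ordered by label", {
  a <- fake_assignments(c("b", "a", "c", "a", "c", "b"))
  tab <- frequency_table(a, "topic")
  expect_equal(tab$label, c("a", "b", "c"))
})

test_that("exhaustive tables sum to one and disciplines conserve topic mass", {
  lex <- default_lexicon()
  sim <- generate_corpus(generator_config(n_posts = 600, seed = 3), lex)
  a <- assign_corpus(sim$corpus, lex)
  a <- a[!a$excluded, , drop = FALSE]
  topic_tab <- frequency_table(a, "topic")
  disc_tab <- frequency_table(a, "discipline")
  expect_equal(sum(topic_tab$relative_frequency), 1, tolerance = 1e-9)
  expect_equal(sum(disc_tab$relative_frequency), 1, tolerance = 1e-9)
  for (d in disc_tab$label) {
    members <- lex$topic[lex$discipline == d]
    expect_equal(
      disc_tab$relative_frequency[disc_tab$label == d],
      sum(topic_tab$relative_frequency[topic_tab$label %in% members]),
      tolerance = 1e-12, info = d
    )
  }
})

test_that("cumulative_curve takes partial sums and ends at one", {
  a <- fake_assignments(c(rep("x", 5), rep("y", 3), rep("z", 2)))
  curve <- cumulative_curve(frequency_table(a, "topic"))
  expect_equal(curve$cumulative_fraction, c(0.5, 0.8, 1.0))
  expect_equal(curve$rank, 1:3)
  expect_true(all(diff(curve$cumulative_fraction) >= 0))

  single <- cumulative_curve(frequency_table(fake_assignments("x"), "topic"))
  expect_equal(single$cumulative_fraction, 1)
})

test_that("top_n_topics ranks within a subreddit with lexicon tie-break", {
  a <- fake_assignments(
    c("a", "a", "a", "b", "b", "c", "z"),
    subreddits = c(rep("s1", 6), "s2")
  )
  top <- top_n_topics(a, "s1", n = 2)
  expect_equal(top$topic, c("a", "b"))
  expect_equal(top$count, c(3L, 2L))
  # n larger than distinct topics returns everything
  expect_equal(nrow(top_n_topics(a, "s1", n = 10)), 3)
  # unknown subreddit is empty, not an error
  expect_equal(nrow(top_n_topics(a, "nosuch", n = 5)), 0)

  # tie at the top broken by lexicon order (beta before alpha here)
  lex <- keyword_lexicon(tibble::tibble(
    topic = c("beta", "alpha"), discipline = "d",
    keywords = list("b", "a")
  ))
  tied <- fake_assignments(c("alpha", "beta"), subreddits = "s")
  expect_equal(top_n_topics(tied, "s", n = 1, lex = lex)$topic, "beta")
  expect_equal(top_n_topics(tied, "s", n = 1)$topic, "alpha") # alphabetical
})

test_that("coverage_stats summarises per-subreddit top-n coverage", {
  # s1: 10 posts, top-1 topic covers 4; s2: 10 posts, top-1 covers 6
  a <- fake_assignments(
    c(rep("a", 4), c("b", "c", "d", "e", "f", "g"),
      rep("a", 6), c("b", "c", "d", "e")),
    subreddits = c(rep("s1", 10), rep("s2", 10))
  )
  cs <- coverage_stats(a, c("s1", "s2"), n = 1)
  expect_equal(cs$mean, 0.5)
  expect_equal(cs$sd, stats::sd(c(0.4, 0.6)))
  expect_equal(unname(cs$interval["lower"]), 0.5 - cs$sd)

  # identical coverages collapse the interval to the mean
  b <- fake_assignments(rep(c("a", "b"), 4),
                        subreddits = rep(c("s1", "s2"), each = 4))
  cs2 <- coverage_stats(b, c("s1", "s2"), n = 2)
  expect_equal(cs2$sd, 0)
  expect_equal(unname(cs2$interval), c(cs2$mean, cs2$mean))

  expect_error(coverage_stats(a, "s1"), "at least 2")
  expect_error(coverage_stats(a, c("s1", "nosuch")), "no assignments")
})

test_that("interval conventions cap to [0, 1] and differ as documented", {
  pm <- httag:::coverage_interval(0.9, 0.3, 10, "mean_pm_sd")
  expect_equal(unname(pm), c(0.6, 1))
  sem <- httag:::coverage_interval(0.9, 0.3, 10, "normal_sem")
  expect_equal(unname(sem), c(0.9 - 1.96 * 0.3 / sqrt(10), 1))
})

test_that("subreddit slices agree with the full per-subreddit tabulation", {
  set.seed(17)
  a <- fake_assignments(
    sample(letters[1:5], 60, replace = TRUE),
    subreddits = sample(c("s1", "s2", "s3"), 60, replace = TRUE)
  )
  full <- frequency_table(a, "subreddit")
  for (s in c("s1", "s2", "s3")) {
    slice <- a[a$subreddit == s, , drop = FALSE]
    expect_equal(full$count[full$label == s], nrow(slice))
  }
})

test_that("percent rounding is half-up at the printed precision", {
  expect_equal(percent(5876 / 78980), 7.44)
  expect_equal(round_half_up(83.125, 2), 83.13)
  expect_equal(round_half_up(2.5), 3)
  expect_equal(round_half_up(-2.5), -3)
})
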