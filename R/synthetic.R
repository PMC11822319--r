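#' Configuration for the synthetic corpus generator
#'
#' The generator emulates the corpus the tagging pipeline was designed for:
#' Reddit-style posts selected by a "get tested / get checked" proximity
#' query, a mix of health-relevant posts with planted topic keywords and
#' irrelevant posts, spread over included and excluded subreddits. Defaults
#' mirror the source study's observed conditions at roughly 1/100 scale:
#' about 3500 posts, ~29% of posts irrelevant before subreddit filtering
#' and ~15.5% after (posts in excluded subreddits are always irrelevant;
#' the two knobs below combine to 0.16 + 0.84 x 0.155 ~ 0.29 overall).
#'
#' @param n_posts Number of posts to generate.
#' @param topic_mixture Named numeric vector of topic probabilities (must
#'   sum to 1), or `NULL` for uniform over the lexicon's non-fallback
#'   topics.
#' @param irrelevant_fraction Probability that a post in an *included*
#'   subreddit is irrelevant (carries no lexicon keyword).
#' @param excluded_subreddit_fraction Probability that a post lands in an
#'   excluded subreddit (all such posts are irrelevant).
#' @param keywords_per_post Length-2 integer range: how many of the planted
#'   topic's keyword phrases each relevant post embeds.
#' @param filler_vocab_size Size of the nonsense filler vocabulary; filler
#'   words are constructed disjoint from all lexicon keywords and query
#'   terms so noise cannot create accidental hits.
#' @param trigger_phrase_rate Probability that a post contains a
#'   query-satisfying phrase such as "get tested for".
#' @param confusable_rate Probability that a relevant post additionally
#'   embeds one keyword from a second, random topic (exercises the
#'   tie-break cascade); 0 by default.
#' @param included_subreddits,excluded_subreddits Character pools the
#'   generator draws subreddit names from.
#' @param seed Integer seed; generation is deterministic given the config.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_posts = 3500,
                             topic_mixture = NULL,
                             irrelevant_fraction = 0.155,
                             excluded_subreddit_fraction = 0.16,
                             keywords_per_post = c(1L, 3L),
                             filler_vocab_size = 200,
                             trigger_phrase_rate = 0.9,
                             confusable_rate = 0,
                             included_subreddits = c(
                               "askreddit", "askdocs", "amitheasshole",
                               "relationship_advice", "medical", "advice",
                               "std", "anxiety", "adhd", "pregnant",
                               "diabetes", "hypothyroidism"
                             ),
                             excluded_subreddits = c(
                               "gaming", "movies", "technology", "politics",
                               "music"
                             ),
                             seed = 1) {
  probs <- c(irrelevant_fraction, excluded_subreddit_fraction,
             trigger_phrase_rate, confusable_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("rates must lie in [0, 1]", call. = FALSE)
  }
  if (n_posts < 0) {
    stop("n_posts must be >= 0", call. = FALSE)
  }
  if (!is.null(topic_mixture)) {
    if (is.null(names(topic_mixture)) || any(topic_mixture < 0) ||
        abs(sum(topic_mixture) - 1) > 1e-8) {
      stop("topic_mixture must be a named probability vector summing to 1",
           call. = FALSE)
    }
  }
  keywords_per_post <- as.integer(keywords_per_post)
  if (length(keywords_per_post) != 2 || keywords_per_post[1] < 1 ||
      keywords_per_post[2] < keywords_per_post[1]) {
    stop("keywords_per_post must be an increasing range starting at >= 1",
         call. = FALSE)
  }
  structure(
    list(
      n_posts = as.integer(n_posts),
      topic_mixture = topic_mixture,
      irrelevant_fraction = irrelevant_fraction,
      excluded_subreddit_fraction = excluded_subreddit_fraction,
      keywords_per_post = keywords_per_post,
      filler_vocab_size = as.integer(filler_vocab_size),
      trigger_phrase_rate = trigger_phrase_rate,
      confusable_rate = confusable_rate,
      included_subreddits = normalize_subreddit(included_subreddits),
      excluded_subreddits = normalize_subreddit(excluded_subreddits),
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

.trigger_phrases <- c(
  "get tested for", "got tested for", "get checked for", "got checked for",
  "should i get tested for", "want to get checked for"
)

#' Generate a synthetic corpus with planted ground truth
#'
#' Each relevant post draws a topic from the mixture and embeds one or more
#' of that topic's keyword phrases amid nonsense filler; with probability
#' `trigger_phrase_rate` it also carries a proximity-query-satisfying
#' phrase. Irrelevant posts carry filler (and possibly a trigger phrase)
#' but no lexicon keyword. A configured fraction of posts lands in excluded
#' subreddits. The truth table records the planted topic of every post
#' (`"irrelevant"` for noise posts), so selection, assignment, analytics
#' and review tooling can all be scored without any external data.
#'
#' @param config A [generator_config()].
#' @param lex A [keyword_lexicon()]; mixture topics must exist in it.
#' @return List with `corpus` (a [as_corpus()] object) and `truth` (tibble:
#'   `post_id`, `planted_topic`, `in_excluded_subreddit`, `has_trigger`).
#' @export
generate_corpus <- function(config, lex) {
  stopifnot(inherits(config, "generator_config"),
            inherits(lex, "keyword_lexicon"))
  topics <- lex$topic[lex$topic != "nonmedical"]
  mixture <- config$topic_mixture
  if (is.null(mixture)) {
    mixture <- stats::setNames(rep(1 / length(topics), length(topics)), topics)
  }
  unknown <- setdiff(names(mixture), lex$topic)
  if (length(unknown) > 0) {
    stop("topic_mixture references unknown topic(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  n <- config$n_posts
  if (n == 0) {
    return(list(corpus = empty_corpus("synthetic"),
                truth = tibble::tibble(post_id = character(),
                                       planted_topic = character(),
                                       in_excluded_subreddit = logical(),
                                       has_trigger = logical())))
  }

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
  set.seed(config$seed)

  filler <- filler_vocab(config$filler_vocab_size, lex)
  kw_lo <- config$keywords_per_post[1]
  kw_hi <- config$keywords_per_post[2]

  post_id <- sprintf("p%06d", seq_len(n))
  in_excluded <- stats::runif(n) < config$excluded_subreddit_fraction
  irrelevant <- in_excluded | (stats::runif(n) < config$irrelevant_fraction)
  has_trigger <- stats::runif(n) < config$trigger_phrase_rate
  planted <- rep("irrelevant", n)
  rel <- which(!irrelevant)
  planted[rel] <- sample(names(mixture), length(rel), replace = TRUE,
                         prob = mixture)

  subreddit <- character(n)
  subreddit[in_excluded] <- sample(config$excluded_subreddits,
                                   sum(in_excluded), replace = TRUE)
  subreddit[!in_excluded] <- sample(config$included_subreddits,
                                    sum(!in_excluded), replace = TRUE)

  title <- character(n)
  body <- character(n)
  for (i in seq_len(n)) {
    chunks <- list(sample(filler, sample(6:14, 1), replace = TRUE))
    if (planted[i] != "irrelevant") {
      kws <- lex$keywords[[match(planted[i], lex$topic)]]
      k <- sample(seq(kw_lo, kw_hi), 1)
      chunks <- c(chunks, as.list(sample(kws, min(k, length(kws)))))
      if (config$confusable_rate > 0 &&
          stats::runif(1) < config$confusable_rate) {
        other <- sample(setdiff(names(mixture), planted[i]), 1)
        chunks <- c(chunks,
                    sample(lex$keywords[[match(other, lex$topic)]], 1))
      }
    }
    if (has_trigger[i]) {
      chunks <- c(chunks, sample(.trigger_phrases, 1))
    }
    chunks <- c(chunks, list(sample(filler, sample(4:10, 1), replace = TRUE)))
    body[i] <- paste(unlist(sample(chunks)), collapse = " ")
    title[i] <- paste(sample(filler, sample(2:5, 1), replace = TRUE),
                      collapse = " ")
  }

  corpus <- as_corpus(
    tibble::tibble(
      post_id = post_id,
      subreddit = subreddit,
      created_date = as.Date("2019-01-01") + sample.int(365, n, replace = TRUE) - 1,
      title = title,
      body = body,
      is_comment = stats::runif(n) < 0.3
    ),
    provenance = sprintf("synthetic (seed %d)", config$seed)
  )
  truth <- tibble::tibble(
    post_id = post_id,
    planted_topic = planted,
    in_excluded_subreddit = in_excluded,
    has_trigger = has_trigger
  )
  list(corpus = corpus, truth = truth)
}

# Nonsense filler words ("zq1x", "zq2x", ...) that survive tokenization as
# single tokens, are lemma-stable (digits block suffix rules), and never
# collide with lexicon keywords or query terms.
filler_vocab <- function(size, lex) {
  vocab <- sprintf("zq%dx", seq_len(size))
  kw_tokens <- unique(unlist(lapply(unlist(lex$keywords), tokenize)))
  vocab <- setdiff(vocab, c(kw_tokens, unlist(default_query()$groups)))
  vocab
}

#' Generate a synthetic keyword lexicon
#'
#' Builds a valid lexicon of `n_topics` topics (including the reserved
#' `nonmedical` fallback) spread round-robin over `n_disciplines`
#' disciplines (including the fallback's own), with keyword sets that are
#' pairwise disjoint by construction, so tie-breaking never activates and
#' [validate_lexicon()] is clean. `generate_toy_lexicon(82, 17)` reproduces
#' the shape of the default taxonomy.
#'
#' @param n_topics Total number of topics, counting `nonmedical`.
#' @param n_disciplines Total number of disciplines, counting `nonmedical`.
#' @param seed Integer seed (keyword counts are drawn from it).
#' @return A [keyword_lexicon()].
#' @export
generate_toy_lexicon <- function(n_topics, n_disciplines, seed = 1) {
  if (n_disciplines < 1 || n_topics < n_disciplines) {
    stop("need n_topics >= n_disciplines >= 1", call. = FALSE)
  }
  n_named <- n_topics - 1
  n_named_disc <- n_disciplines - 1
  if (n_named > 0 && n_named_disc == 0) {
    stop("cannot place ", n_named, " named topics with no named disciplines",
         call. = FALSE)
  }
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
  if (n_named == 0) {
    return(keyword_lexicon(tibble::tibble(
      topic = character(), discipline = character(), keywords = list()
    )))
  }
  disc_names <- sprintf("disc%02d", seq_len(n_named_disc))
  topics <- tibble::tibble(
    topic = sprintf("topic%03d", seq_len(n_named)),
    discipline = disc_names[((seq_len(n_named) - 1) %% length(disc_names)) + 1],
    keywords = lapply(seq_len(n_named), function(i) {
      k <- sample(2:4, 1)
      # single- and two-word phrases, all carrying the topic index
      kws <- sprintf("t%03dkw%d", i, seq_len(k))
      if (k > 2) {
        kws[k] <- paste(kws[k], sprintf("t%03dtail", i))
      }
      kws
    })
  )
  keyword_lexicon(topics)
}
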