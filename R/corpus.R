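#' Construct a corpus of forum posts
#'
#' A corpus is a tibble of posts with one row per post or comment and a
#' `provenance` attribute recording where it came from. Subreddit names are
#' normalized (leading `"r/"` stripped, lowercased) so that filters and
#' per-subreddit tabulations never depend on how the name was written.
#'
#' @param posts A data frame with columns `post_id`, `subreddit`,
#'   `created_date`, `title`, `body`, `is_comment`.
#' @param provenance Free-text label describing the origin of the corpus.
#' @return A `corpus` object (a tibble subclass).
#' @details Invariants enforced here: non-empty unique `post_id`; parseable
#'   ISO-8601 `created_date`; at least one of `title`/`body` non-empty per
#'   post. Comments are expected to carry their parent submission's title in
#'   `title` (resolved at ingest time, not by this package), because the
#'   title provides the context used for matching.
#' @export
as_corpus <- function(posts, provenance = "unspecified") {
  posts <- tibble::as_tibble(posts)
  required <- c("post_id", "subreddit", "created_date", "title", "body", "is_comment")
  missing_cols <- setdiff(required, names(posts))
  if (length(missing_cols) > 0) {
    stop("corpus is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  posts <- posts[required]
  posts$post_id <- as.character(posts$post_id)
  posts$subreddit <- normalize_subreddit(as.character(posts$subreddit))
  posts$title <- as.character(posts$title)
  posts$body <- as.character(posts$body)
  posts$is_comment <- as.logical(posts$is_comment)
  if (!inherits(posts$created_date, "Date")) {
    dates <- as.Date(as.character(posts$created_date), format = "%Y-%m-%d")
    if (anyNA(dates) && nrow(posts) > 0) {
      bad <- which(is.na(dates))[1]
      stop("unparseable created_date for post_id '", posts$post_id[bad],
           "' (expected YYYY-MM-DD)", call. = FALSE)
    }
    posts$created_date <- dates
  }
  if (any(!nzchar(posts$post_id))) {
    stop("empty post_id in corpus", call. = FALSE)
  }
  if (anyDuplicated(posts$post_id)) {
    dup <- posts$post_id[duplicated(posts$post_id)][1]
    stop("duplicate post_id '", dup, "' in corpus", call. = FALSE)
  }
  empty_both <- !nzchar(posts$title) & !nzchar(posts$body)
  if (any(empty_both)) {
    stop("post '", posts$post_id[which(empty_both)[1]],
         "' has empty title and body", call. = FALSE)
  }
  structure(posts,
            provenance = provenance,
            class = c("corpus", class(posts)))
}

#' Normalize a subreddit name
#'
#' Strips a leading `"r/"` (any case) and lowercases, so `"r/AskDocs"`,
#' `"askdocs"` and `"ASKDOCS"` all refer to the same forum. Idempotent.
#'
#' @param x Character vector of subreddit names.
#' @return Normalized character vector.
#' @export
normalize_subreddit <- function(x) {
  tolower(sub("^([rR]/)+", "", x))
}

#' Read a post corpus from line-delimited JSON
#'
#' One JSON object per line with fields `post_id`, `subreddit`,
#' `created_date` (`"YYYY-MM-DD"`), `title`, `body`, `is_comment`. Input
#' order is preserved; subreddits are normalized on read.
#'
#' @param path Path to a JSONL file.
#' @return A [as_corpus()] object with `provenance` set to the path.
#' @export
read_posts <- function(path) {
  if (!file.exists(path)) {
    stop("no such file: ", path, call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(empty_corpus(provenance = path))
  }
  records <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
      error = function(e) {
        stop("malformed JSON on line ", i, " of ", path, ": ",
             conditionMessage(e), call. = FALSE)
      }
    )
    required <- c("post_id", "subreddit", "created_date", "title", "body",
                  "is_comment")
    missing_fields <- setdiff(required, names(rec))
    if (length(missing_fields) > 0) {
      stop("line ", i, " of ", path, " is missing field(s): ",
           paste(missing_fields, collapse = ", "), call. = FALSE)
    }
    records[[i]] <- tibble::tibble(
      post_id = as.character(rec$post_id),
      subreddit = as.character(rec$subreddit),
      created_date = as.character(rec$created_date),
      title = as.character(rec$title),
      body = as.character(rec$body),
      is_comment = as.logical(rec$is_comment)
    )
  }
  posts <- dplyr::bind_rows(records)
  if (anyDuplicated(posts$post_id)) {
    dup <- posts$post_id[duplicated(posts$post_id)][1]
    stop("duplicate post_id '", dup, "' in ", path, call. = FALSE)
  }
  as_corpus(posts, provenance = path)
}

#' Write a post corpus as line-delimited JSON
#'
#' Inverse of [read_posts()]: `read_posts(write_posts(corpus, path))`
#' reproduces the corpus field for field (subreddits are already normalized
#' in any valid corpus, so normalization on re-read is the identity).
#'
#' @param corpus A corpus.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_posts <- function(corpus, path) {
  lines <- character(nrow(corpus))
  for (i in seq_len(nrow(corpus))) {
    lines[i] <- jsonlite::toJSON(
      list(
        post_id = corpus$post_id[i],
        subreddit = corpus$subreddit[i],
        created_date = format(corpus$created_date[i], "%Y-%m-%d"),
        title = corpus$title[i],
        body = corpus$body[i],
        is_comment = corpus$is_comment[i]
      ),
      auto_unbox = TRUE
    )
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Matchable text of a post
#'
#' The text that selection and topic assignment operate on: the title and
#' body joined with a single space (no separator when either side is empty).
#' Titles are included because they give comments and short posts their
#' context.
#'
#' @param title,body Character vectors (recycled to a common length).
#' @return Character vector of joined texts.
#' @examples
#' matchable_text("Worried", "should I get tested for HIV")
#' @export
matchable_text <- function(title, body) {
  if (is.data.frame(title)) {
    body <- title$body
    title <- title$title
  }
  ifelse(
    nzchar(title) & nzchar(body), paste(title, body),
    ifelse(nzchar(title), title, body)
  )
}

# An empty but schema-complete corpus.
empty_corpus <- function(provenance = "empty") {
  as_corpus(
    tibble::tibble(
      post_id = character(), subreddit = character(),
      created_date = as.Date(character()), title = character(),
      body = character(), is_comment = logical()
    ),
    provenance = provenance
  )
}

#' @export
print.corpus <- function(x, ...) {
  cat("<corpus> ", nrow(x), " posts (provenance: ",
      attr(x, "provenance"), ")\n", sep = "")
  NextMethod()
}
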