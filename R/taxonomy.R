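#' Construct a keyword lexicon
#'
#' A keyword lexicon maps each topic to one parent medical discipline
#' (chapter-level groupings modeled on the ICD-10) and to a list of trigger
#' keyword phrases. The reserved fallback topic `"nonmedical"` (own
#' discipline, empty keyword list) is always present: posts matching no
#' keyword fall back to it.
#'
#' @param topics A data frame with columns `topic`, `discipline`, and
#'   `keywords` (a list column of character vectors). File/argument order is
#'   preserved and serves as the final assignment tie-break.
#' @return A `keyword_lexicon` object: a tibble with columns `topic`,
#'   `discipline`, `keywords` (phrases as written) and `lemmas` (each phrase
#'   pre-lemmatized into a token vector).
#' @export
keyword_lexicon <- function(topics) {
  topics <- tibble::as_tibble(topics)
  stopifnot(all(c("topic", "discipline", "keywords") %in% names(topics)))
  topics$topic <- as.character(topics$topic)
  topics$discipline <- as.character(topics$discipline)
  if (!"nonmedical" %in% topics$topic) {
    topics <- dplyr::bind_rows(
      topics,
      tibble::tibble(topic = "nonmedical", discipline = "nonmedical",
                     keywords = list(character()))
    )
  }
  if (anyDuplicated(topics$topic)) {
    dup <- topics$topic[duplicated(topics$topic)][1]
    stop("duplicate topic '", dup, "' in lexicon", call. = FALSE)
  }
  nm <- topics$topic == "nonmedical"
  if (any(lengths(topics$keywords[nm]) > 0)) {
    stop("the reserved topic 'nonmedical' must have no keywords", call. = FALSE)
  }
  if (any(lengths(topics$keywords[!nm]) == 0)) {
    bad <- topics$topic[!nm][lengths(topics$keywords[!nm]) == 0][1]
    stop("topic '", bad, "' has no keywords", call. = FALSE)
  }
  topics$keywords <- lapply(topics$keywords, function(k) tolower(as.character(k)))
  topics$lemmas <- lapply(topics$keywords, function(k) lapply(k, normalize_tokens))
  structure(topics, class = c("keyword_lexicon", class(topics)))
}

#' Load a keyword lexicon from YAML
#'
#' The file format mirrors the taxonomy: a top-level `disciplines` mapping,
#' each discipline holding topics, each topic holding its keyword list:
#'
#' ```yaml
#' disciplines:
#'   infectious diseases:
#'     STIs: [chlamydia, gonorrhea, bacterial vaginosis]
#' ```
#'
#' The reserved `nonmedical` topic is implicit and appended automatically.
#' Topic order follows file order.
#'
#' @param path Path to a lexicon YAML file.
#' @return A [keyword_lexicon()].
#' @export
load_lexicon <- function(path) {
  if (!file.exists(path)) {
    stop("no such file: ", path, call. = FALSE)
  }
  doc <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop("cannot parse lexicon YAML ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
  if (is.null(doc)) {
    doc <- list()
  }
  extra <- setdiff(names(doc), "disciplines")
  if (length(extra) > 0) {
    stop("unknown top-level section(s) in lexicon: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  disc <- doc$disciplines
  rows <- list()
  seen <- character()
  for (dname in names(disc)) {
    topics <- disc[[dname]]
    for (tname in names(topics)) {
      if (tname %in% seen) {
        stop("topic '", tname, "' appears under two disciplines in ", path,
             call. = FALSE)
      }
      seen <- c(seen, tname)
      rows[[length(rows) + 1]] <- tibble::tibble(
        topic = tname, discipline = dname,
        keywords = list(as.character(unlist(topics[[tname]])))
      )
    }
  }
  topics <- if (length(rows) > 0) {
    dplyr::bind_rows(rows)
  } else {
    tibble::tibble(topic = character(), discipline = character(),
                   keywords = list())
  }
  keyword_lexicon(topics)
}

#' Write a keyword lexicon to YAML
#'
#' Inverse of [load_lexicon()] (the implicit `nonmedical` topic is not
#' written): `load_lexicon(write_lexicon(lex, path))` equals `lex`.
#'
#' @param lex A [keyword_lexicon()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lex, path) {
  lex <- lex[lex$topic != "nonmedical", , drop = FALSE]
  disciplines <- list()
  for (i in seq_len(nrow(lex))) {
    d <- lex$discipline[i]
    if (is.null(disciplines[[d]])) {
      disciplines[[d]] <- list()
    }
    disciplines[[d]][[lex$topic[i]]] <- lex$keywords[[i]]
  }
  yaml::write_yaml(list(disciplines = disciplines), path)
  invisible(path)
}

#' The bundled default health-topic lexicon
#'
#' Loads the lexicon shipped with the package: 82 topics in 17 medical
#' disciplines (including the reserved `nonmedical` fallback). The topic
#' and discipline structure follows the published taxonomy for health
#' discussion on Reddit; the keyword lists are a documented reconstruction
#' seeded from phrases quoted in that work, and users are expected to extend
#' them for serious use.
#'
#' @return A [keyword_lexicon()].
#' @export
default_lexicon <- function() {
  load_lexicon(system.file("extdata", "default_lexicon.yaml",
                           package = "httag", mustWork = TRUE))
}

#' Report keyword collisions in a lexicon
#'
#' Keyword overlap between topics biases assignment (a phrase such as
#' "difficulty urinating" could plausibly trigger two topics), so the
#' validator reports, as findings rather than failures:
#' * `collision` — the identical (lemmatized) phrase under two or more
#'   topics;
#' * `prefix` — a phrase that is a strict prefix of another topic's longer
#'   phrase, which the longer phrase's occurrences will always co-trigger.
#'
#' @param lex A [keyword_lexicon()].
#' @return A tibble of findings with columns `type`, `phrase`, `topics`;
#'   zero rows when clean.
#' @export
validate_lexicon <- function(lex) {
  stopifnot(inherits(lex, "keyword_lexicon"))
  phrases <- dplyr::bind_rows(lapply(seq_len(nrow(lex)), function(i) {
    lem <- lex$lemmas[[i]]
    if (length(lem) == 0) {
      return(NULL)
    }
    tibble::tibble(
      topic = lex$topic[i],
      phrase = vapply(lem, paste, character(1), collapse = " "),
      lemmas = lem
    )
  }))
  findings <- list()
  if (nrow(phrases) == 0) {
    return(tibble::tibble(type = character(), phrase = character(),
                          topics = character()))
  }
  by_phrase <- split(phrases$topic, phrases$phrase)
  for (ph in names(by_phrase)) {
    tps <- unique(by_phrase[[ph]])
    if (length(tps) > 1) {
      findings[[length(findings) + 1]] <- tibble::tibble(
        type = "collision", phrase = ph,
        topics = paste(sort(tps), collapse = " | ")
      )
    }
  }
  for (i in seq_len(nrow(phrases))) {
    pi <- phrases$lemmas[[i]]
    for (j in seq_len(nrow(phrases))) {
      if (phrases$topic[i] == phrases$topic[j]) next
      pj <- phrases$lemmas[[j]]
      if (length(pi) < length(pj) && identical(pi, pj[seq_along(pi)])) {
        findings[[length(findings) + 1]] <- tibble::tibble(
          type = "prefix", phrase = phrases$phrase[i],
          topics = paste0(phrases$topic[i], " < ", phrases$topic[j],
                          " ('", phrases$phrase[j], "')")
        )
      }
    }
  }
  if (length(findings) == 0) {
    return(tibble::tibble(type = character(), phrase = character(),
                          topics = character()))
  }
  dplyr::distinct(dplyr::bind_rows(findings))
}

#' Look up the discipline of a topic
#'
#' @param lex A [keyword_lexicon()].
#' @param topic Topic name.
#' @return The unique discipline name.
#' @examples
#' discipline_of(default_lexicon(), "STIs") # "infectious diseases"
#' @export
discipline_of <- function(lex, topic) {
  stopifnot(inherits(lex, "keyword_lexicon"), length(topic) == 1)
  i <- match(topic, lex$topic)
  if (is.na(i)) {
    stop("unknown topic '", topic, "'", call. = FALSE)
  }
  lex$discipline[i]
}

#' @export
print.keyword_lexicon <- function(x, ...) {
  cat("<keyword_lexicon> ", nrow(x), " topics, ",
      length(unique(x$discipline)), " disciplines, ",
      sum(lengths(x$keywords)), " keyword phrases\n", sep = "")
  NextMethod()
}
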