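#' Rule-based English lemmatizer
#'
#' Collapses regular plural and verb inflections so that inflected post
#' tokens match lexicon keywords: "tests", "tested", "testing" -> "test";
#' "checked" -> "check"; "bodies" -> "body". The same function is applied to
#' keyword phrases at lexicon load and to post tokens at assignment time, so
#' matching only requires the mapping to be consistent, not dictionary-
#' perfect: a stem such as "smoking" -> "smok" still matches because both
#' sides are reduced identically.
#'
#' Rules, in order, per token: a small irregular-noun table; `-ies -> -y`;
#' `-es` after sibilants stripped; a final `-s` (not `-ss`/`-us`/`-is`)
#' stripped; `-ied -> -y`; `-ed` and `-ing` stripped when the remaining stem
#' has at least three characters and a vowel, with a doubled final consonant
#' undoubled (except `ll`, `ss`, `zz`). Tokens of three characters or fewer
#' and tokens containing digits pass through unchanged.
#'
#' @param tokens Character vector of lowercase word tokens.
#' @return Character vector of lemmas, same length.
#' @examples
#' lemmatize(c("tests", "tested", "testing", "checked", "running"))
#' @export
lemmatize <- function(tokens) {
  if (length(tokens) == 0) {
    return(character())
  }
  vapply(tokens, lemmatize_one, character(1), USE.NAMES = FALSE)
}

.irregular_lemmas <- c(
  men = "man", women = "woman", children = "child", teeth = "tooth",
  feet = "foot", mice = "mouse", geese = "goose", wives = "wife",
  lives = "life", knives = "knife",
  # uninflected despite a removable-looking ending
  news = "news", lens = "lens", species = "species", scabies = "scabies",
  herpes = "herpes", rabies = "rabies", diabetes = "diabetes"
)

lemmatize_one <- function(w) {
  hit <- .irregular_lemmas[w]
  if (!is.na(hit)) {
    return(unname(hit))
  }
  n <- nchar(w)
  if (n <= 3 || grepl("[0-9]", w)) {
    return(w)
  }
  has_vowel <- function(s) grepl("[aeiouy]", s)
  # plural-style endings
  if (n >= 5 && endsWith(w, "ies")) {
    return(paste0(substr(w, 1, n - 3), "y"))
  }
  if (grepl("(x|ch|sh|ss|z)es$", w)) {
    return(sub("es$", "", w))
  }
  if (grepl("[^sui]s$", w)) {
    return(substr(w, 1, n - 1))
  }
  # past tense
  if (n >= 5 && endsWith(w, "ied")) {
    return(paste0(substr(w, 1, n - 3), "y"))
  }
  if (endsWith(w, "ed") && !endsWith(w, "eed")) {
    stem <- substr(w, 1, n - 2)
    if (nchar(stem) >= 3 && has_vowel(stem)) {
      return(undouble(stem))
    }
  }
  # progressive
  if (endsWith(w, "ing")) {
    stem <- substr(w, 1, n - 3)
    if (nchar(stem) >= 3 && has_vowel(stem)) {
      return(undouble(stem))
    }
  }
  w
}

# "stopp" -> "stop", "runn" -> "run"; keep "ll"/"ss"/"zz" (fall, miss, buzz).
undouble <- function(stem) {
  n <- nchar(stem)
  last <- substr(stem, n, n)
  prev <- substr(stem, n - 1, n - 1)
  if (n >= 3 && last == prev && !last %in% c("l", "s", "z") &&
      !grepl("[aeiou]", last)) {
    return(substr(stem, 1, n - 1))
  }
  stem
}

#' Tokenize and lemmatize text
#'
#' [tokenize()] followed by [lemmatize()]; the normal-form token sequence
#' on which keyword matching operates.
#'
#' @param text A single character string.
#' @return Character vector of lemma tokens.
#' @examples
#' normalize_tokens("tested positive") # "test" "positive"
#' @export
normalize_tokens <- function(text) {
  lemmatize(tokenize(text))
}
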