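Package: httag
Title: Lexicon-Based Health Topic Tagging for Social Media Posts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mining health-related discussion from Reddit-style
    forum corpora. Selects posts with a boolean proximity query (terms such
    as "get tested" or "got checked" within a token window), filters posts by
    subreddit and irrelevant-term lists, assigns exactly one health topic per
    post by lemmatized keyword matching against an editable lexicon of topics
    grouped into ICD-10-chapter-style medical disciplines, and summarises the
    result as topic and discipline frequency tables, per-subreddit top-topic
    reports, and top-5 coverage statistics. Includes tooling for blinded
    manual-review sampling with accuracy and false-positive-rate statistics,
    and a synthetic corpus generator with planted ground truth for end-to-end
    testing. A command-line entry point wires the stages into a reproducible
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
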