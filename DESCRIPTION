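Package: rxcritic
Title: Guideline-Based Critiquing of Drug Prescriptions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compiles structured therapeutic recommendations from clinical
    practice guidelines, together with eight guideline-independent generic
    recommendations, into executable "if conditions then criticism" rules, and
    critiques physician prescriptions against a patient's therapeutic history.
    Knowledge bases declare drug classes (sets of ATC codes), recommendable
    treatments, and recommendations with per-line criticism labels; the
    inference engine fires the compiled rules on the proposed prescription,
    composes a human-readable critique, computes treatment suggestions, and
    progressively relaxes line-of-treatment rules when no suggestion survives.
    Verification tools enumerate the knowledge base's input-vector space,
    regenerate its behaviour as an unpruned gain-ratio decision tree, and
    generate seeded test bases of recommended and random non-recommended
    prescriptions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    yaml,
    jsonlite,
    tibble,
    generics,
    ggplot2,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    rpart,
    withr
Config/testthat/edition: 3
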