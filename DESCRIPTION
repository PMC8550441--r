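Package: equiset
Title: Discovery of Multiple Statistically Equivalent Markov Blankets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-backward Markov blanket selection for tabular data with a
    backtracking multiple-solutions search (TMFBS), sound pruning rules, a
    TIE*-IGS baseline, statistical tests of feature-set equivalence
    (permutation variance test, information-equivalence likelihood-ratio
    tests, J-test), a compressed multiple-solutions graph representation of
    the solution family, and a synthetic-data generator with known
    ground-truth blanket families.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
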