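Package: caremap
Title: Dual Capability Portraits and Service-Need Mapping for Community
    Elderly Care
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Decision-support engine for identifying community age-friendly
    service needs from dual digital capability portraits. Encodes each older
    adult's individual functional capability (28 ordinal indicators) and
    family caregiving capability (8 ordinal indicators) as 0-4 score vectors,
    translates capability states into candidate services through total
    rule-based mapping matrices, and re-prioritizes candidates with a
    user-based collaborative-filtering layer over portrait similarity.
    Includes community-level aggregation and risk screening, a correlated
    latent-Gaussian generator for synthetic populations, CSV/JSON readers and
    writers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
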