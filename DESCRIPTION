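Package: elicitsn
Title: Five-Step Expert Elicitation of Skew-Normal Priors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for eliciting expert judgment as a skew-normal prior
    distribution using a five-step protocol: digitized trial-roulette
    (chips-and-bins) capture of a location estimate, maximum-likelihood
    fitting of the Fernandez-Steel skew normal with moments held fixed,
    construction of a full prior from a location estimate plus reasonable
    lower and upper bounds, linear rescaling so experts elicited on
    different scales become comparable, and Bayesian updating of the
    elicited prior against data including a prior-data conflict
    diagnostic. A synthetic-expert simulator makes the whole pipeline
    testable without human input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    graphics,
    jsonlite,
    pracma,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
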