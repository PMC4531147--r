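Package: gubsc
Title: Behavioural Specification and Compilation of Synthetic Gene Circuits
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A domain-specific language for describing the expected
    observations of a synthetic biological function as causal relations
    between agents (genes, proteins), together with a compiler that selects
    and assembles components from a part library so that the assembly's
    described behaviour logically covers the programmed behaviour.
    Programs are interpreted over linear Kripke models built from
    experimental histories; covering is established by constraint-based
    pre-selection of component subsets, ACI-unification of causal rules
    with substitution of variable agents by library constants, and a
    directed evolutionary search for large libraries.  Includes bounded
    model checking of behavioural inclusion and observability, XML/JSON
    component-library input/output, a reproducible benchmark generator,
    and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    xml2,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
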