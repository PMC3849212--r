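Package: agemapr
Title: Literature-Derived Mouse-Human Age Mapping for Disease Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Mines age and disease mentions from MEDLINE-format abstracts,
    stores the resulting evidence in a three-table knowledgebase, builds
    normalized age-disease frequency matrices for mouse (1-day bins) and
    human (1-year bins), estimates a disease-specific age shift between the
    two species by maximizing the Pearson correlation over all lags of the
    human pattern against the mouse pattern, and exposes the resulting
    disease-specific mouse-to-human age map as a queryable object. Also
    provides hierarchical clustering of diseases by their age pattern and a
    fully seeded synthetic-data generator (toy ontologies, template corpora
    with gold annotations, matrix pairs with planted shifts) used to
    validate every stage against known ground truth.
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
    ape
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
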