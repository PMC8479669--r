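Package: gmsca
Title: Gene Multifunctionality via Secondary Co-Expression Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds weighted gene co-expression networks from bulk-tissue
    expression, annotates modules with cell types by marker enrichment,
    removes each cell type's expression signal by principal-component
    subtraction to build secondary networks, and classifies genes as
    typed, activated, deactivated or multifunctional to uncover multiple
    <gene, cell type, function> annotations per gene. Includes a synthetic
    bulk-expression generator with planted cell-type modules and validation
    statistics (module preservation Z-summary, specificity matrices,
    bootstrap expression enrichment, phenotype-term coverage/fold-change).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    mclust
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
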