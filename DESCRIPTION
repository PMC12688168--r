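Package: chemoresistome
Title: Longitudinal Gene-Pattern Classification and Chemoresistome Mapping
        for Matched Tumor Triplets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
        role = c("aut", "cre"))
Description: Analysis pipeline for longitudinal transcriptomics of matched
        normal / pretreatment / posttreatment tumor triplets from patients
        receiving neoadjuvant chemotherapy. Classifies per-gene per-patient
        expression trajectories into eight theoretical temporal patterns by
        maximal correlation, derives response-associated and persistently
        dysregulated ("resistance") genes, computes per-patient per-pathway
        resistance scores with a bootstrap null, and computes a simplified
        principal-curve pathway deregulation score. Ships a negative-binomial
        synthetic cohort generator with planted ground truth so the whole
        pipeline is testable without access to patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    tools,
    survival,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
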