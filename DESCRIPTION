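Package: tanninflow
Title: Kendrick Mass Defect, Compound-Class and Genome-Resolved
    Metaproteome Analysis of Condensed Tannin Degradation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for tracking anaerobic condensed-tannin (CT)
    depolymerization in soil reactors. Implements Kendrick mass defect (KMD)
    analysis of FTICR-MS peak lists with the (epi)catechin repeat unit as the
    Kendrick base, a theoretical CT oligomer ion ladder (charge states,
    13C isotopologues) for peak classification, simplified CHO molecular
    formula assignment with van Krevelen compound-class quantitation,
    genome-resolved metaproteome quantitation (peptide uniqueness classes,
    normalized spectral abundance factors, MAG contribution profiles and a
    coverage-based MAG presence rule), moderated differential-abundance
    calling on log2 metabolite peak areas, and a synthetic-data generator
    that emulates all pipeline inputs for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
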