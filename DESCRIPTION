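Package: ravarkit
Title: Reproducibility-Graded Curation of Rheumatoid Arthritis Risk Variants and Genetic Risk Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Toolkit for curating genetic-association evidence for rheumatoid
    arthritis and predicting an individual's genetic risk. Association results
    from genome-wide and follow-up studies are re-graded under dual significance
    regimes, grouped into nine geographical populations, reduced to one
    representative association per variant and population (largest case count),
    and classified as inter-population reproduced, intra-population reproduced,
    or unconfirmed, with opposite-direction associations excluded. Confirmed
    markers are pruned to one lead variant per linkage-disequilibrium locus and
    combined into a weighted genetic risk score (log odds ratio, additive in
    risk-allele copy number), a per-marker and overall relative genetic risk
    normalized by the Hardy-Weinberg population-average risk, and a lifetime
    risk (relative risk times population prevalence). A synthetic association
    generator with planted reproducibility classes supports end-to-end testing.
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
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
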