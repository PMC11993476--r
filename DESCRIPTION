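Package: adcscreen
Title: Antibody-Drug Conjugate Target Nomination and Payload Screening from
    Paired Tumor-Normal Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable pipeline for nominating antibody-drug
    conjugate (ADC) targets and payloads from paired tumor versus
    normal-adjacent-tissue (NAT) protein abundance data. Stages cover paired
    differential proteomics with Benjamini-Hochberg FDR control, filtering of
    candidates to the cell-surface proteome, an ordinal normal-tissue
    expression index, per-patient tumor-specificity profiling, and a
    druggable-target screen against drug catalogs. Downstream quantifications
    include antibody internalization kinetics from flow-cytometry MFI time
    series, radial-distance proximity statistics on multiplexed
    immunofluorescence cell maps, median-split immune-fraction associations,
    and small clinical metrics (IHC H-score, caliper tumor volume,
    chromosomal-instability classification, mutation-prevalence contingency).
    A synthetic-data module generates every pipeline input with planted
    ground truth so all stages are testable without external data.
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
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
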