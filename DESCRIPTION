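Package: intprofiler
Title: Retroviral Vector Integration-Site Profiling from Simulated LM-PCR Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses retroviral vector integration-site
    cohorts recovered by ligation-mediated PCR (LM-PCR). Generates a
    synthetic multi-chromosome reference genome with a non-overlapping gene
    annotation and labelled gene sets (e.g. cancer-related genes), draws
    integration-site cohorts from a mixture of a genome-uniform background
    and a component enriched near transcription start sites (TSS), and
    simulates junction libraries under an MseI/PstI restriction digest with
    linker ligation and nested PCR. Downstream stages parse junction reads
    into genomic flanks, place each flank on the reference with a unique
    best-hit substitution-only mapper, collapse reads to independent
    integration sites, classify sites relative to transcriptional units,
    TSS windows and labelled genes, build TSS-centred integration density
    profiles, and compare cohorts with 2x2 chi-square or Fisher exact
    tests, reproducing the foamy-virus versus gammaretroviral vector
    TSS-proximity contrast used in genotoxicity screening.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
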