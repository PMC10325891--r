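Package: ratioscreen
Title: Simulation and Analysis of Ratiometric FACS-Based CRISPRi Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pooled CRISPR interference screens read out by
    fluorescence-activated sorting of a dual-fluorescence translation
    reporter (GFP driven by a near-cognate start codon, normalised by
    IRES-driven mCherry). Provides a generative simulator of polyclonal
    reporter populations and tail-sorted, sequenced screen count tables;
    sgRNA and gene-level enrichment statistics with a Mann-Whitney
    non-targeting null, Fisher replicate combination and an empirical
    quasi-gene hit threshold; flow-cytometry gating and internally
    controlled reporter phenotypes; dual-sgRNA additive interaction
    calls; perturbation-profile embedding and clustering; and gene-set
    over-representation summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
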