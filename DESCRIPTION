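Package: dgmr
Title: Drug-Target Mendelian Randomization for the Druggable Genome
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A summary-statistics pipeline for druggable-genome drug-target
    discovery: cis-eQTL instrumental-variable selection (transcription-start-site
    window, false-discovery-rate filter, confounder blocklist, greedy LD
    clumping), allele harmonization across exposure and outcome studies,
    two-sample Mendelian randomization (Wald ratio, inverse-variance weighted,
    MR-Egger, weighted median) with Steiger directionality and
    Benjamini-Hochberg control, Bayesian colocalization via Wakefield
    approximate Bayes factors, phenome-wide on-target safety screening, and a
    tiered drug-repurposing triage. Includes a ground-truth summary-statistics
    simulator (LD-blocked loci, eQTL and case-control GWAS effect sizes,
    shared versus distinct causal variants) so that every stage is testable
    without external consortium data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
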