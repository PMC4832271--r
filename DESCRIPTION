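Package: ebfine
Title: Empirical Bayes Fine-Mapping with Functional Annotation Priors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fine-mapping of case-control association signals using Wakefield
    approximate Bayes factors with an empirical-Bayes prior variance for the
    log odds ratio, expert-elicited functional-group prior probabilities of
    causal association, and posterior-probability ranking and filtering of
    SNPs. Includes an LD-block haplotype and retrospective case-control
    genotype simulator, per-SNP logistic association summaries, elicitation
    solvers for group priors, and threshold-averaged ROC evaluation across
    simulated replicates.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
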