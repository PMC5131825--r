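Package: zfdiv
Title: Multiparameter Functional-Diversity Analysis of C2H2 Zinc-Finger
    Transcription Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the functional diversity of C2H2
    zinc-finger transcription factors from ChIP-seq peak sets, DNA-binding
    motifs, AP-MS protein-protein interaction profiles and perturbation
    expression data. Implements replicate summit merging, base-pair Jaccard
    similarity and replicate specificity; PWM scanning with
    dinucleotide-shuffled AUROC, central-enrichment window selection and
    affinity-cutoff optimisation; genomic-context statistics (feature
    fold-enrichment, histone fold-change, endogenous-retroelement overlap
    and enrichment, SNP-depletion binomial tests); spectral-count
    odds-ratio interaction scoring with low-variation prey filtering and
    regulatory-direction classification; PAM/silhouette profile-count
    estimation with cross-parameter correlation; and a Monte-Carlo
    simulation of neutral codon evolution. A synthetic-data generator
    emulates every input with planted ground truth so the whole pipeline
    is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    pracma,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
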