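Package: clonesel
Title: Somatic Clonal Selection Analysis for UV-Exposed Epidermis and Tumors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify somatic mutational selection in deep targeted
    sequencing of normal epidermis and multi-region tumors, modelled on
    UV-driven mouse skin carcinogenesis studies. Implements a site-specific
    beta-binomial error-model variant caller with a panel of normals, the
    five-rule post-calling filter chain (depth, germline, strand support,
    dinucleotide merging, clone merging across contiguous biopsies),
    trinucleotide-context-normalized dN/dS with likelihood-ratio tests and
    positive/negative selection classification, the summed variant allele
    frequency selection statistic (VAF_ns/VAF_s) with Wilcoxon testing,
    tissue-colonization estimates with copy-number uncertainty bounds,
    penalized least-squares copy-number segmentation with a gamma parameter
    sweep, a priority-rule monoclonal/multifocal tumor clonality classifier,
    and a fully synthetic data generator with known ground truth for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Biostrings,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
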