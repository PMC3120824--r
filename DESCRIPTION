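Package: venomscan
Title: Branch-Site Selection Tests and Physicochemical Divergence
    Profiling for Venom-Targeted Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting episodic positive selection on
    venom-targeted proteins and for characterizing the physicochemical
    consequences of the implicated substitutions.  Implements the
    branch-site codon-model test of positive selection (modified model A
    versus its omega2 = 1 null, Goldman-Yang rate matrix with F3x4
    frequencies, likelihood-ratio test against chi-squared with one
    degree of freedom) with Bayes-Empirical-Bayes identification of
    positively selected sites; per-residue charge and Kyte-Doolittle
    hydropathy change profiles between venom-resistant and non-resistant
    taxon groups with rank-sum and G tests, sliding-window smoothing,
    and a permutation null for the regression of change magnitude on
    distance to annotated toxin-binding sites.  Includes seeded
    simulators for codon alignments evolved under the branch-site
    site-class mixture and for amino-acid alignments carrying localized
    property shifts, so the whole pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
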