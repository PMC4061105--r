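Package: hmmdissect
Title: Segment-Wise Dissection of Profile-HMM Alignment Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs HMMER-style profile hidden Markov model alignment
    scores from the parameters stored in HMMER2-format model files, splits
    the total log-odds score of a model-to-sequence alignment into
    fold-critical and remnant segment contributions, and evaluates each
    contribution independently with Gumbel extreme-value E-values. Domain
    models can be segmented from DSSP secondary-structure annotations, from
    a CLUSTALX-style alignment quality score, or from SEG low-complexity
    masks. Additional tools label hits as true/false positives/negatives
    from the three E-values, pair hits across two search engines, and
    summarise concordance and error rates, so that false homologies driven
    by non-globular segments are suppressed and obscured true homologies
    recovered.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
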