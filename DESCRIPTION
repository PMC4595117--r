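Package: ctxalign
Title: Context-Aware Protein Multiple Sequence Alignment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Progressive profile-profile multiple sequence alignment of
    proteins that exploits local sequence context: fast GOR-style
    single-sequence secondary-structure prediction fused into the column
    score through a 3x3 structure log-odds matrix, and a model of gap
    opening and extension costs driven by the residues flanking and
    opposing a gap. Includes the estimators that fit both context models
    from labeled corpora and gap databases, benchmark scoring with
    core-block semantics (Q, Modeler, total-column and Cline shift
    scores, secondary-structure identity), and seeded simulators for
    protein families, labeled secondary-structure corpora and
    gap-annotated sequence pairs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    ape,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
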