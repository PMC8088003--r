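Package: nrroot
Title: Maximum-Likelihood Root Placement on Phylogenetic Trees Under a
    Non-Reversible Substitution Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Places a root on an existing unrooted phylogenetic tree by
    maximum likelihood under the non-reversible UNREST nucleotide
    substitution model, optionally with discrete-gamma rate heterogeneity
    and a proportion of invariant sites (UNREST+G+I).  Because likelihood
    under a non-reversible model depends on the root position, every branch
    can be scored as a candidate root; the root position along a branch of
    length t is parameterised as a split into beta*t and (1-beta)*t and
    optimised by bracketing plus Brent's method.  A fast heuristic search
    mode returns the best root, while an exhaustive mode evaluates every
    branch and reports likelihood weight ratios quantifying root-placement
    uncertainty.  Includes alignment (FASTA/PHYLIP) and newick input,
    site-pattern compression, a crash-safe append-only checkpoint log with
    Adler-32 checksums, and a sequence simulator for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Matrix,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
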