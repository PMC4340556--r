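Package: aflattice
Title: Anisotropic Excitable-Lattice Model of Atrial Fibrillation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Synchronous cellular-automaton model of activation wave-front
    propagation on an anisotropic branching-cable substrate mimicking atrial
    muscle. Transverse cell-to-cell couplings are present with probability nu
    and a fraction delta of cells are dysfunctional, failing to excite with
    probability epsilon. The package generates substrates, runs the excitation
    dynamics with pacing, locates the two-cable critical regions that can
    initiate and sustain micro-reentry, evaluates the closed-form risk of
    fibrillation-inducing structures and the threshold coupling nu-star, and
    reproduces the phase diagram in nu and the termination of reentry by a
    targeted ablation lesion. Substrates, traces and snapshots round-trip
    through documented plain-text serialization formats.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
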