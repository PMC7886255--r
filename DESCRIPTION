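Package: aobn
Title: Attractor Observability in Boolean Networks
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for synchronous Boolean network dynamics and for the
    attractor-observability problem: given the singleton and cyclic attractors
    of a gene regulatory Boolean network, find the minimum number of
    consecutive nodes (genes) whose joint binary state discriminates every
    attractor from every other, together with the achieving windows. Includes
    exhaustive attractor enumeration for small networks, a zero-run solver
    over pairwise XOR matrices with phase-combination enumeration for cyclic
    attractors, an independent brute-force oracle, random-instance
    simulations, and the bundled Drosophila melanogaster segment-polarity
    steady-state application.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: jsonlite, stats, tools, utils
Suggests: optparse, testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
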