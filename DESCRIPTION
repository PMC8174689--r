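Package: nucbreathe
Title: Nucleosome Breathing Geometry and Histone Tail-DNA Interaction Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of nucleosome breathing motions in molecular dynamics
    trajectories: a dyad-anchored coordinate frame and linker-DNA opening
    angles (gamma1 out-of-plane, gamma2 in-plane), DNA radius of gyration,
    gyre-resolved histone-DNA contact counts, inverse-power weighted mean and
    minimal distances, per-residue distance profiles for epigenetically
    modifiable tail residues, k-means conformational clustering with
    DNA-to-tail-cluster co-occupancy matrices, and 5-95 percentile summaries.
    Includes an idealized synthetic nucleosome generator with prescribed
    per-arm opening angles and histone tail placement modes, providing ground
    truth for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
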