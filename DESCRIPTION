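Package: carbanm
Title: Elastic Network Analysis of Carbamate-Bridged Channel Gating
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds anisotropic elastic network models (ANM) from the
    C-alpha coordinates of oligomeric membrane-channel structures and
    represents CO2 binding as inter-subunit "carbamate bridge" springs
    (one Hookean spring per subunit interface, e.g. K125 to R104 of the
    neighbouring connexin 26 monomer).  Provides normal-mode solution and
    thermal-amplitude mode fractions, mode-overlap comparison between the
    unbound and bridge-bound states with best-match reordering, a pore
    occlusion metric along a mode, an inter-subunit salt-bridge distance
    screen, sequence-motif detection and mutagenesis construction for
    carbamylation-competent connexins, and deterministic C_n-symmetric
    synthetic oligomer generators so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
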