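Package: gphrtmd
Title: Structural Analysis of Glycoprotein Hormone Receptor Transmembrane Domains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the seven-helix transmembrane domain (TMD) of
    class A G protein-coupled receptors, with emphasis on the glycoprotein
    hormone receptors (TSHR, FSHR, LHR). Provides motif-anchored
    Ballesteros-Weinstein residue numbering, helix-axis fitting with proline
    kink and alpha-bulge detection, distance-based classification of
    inter-residue interactions (salt bridges, hydrogen bonds, weak polar,
    aromatic, hydrophobic and induced-dipole contacts), activation-state
    fingerprinting (ionic lock, tyrosine toggle, hydrophobic core), rigid
    superposition and per-helix movement and rotation decomposition between
    inactive and active conformations, and interaction-based rationalisation
    of activating and inactivating receptor mutations against packaged
    phenotype tables. A deterministic synthetic-bundle generator plants kinks,
    bulges, contact pairs and rigid activation motions so every analysis stage
    is testable without structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
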