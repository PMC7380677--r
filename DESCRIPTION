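Package: xlmapper
Title: Map Chemical Crosslinking Mass-Spectrometry Restraints onto Protein Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps residue-pair restraints from chemical crosslinking mass
    spectrometry (XL-MS) onto protein structures or structural models.
    Parses pipe-delimited crosslink and mono-link (dead-end) lists in the
    Jwalk dialect, reads PDB or mmCIF coordinate files, computes
    Calpha-Calpha Euclidean distances, classifies each crosslink as
    satisfied or violated against a crosslinker spacer-arm distance
    threshold, flags links to residues absent from the structure, and
    exports CSV reports and PyMOL command scripts that draw crosslinks as
    dashed lines between Calpha atoms and mono-links as spheres, colored
    by satisfaction status. Includes a deterministic generator of linear
    Calpha-trace fixtures with closed-form inter-residue distances for
    testing, and a command-line interface over the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
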