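Package: pitha
Title: Structure-Based Immunogenicity Prediction for Therapeutic Antibodies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the clinical immunogenicity of humanized and full-human
    therapeutic antibodies from structural and sequence features of the
    complementarity-determining regions (CDRs): the cavity volume at the CDR
    region, the hydrophobic solvent-accessible surface area of the CDR-H3
    loop, and the presence of glycine at the CDR-H2 beta-turn, combined by a
    radial-basis-function support vector machine (PITHA). Includes a
    Shrake-Rupley solvent-accessible surface area engine with an
    antibody-specific radii set, a grid flood-fill cavity detector and a
    parser for fpocket-style pocket reports, Kabat-based CDR annotation, a
    profile-based humanness score, curated feature tables for 52 FDA-approved
    antibodies with immunogenicity labels, and synthetic-structure generators
    with independent Monte-Carlo oracles for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    kernlab,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
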