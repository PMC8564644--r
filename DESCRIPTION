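Package: tcrdyn
Title: Longitudinal T Cell Receptor Repertoire Diversity and Clonal Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for longitudinal analysis of T cell receptor (TCR) beta-chain
    CDR3 repertoires from bulk immunosequencing. Reads immunoSEQ-style and AIRR
    rearrangement tables, computes depth-normalized Renyi diversity profiles and
    Shannon diversity under read-subsampling (rarefaction), classifies per-patient
    diversity change against baseline, detects and categorizes new clones among
    the most abundant follow-up clonotypes using nucleotide identity, amino-acid
    identity and Levenshtein-distance-1 similarity, builds amino-acid similarity
    networks over abundant clonotypes, and tracks selected clones across a time
    course. Includes a synthetic repertoire simulator with planted ground truth
    for end-to-end validation, and a pipeline driver that produces the full set
    of per-patient output tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    igraph,
    jsonlite,
    yaml,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
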