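Package: nucscreen
Title: Confidence-Weighted Screening of Predicted Nucleosome-Binder Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores predicted binder-nucleosome complex structures by a
    confidence-weighted contact strength factor (SF): binder-histone residue
    pairs in atomic contact at 5 Angstroms are weighted by transformed
    predicted aligned error (PAE) and pLDDT, summed, and normalized against a
    reference complex. Provides candidate ranking with Kneedle knee detection,
    acidic-patch analyses (patch-contact extraction, inter-model consistency
    via mode pairwise RMSD, arginine/lysine anchor motif windows, benchmark
    hit-calling against experimental structures), histone-combination
    classification of binding modes, and a fully synthetic mini-nucleosome
    fixture generator with exactly known planted contacts and confidences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
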