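Package: csranker
Title: Cost-Sensitive Online Kernel Rescoring of Peptide-Spectrum Matches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-database-search rescoring of peptide-spectrum matches (PSMs)
    with a cost-sensitive, ramp-loss kernel ranking model. Incorrect target
    labels are absorbed by a bounded (ramp) loss while decoy mislabels, which
    are known errors, carry a larger hinge penalty. The nonconvex objective is
    trained either by a full-batch concave-convex procedure (CCCP) or by an
    online active-set dual solver that visits one PSM per round and keeps
    memory quadratic in the active-set size rather than the dataset size.
    Includes target-decoy false discovery rate (FDR) selection with q-value
    monotonization, entrapment false-match-rate reporting, cross-validated
    parameter tuning, a synthetic PSM generator with planted ground truth, and
    readers for delimited PSM tables including a Percolator-style PIN dialect.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    kernlab
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
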