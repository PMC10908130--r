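Package: safescreen
Title: Simulation Framework for the SAFE Stopping Heuristic in Active-Learning Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and evaluating the SAFE procedure, a
    four-phase stopping heuristic for active-learning-aided title/abstract
    screening in systematic reviews. Provides bibliographic corpus input
    and validation (CSV and RIS), a synthetic labeled-corpus generator
    with controllable prevalence, lexical separability and a
    divergent-vocabulary "hard" relevant subpopulation, pluggable
    TF-IDF-based and embedding-based ranking models, composable stopping
    criteria (key papers, screening floors, consecutive-irrelevant
    windows, recall plateaus), an oracle screener with optional
    false-negative error, and evaluation metrics (recall curves, work
    saved over sampling, PRISMA-style flow counts).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
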