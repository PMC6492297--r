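Package: npcperm
Title: Two-Level Permutation Inference by Non-Parametric Combination of
    Replicated Tests
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tests association between observed subject-level variables and
    an unobserved quantity that is measured only through many noisy
    replications (for example, repeated functional-connectivity estimates
    from re-runs of a stochastic inference algorithm). First-level
    parametric correlation tests per replication are combined with the
    geometric or arithmetic mean of p-values, and a second-level
    permutation step (non-parametric combination, NPC) turns the combined
    summary into a valid p-value, with min-p family-wise error correction
    and Benjamini-Hochberg FDR across variables. Includes a ridge
    regression F-test permutation baseline, synthetic-data generators for
    toy and functional-connectivity simulation studies, and reproducible
    experiment runners for power and type-I-error grids.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, optparse
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
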