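Package: turnoverAging
Title: Pulse-SILAC Protein Lifetime Estimation and Aged-Versus-Young
    Proteome Turnover Comparison
Version: 0.1.0
Authors@R:
    person("Turnover", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for in vivo pulse-SILAC protein turnover analysis of
    brain tissue. Implements the double-exponential lysine precursor-pool
    forward model with intrinsic correction for amino-acid reuse,
    per-protein half-life fitting from heavy/light ratio time courses
    with profile-likelihood 95% confidence intervals and quality-control
    filters, median-rescaled aged-versus-young lifetime comparison
    (log2 fold changes, direction-consistency filtering, extremes,
    percentile groups, lifetime-compression and raw-ratio
    bidirectionality diagnostics, abundance quadrants, cell-type
    specificity), sequence-derived biochemical features (composition,
    isoelectric point, GRAVY, average biosynthetic cost), a statistical
    battery (paired signed-rank, Welch ANOVA with Games-Howell or
    permutation Dunnett post hoc, Anderson-Darling log-normality), and a
    synthetic labeling-cohort generator that emulates the data structure
    of a MaxQuant proteinGroups workflow so the whole pipeline is
    testable without raw mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
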