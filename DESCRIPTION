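Package: triogreml
Title: Family-Based GREML for Direct Genetic Effects and Genetic Nurture
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and estimation toolkit for family-based genomic REML
    (GREML) analyses of parent-offspring data. Simulates genotyped
    mother-father-child trios with Mendelian transmission, polygenic direct
    effects, parental genetic-nurture effects with a tunable direct/nurture
    effect correlation, and Likert questionnaire responses; scores
    questionnaire scales with missingness caps and mean imputation; applies
    post-imputation SNP quality control including an exact Hardy-Weinberg
    test; builds within- and cross-generation genomic relatedness matrices
    (GCTA estimator) with greedy relatedness pruning; and fits offspring-only
    and extended parent-offspring variance-component models by
    average-information REML with likelihood-ratio tests and a combined
    genetic-variance summary.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
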