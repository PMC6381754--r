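Package: methresp
Title: Promoter-Methylation Signatures of Chemotherapy Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovery and validation of CpG-methylation biomarkers of
    pathological complete response (residual cancer burden 0) to neoadjuvant
    chemotherapy in triple-negative breast cancer. Implements a five-filter
    differential-methylation cascade over 450K-style beta values (rank-sum p,
    effect size, promoter island/shore annotation, intragroup dispersion,
    consecutive-CpG consistency), pyrosequencing-style replication in an
    independent cohort, AIC selection of a linear two-gene methylation score
    with a bootstrap ROC/Youden decision rule, delta-delta-Ct expression
    analysis with methylation-expression correlation, and a seeded synthetic
    cohort generator with planted ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
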