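Package: cdace
Title: Crohn's Disease Activity in Capsule Endoscopy (CDACE) Scoring and Validation Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Computes the CDACE composite score for small-bowel capsule
    endoscopy (SBCE) readings in Crohn's disease, from per-lesion annotations
    through the quartile inflammation profile to the positional composite
    (Li x 100 + R x 10 + S) and its decoded components. Also implements the
    two established comparator scores (Lewis Score, CECDAI), the statistical
    machinery used to validate composite endoscopic indices (Spearman rank
    correlation, ROC-based cutoff selection with sensitivity, specificity,
    PPV and NPV, intraclass correlation ICC(2,1) with confidence interval,
    Shapiro-Wilk normality), and a synthetic SBCE cohort simulator with
    known ground truth for end-to-end testing of the analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
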