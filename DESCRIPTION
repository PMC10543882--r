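Package: pdcalbal
Title: Calcium Mass Balance, Adequacy and Bone Density Analysis for
    Peritoneal Dialysis Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes 24-hour peritoneal calcium mass balance for peritoneal
    dialysis patients from dialysate prescriptions and pooled effluent
    collections, with explicit handling of the flush-before-fill bag overfill
    used in manual (CAPD) exchanges. Extends the net peritoneal balance with
    urinary calcium losses and with elemental calcium absorbed from
    calcium-containing phosphate binders. Also provides standard dialysis
    adequacy measures (weekly Kt/V urea by route, protein nitrogen appearance,
    peritoneal equilibration test transporter categories), WHO bone-density
    classification from DXA T and Z scores, a synthetic cohort generator with
    a mechanistic dialysate-equilibration model, and a cohort statistical
    screen (grouped summaries, Spearman screen, backward stepwise logistic
    regression with odds ratios and Nagelkerke pseudo-R2).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
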