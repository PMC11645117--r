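Package: hcesfort
Title: Apparent Micronutrient Intakes and Fortification Scenarios from
    Household Consumption Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts household consumption and expenditure survey (HCES) food
    records into apparent micronutrient intakes per adult female equivalent
    (AFE), estimates the survey-weighted prevalence at risk of inadequate and
    excess apparent intakes, and models the contribution of large-scale food
    fortification of cooking oil, wheat flour and maize flour under four
    compliance scenarios. Ships a synthetic survey generator emulating a
    Tanzania National Panel Survey style 7-day, 60-item food module with known
    ground truth, so the whole pipeline is testable without restricted
    microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
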