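Package: lqrscreen
Title: Cognitive Impairment Screening from Low-Quality Questionnaire Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Passive screening for cognitive impairment from the response
    quality of brief well-being questionnaires. Fits Samejima's graded
    response model by marginal maximum likelihood, scores respondents'
    latent traits by expected a posteriori estimation, and derives two
    person-by-item low-quality-response indices (squared residuals from the
    model-expected response and the model probability of the observed
    response). These indices, optionally combined with age and gender, feed
    class-weighted risk models (a multilayer perceptron and classical
    baselines) whose referral threshold is chosen to minimise an
    underdiagnosis-to-overdiagnosis cost ratio. Includes a synthetic cohort
    generator with injected careless responding, skipping and
    straight-lining, screening-efficiency curves, and rule-based comparator
    strategies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    pracma,
    glmnet,
    rpart,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
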