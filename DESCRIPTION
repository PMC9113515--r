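Package: inkassess
Title: Digital Pen Features and Automatic Scoring of Neurocognitive Assessments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing digital ink recordings of paper-pencil
    neurocognitive assessments. Provides a canonical ink data model with
    InkML and JSON-lines readers and writers, a bank of 176 digital pen
    features in five provenance-tagged families (Rubine, Willems & Niels,
    HBF49, mode-detection, and cognitive-assessment features), automatic
    scorers for the Clock Drawing Test (20-point CDIS scheme), the Trail
    Making Test (path analysis against a 25-node template) and the
    Rey-Osterrieth Complex Figure (18 sub-figures, 36 points), binary
    healthy/suspicious labelling rules, a synthetic ink generator that
    emulates healthy and cognitively impaired elderly writing, and a
    cross-validated classification benchmark over ten machine learning
    methods with t-SNE visualisation of the feature space.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    class,
    e1071,
    glmnet,
    graphics,
    grDevices,
    jsonlite,
    pROC,
    randomForest,
    rpart,
    stats,
    utils,
    xgboost,
    xml2
Suggests:
    cluster,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
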