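Package: cpemm
Title: Ensemble Merit Merge Feature Selection with Binary Particle Swarm Search
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Wrapper feature selection for multiclass clinical tabular data.
    Candidate feature subsets are searched with binary Particle Swarm
    Optimisation, scored by the cross-validated accuracy of bagged base
    classifiers (a C4.5-style decision tree, naive Bayes, random forest, or
    an RBF-kernel support vector machine), and the merit-ranked subsets are
    consolidated with the three-case Merit Merge procedure into a final
    feature set and fitted ensemble. Includes dataset readers for CSV and
    ARFF with class-wise imputation and normalisation, stratified
    cross-validation and train/test evaluation with one-vs-rest ROC/AUC and
    Press' Q significance testing, and a synthetic-data generator with
    planted informative, redundant and noise features for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    e1071,
    randomForest,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rpart,
    jsonlite
Config/testthat/edition: 3
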