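Package: roughkm
Title: Rough K-Means Ambiguity Filtering for Disease Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Rough K-means (RKM) soft clustering with lower and upper
    approximations separated by a distance-ratio threshold, used to detect
    and exclude ambiguous records from tabular disease datasets before
    classification. Includes loaders and preprocessing for common chronic
    disease CSV schemas, four reference classifiers (Gaussian naive Bayes,
    RBF-kernel support vector machine, K-nearest neighbours, random
    forest), confusion-matrix metrics (accuracy, sensitivity, specificity,
    precision, F1), a paired baseline-versus-filtered experiment pipeline,
    and a synthetic generator that plants class-overlap ambiguity with
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    randomForest,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
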