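Package: tricgen
Title: Synthetic Three-Way Datasets with Planted Triclustering Solutions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Generates synthetic three-way datasets (observations x features
    x contexts) with planted, ground-truth triclusters for benchmarking
    triclustering algorithms. Supports numeric (real or integer) and symbolic
    alphabets, configurable background distributions, constant, additive,
    multiplicative and order-preserving coherence patterns on each dimension,
    plaid composition of overlapping triclusters, and controlled injection of
    missing values, noise and errors. Datasets are written as tab-separated
    slice files together with a machine-readable triclustering solution
    (ground truth) in JSON and plain text.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: jsonlite, stats, utils, yaml
Suggests: optparse, testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
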