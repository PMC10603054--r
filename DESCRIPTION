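Package: bindnet
Title: Dynamic Protein-RNA Binding Prediction from Sequence and In Vivo Structure
Version: 0.1.0
Authors@R:
    person("bindnet", "developers", email = "bindnet@example.org", role = c("aut", "cre"))
Description: Predicts RNA-binding-protein (RBP) binding events from RNA
    sequence and in vivo icSHAPE secondary-structure reactivity. Implements
    the full pipeline: icSHAPE reactivity scoring from raw RT-stop and
    base-density replicate counts; construction of fixed-length labelled
    datasets from confidence-ranked binding peaks; k-mer tokenization with a
    trainable multi-head self-attention encoder; a hierarchical multi-scale
    residual convolutional network with a pyramid binding predictor; training
    with warm-up and early stopping; and attention-based interpretation
    (motif calling, saliency spreading, gradient attribution, variant-effect
    scoring). All neural-network layers are implemented natively on BLAS
    matrix operations with manual backpropagation, and every component is
    exercisable on bundled synthetic-data generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    withr,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
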