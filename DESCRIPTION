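Package: epiattn
Title: Enhancer-Promoter Interaction Prediction with a k-mer Transformer
    and Attention-Based Motif Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts enhancer-promoter interactions (EPIs) from DNA
    sequence alone using a k-mer tokenized Transformer encoder with a
    TextCNN classification head, trained end to end in native R matrix
    code. Includes masked-language-model pre-training on genome-derived
    corpora, class-balanced fine-tuning with window-shift augmentation,
    domain-adversarial (DANN) transfer between cell lines via a gradient
    reversal layer, attention-based de novo motif discovery with
    hypergeometric enrichment and MEME export, high-attention k-mer pair
    mining, and a fully seeded synthetic-data generator with planted motif
    grammars so every stage is trainable and testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    pROC,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
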