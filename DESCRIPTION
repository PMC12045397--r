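Package: maskprobe
Title: Probing In-Context Retrieval in Masked Biological Sequence Language Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect and characterize in-context retrieval in masked
    sequence language models for proteins and RNA. Provides seeded generators for
    the sequence constructions used in retrieval probing (tandem repeats, mutated
    copies, needle-in-a-haystack layouts, one-skip pairs, reverse-complement
    contexts, contra-lateral insertions), pseudo-perplexity and entropy scoring
    (one-at-a-time and single-pass variants, plus a left-to-right perplexity),
    a uniform prediction/embedding contract with a configurable deterministic
    mock retrieval model, eight probe pipelines that emit tidy result tables,
    and an embedding-information regression that trains small ensembles to read
    predictive profiles back out of residue-level embeddings.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
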