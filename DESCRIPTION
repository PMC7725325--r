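Package: plastrans
Title: Transmissibility Annotation of Plasmid DNA Fragments from Sequence Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates plasmid DNA fragments and contigs as transmissible
    (conjugative or mobilizable) versus non-transmissible from sequence
    signatures alone, without marker-gene search. Implements the information
    entropy of amino acid (IEA) statistic that quantifies the randomness of
    synonymous codon usage per genome, a two-branch convolutional neural
    network classifier operating on six-frame triplet-code and dual-strand
    base one-hot encodings, a synthetic benchmark generator emulating
    host codon-usage amelioration, and the fragment-level evaluation
    protocol (recall, precision, F1, AUC, uncertainty thresholding).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
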