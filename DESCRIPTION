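Package: bestop
Title: Design and Quantification of Cytidine Base-Editing Stop-Codon Knockouts
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for working with BE3-style cytidine base editors as gene
    knockout reagents. Scans coding sequences for NGG-PAM protospacers in
    which a C-to-T (or G-to-A on the opposite strand) edit inside the
    deamination window converts an in-frame CAA, CAG, CGA or TGG codon into
    a premature stop codon, and summarizes targetability per gene.
    Quantifies editing outcomes from targeted amplicon deep sequencing:
    sliding-window quality trimming, paired-barcode demultiplexing,
    alignment-based read classification by C-to-T conversion inside the
    20-bp target site, per-guide efficiency, per-position substitution
    matrices, editing-window probability profiles, multiplex substitution
    histograms, and indel frequency calling. Ships a seeded simulator that
    generates coding sequences with planted knockout sites and barcoded
    amplicon reads with specified per-position editing probabilities,
    indel rates and sequencing error, so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    BiocGenerics,
    Biostrings,
    graphics,
    grDevices,
    jsonlite,
    pheatmap,
    stats,
    tools,
    utils
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
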