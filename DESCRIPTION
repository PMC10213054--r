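Package: oligostore
Title: DNA Data Storage with Convolutional Codes and CTC-Aware List-Viterbi Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encode arbitrary byte streams into pools of short synthetic
    oligonucleotides and decode them back from (simulated) nanopore reads.
    The inner code is a punctured convolutional code with an 8-bit CRC per
    oligo; the outer code is a Reed-Solomon erasure code across oligos that
    tolerates whole-oligo dropout. Decoding operates directly on the
    basecaller's connectionist temporal classification (CTC) posterior
    matrices via a list-Viterbi dynamic program over joint (code state,
    sequence position) trellis states, retaining the top-L candidate
    messages per state and filtering candidates with the CRC. A calibrated
    synthetic nanopore channel (dwell, blank, substitution, indel, coverage
    skew, dropout and chimera models) makes the full encode-sequence-decode
    loop testable without real flowcell data. Also implements combinatorial
    barcode addresses (CBA): k-mer-disjoint 20-mer barcode design, 6-subunit
    octal addresses, k-mer decoding with a strict inclusion criterion, and a
    gain/leak model of hierarchical amplification-based retrieval.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
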