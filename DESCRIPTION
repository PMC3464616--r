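Package: solidecc
Title: Linear-Code Analysis and Decoding for SOLiD Two-Base and Exact Call
    Chemistry Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the convolutional code over GF(4) that
    underlies the SOLiD sequencing platform's two-base ('color space')
    encoding and its Exact Call Chemistry (ECC) extension. Implements
    finite-field arithmetic on bases and colors, construction of block and
    full code generators and parity-check matrices for arbitrary 5-coefficient
    probe generators, syndrome computation with equivalence-class and
    miscorrection-pattern analysis, enumeration of alternative probe
    chemistries, classical q-ary coding bounds (Hamming, Singleton, Johnson,
    Gilbert-Varshamov) in exact integer arithmetic, hard-decision syndrome
    decoding and soft-information trellis decoding (Viterbi maximum-likelihood
    and forward-backward maximum a posteriori), plus a color-space read
    simulator with Phred-quality error models and a truth-based evaluation
    harness. Readers and writers are included for FASTA, CSFASTA/QUAL and
    FASTQ.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
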