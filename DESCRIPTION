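Package: acoq
Title: Lossless FASTQ Quality Score Compression by Adaptive Coding Order
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Lossless compressor for FASTQ quality scores. Reads are buffered
    as a two-dimensional quality matrix that is traversed in serpentine
    (snake) column order, and every Phred symbol is coded with an adaptive
    binary-carry range coder driven by a compound context: the previous
    quality symbols along the scan path, the quantized per-read mean quality,
    and a second-order base context. Includes the dynamic-programming context
    quantizer that derives row-mean bin boundaries by minimizing a weighted
    distortion objective, a synthetic FASTQ generator reproducing the
    statistical structure the contexts exploit, and compression-rate /
    bits-per-quality evaluation helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
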