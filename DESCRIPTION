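Package: ftsar
Title: Spectral Sequence-Activity Modelling of Combinatorial Protein Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models protein variant activity from sequence alone by encoding
    amino-acid sequences with physicochemical AAindex scales, converting the
    encoded signal into a Fourier magnitude spectrum, and fitting partial
    least squares regression (PLSR) models selected by leave-one-out
    cross-validation. Supports scanning a whole AAindex database for the
    best-performing scale, enumerating the full 2^n combinatorial library of
    a set of point mutations, and ranking all variants by predicted activity.
    Includes a synthetic sequence-activity landscape generator with known
    ground truth and a bundled transaminase thermostability dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    seqinr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
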