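# AAindex1 column order of the two value rows
AACOL <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# toy index: values 1..20 assigned in AAindex1 column order (A=1, R=2, ..., V=20)
toy_index <- function(accession = "TOY0000001") {
  aa_index(accession, stats::setNames(1:20, AACOL),
           "toy scale, 1..20 in column order")
}

# internal constructor, handy for feeding raw signals to pad/fft
signal <- function(values) ftsar:::encoded_signal(values, length(values))

# brute-force O(N^2) DFT magnitude oracle for frequencies k = 0..N/2
dft_oracle <- function(x) {
  N <- length(x)
  n <- 0:(N - 1)
  vapply(0:(N %/% 2), function(k) {
    Mod(sum(x * exp(-2i * pi * k * n / N)))
  }, numeric(1))
}

# random protein sequence over the standard alphabet
random_seq <- function(n) {
  paste(sample(ftsar:::STANDARD_RESIDUES, n, replace = TRUE), collapse = "")
}

# a synthetic stand-in for the transaminase wild type: random 325-residue
# sequence that carries the wild-type residues of the six panel mutations at
# the right positions (the real sequence was never published)
synthetic_transaminase_wt <- function(seed = 42) {
  set.seed(seed)
  res <- sample(ftsar:::STANDARD_RESIDUES, 325, replace = TRUE)
  res[c(77, 97, 210, 245, 292, 295)] <- c("I", "Q", "H", "N", "G", "I")
  paste(res, collapse = "")
}

# AAindex1 text for a single entry with given accession and 20 values in
# column order (values may be character, e.g. "NA")
aaindex_entry_text <- function(accession, values) {
  c(
    paste("H", accession),
    "D test entry",
    "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
    paste0("   ", paste(values[1:10], collapse = "   ")),
    paste0("   ", paste(values[11:20], collapse = "   ")),
    "//"
  )
}
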