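#' Spectrum configuration
#'
#' Bundles the two conventions of the spectral encoding that the literature
#' leaves open: whether the feature vector holds magnitudes `|S_k|` or power
#' `|S_k|^2`, and how the encoded signal is standardized against the 20 values
#' of the amino-acid index.
#'
#' @param spectrum `"magnitude"` (default) or `"power"`.
#' @param standardize `"zscore"` (default: subtract the mean of the 20 index
#'   values and divide by their population standard deviation), `"center"`
#'   (subtract the mean only) or `"none"`.
#' @return A list of class `spectrum_config`.
#' @export
spectrum_config <- function(spectrum = c("magnitude", "power"),
                            standardize = c("zscore", "center", "none")) {
  structure(
    list(
      spectrum = match.arg(spectrum),
      standardize = match.arg(standardize)
    ),
    class = "spectrum_config"
  )
}

#' Encode a protein sequence as a numeric signal
#'
#' Replaces each residue with the value the index assigns to it, optionally
#' standardized against the 20 index values (so that indices on very
#' different scales produce comparable signals).
#'
#' @param seq Protein sequence: a single string, or a character vector of
#'   one-letter codes. Only the 20 standard residues are accepted.
#' @param index An [aa_index].
#' @param standardize `"zscore"`, `"center"` or `"none"`; see
#'   [spectrum_config()]. Standardization statistics are computed from the 20
#'   index values (population variance, denominator 20), not from the
#'   sequence, so all sequences share one affine map.
#'
#' @return An `encoded_signal`: list with `values` (numeric, one per residue)
#'   and `source_length`.
#' @export
encode_sequence <- function(seq, index,
                            standardize = c("zscore", "center", "none")) {
  standardize <- match.arg(standardize)
  stopifnot(inherits(index, "aa_index"))
  residues <- as_residue_vector(seq)
  bad <- which(!(residues %in% STANDARD_RESIDUES))
  if (length(bad) > 0L) {
    stop("non-standard residue '", residues[bad[1L]], "' at position ",
         bad[1L], call. = FALSE)
  }
  values <- unname(index$values[residues])
  if (standardize != "none") {
    m <- mean(index$values)
    values <- values - m
    if (standardize == "zscore") {
      s <- sqrt(mean((index$values - m)^2)) # population SD over the 20 values
      if (s == 0) {
        stop("index '", index$accession,
             "' has zero variance; cannot z-score", call. = FALSE)
      }
      values <- values / s
    }
  }
  encoded_signal(values, length(residues))
}

encoded_signal <- function(values, source_length) {
  structure(
    list(values = as.numeric(values), source_length = as.integer(source_length)),
    class = "encoded_signal"
  )
}

# Accept "ACDE" or c("A","C","D","E"); always return uppercase vector.
as_residue_vector <- function(seq) {
  if (inherits(seq, "encoded_signal")) {
    stop("'seq' is already encoded", call. = FALSE)
  }
  seq <- as.character(seq)
  if (length(seq) == 1L) seq <- strsplit(seq, "", fixed = TRUE)[[1L]]
  if (length(seq) == 0L) stop("empty sequence", call. = FALSE)
  toupper(seq)
}

next_power_of_two <- function(n) {
  stopifnot(n >= 1)
  p <- 1L
  while (p < n) p <- p * 2L
  as.integer(p)
}

is_power_of_two <- function(n) {
  n >= 1 && bitwAnd(as.integer(n), as.integer(n) - 1L) == 0L
}

#' Zero-pad an encoded signal to the next power of two
#'
#' Appends zeros so that the signal length is the smallest power of two at
#' least the residue count (e.g. 325 residues pad to 512 = 2^9). Padding
#' equalizes feature-vector length across sequences and enables the radix-2
#' FFT. A signal already at a power-of-two length is returned unchanged.
#'
#' @param signal An `encoded_signal` from [encode_sequence()].
#' @return An `encoded_signal` whose `values` have power-of-two length;
#'   `source_length` still records the original residue count.
#' @export
pad_signal <- function(signal) {
  stopifnot(inherits(signal, "encoded_signal"))
  n <- length(signal$values)
  if (n == 0L) stop("cannot pad an empty signal", call. = FALSE)
  target <- next_power_of_two(n)
  if (target > n) {
    signal$values <- c(signal$values, rep(0, target - n))
  }
  signal
}

#' Fourier magnitude spectrum of a padded signal
#'
#' Computes `S_k = sum_n s_n exp(-2i pi k n / N)` for `k = 0..N/2` and returns
#' `|S_k|` (or `|S_k|^2` in power mode). Because the input signal is real the
#' upper half of the spectrum mirrors the lower half, so only frequencies
#' `0..N/2` are kept; the DC bin (`k = 0`) is retained.
#'
#' @param padded An `encoded_signal` of power-of-two length (see
#'   [pad_signal()]).
#' @param mode `"magnitude"` or `"power"`.
#' @return A `protein_spectrum`: list with `magnitudes` (length `N/2 + 1`),
#'   `padded_length` and `source_length`.
#' @export
fft_spectrum <- function(padded, mode = c("magnitude", "power")) {
  mode <- match.arg(mode)
  stopifnot(inherits(padded, "encoded_signal"))
  n <- length(padded$values)
  if (!is_power_of_two(n)) {
    stop("signal length ", n,
         " is not a power of two; call pad_signal() first", call. = FALSE)
  }
  s <- stats::fft(padded$values)
  mags <- Mod(s)[seq_len(n %/% 2L + 1L)]
  if (mode == "power") mags <- mags^2
  structure(
    list(
      magnitudes = mags,
      padded_length = as.integer(n),
      source_length = padded$source_length
    ),
    class = "protein_spectrum"
  )
}

#' @export
print.protein_spectrum <- function(x, ...) {
  cat("<protein_spectrum> ", length(x$magnitudes), " bins (padded length ",
      x$padded_length, ", ", x$source_length, " residues)\n", sep = "")
  invisible(x)
}

#' Sequence to spectral feature vector
#'
#' One-call composition of [encode_sequence()], [pad_signal()] and
#' [fft_spectrum()]: the protein-spectrum featurization used throughout the
#' modelling pipeline. A 325-residue sequence yields 512/2 + 1 = 257 features.
#'
#' @inheritParams encode_sequence
#' @param config A [spectrum_config()].
#' @return A `protein_spectrum`.
#' @export
make_feature_vector <- function(seq, index, config = spectrum_config()) {
  stopifnot(inherits(config, "spectrum_config"))
  fft_spectrum(
    pad_signal(encode_sequence(seq, index, standardize = config$standardize)),
    mode = config$spectrum
  )
}

# Feature matrix (one spectrum row per sequence), used by the scan and
# prediction code paths. All sequences must share one length.
spectra_matrix <- function(seqs, index, config) {
  rows <- lapply(seqs, function(s) make_feature_vector(s, index, config)$magnitudes)
  p <- unique(vapply(rows, length, integer(1)))
  if (length(p) != 1L) {
    stop("sequences produce spectra of differing lengths", call. = FALSE)
  }
  do.call(rbind, rows)
}
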