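#' Random synthetic amino-acid indices
#'
#' Draws index value maps with independent standard-normal values per
#' residue. Useful as decoy encoding scales when benchmarking index
#' recovery: a decoy has the same shape as a real physicochemical scale but
#' no relation to the landscape's generating scale.
#'
#' @param n Number of indices.
#' @param accessions Optional character vector of accessions (default
#'   `SYNT000001`, `SYNT000002`, ...).
#' @param seed Optional seed; when `NULL` the current RNG state is used.
#' @return A named list of [aa_index] objects.
#' @export
random_aaindex <- function(n = 1L, accessions = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(accessions)) accessions <- sprintf("SYNT%06d", seq_len(n))
  stopifnot(length(accessions) == n)
  out <- lapply(seq_len(n), function(i) {
    aa_index(
      accessions[i],
      stats::setNames(stats::rnorm(20L), STANDARD_RESIDUES),
      "synthetic random physicochemical scale"
    )
  })
  names(out) <- accessions
  out
}

#' Generate a synthetic sequence-activity landscape with known ground truth
#'
#' Builds a benchmark dataset with the same shape as a small combinatorial
#' mutagenesis study: a random wild-type sequence, `n_mutations` random point
#' substitutions, and a true activity that is exactly linear in the spectrum
#' features of the generating index,
#' `activity(v) = intercept + beta . spectrum(v)`, plus optional Gaussian
#' measurement noise.
#'
#' The true coefficient vector is constructed to be *identifiable from the
#' labeled design*: a sparse random seed over `n_active_features` spectrum
#' bins is projected onto the span of the leading `n_latent_dims` principal
#' directions of the labeled records' centered spectra. A coefficient vector
#' with mass outside that span could never be recovered from the design (13
#' samples cannot pin down 257 free coefficients), so restricting the truth
#' to the variation the design actually probes makes the landscape a
#' correctness benchmark: with `sigma = 0` the pipeline is expected to
#' recover the generating index and reproduce the true ranking of all `2^n`
#' variants exactly, and any failure to do so indicates a defect rather than
#' statistical bad luck. What such a benchmark deliberately does not test is
#' statistical efficiency on landscapes whose structure is *not* fully
#' identifiable -- i.e. real ones.
#'
#' The default design copies the real use case this package targets: a
#' 325-residue protein, 6 candidate mutations (a 64-variant library) and 13
#' labeled records -- the wild type, every single mutant, and 6 random
#' multi-mutation combinations. Activities are shifted so the smallest true
#' activity equals `activity_floor` (half-lives are positive), giving a
#' spread governed by `effect_scale` (default: true activities with a
#' standard deviation of 12 minutes, matching the dispersion typical of a
#' small thermostability panel). The default noise `sigma = 0.7` minutes
#' reflects the replicate uncertainties such panels report.
#'
#' @param length Wild-type length in residues.
#' @param n_mutations Number of candidate point mutations.
#' @param index Generating [aa_index]; a random one is drawn when `NULL`.
#' @param n_active_features Number of spectrum bins carrying the sparse
#'   random seed of the true coefficient vector (before projection).
#' @param n_latent_dims Dimension of the latent activity structure: the true
#'   coefficient vector lives in the span of this many leading principal
#'   directions of the labeled design's spectra (default 3, small enough
#'   that every leave-one-out fold still sees the whole structure).
#' @param effect_scale Standard deviation, in minutes, of the true activities
#'   across the full library.
#' @param sigma Measurement noise SD in minutes (0 for a noiseless panel).
#' @param n_records Number of labeled records (must be at least
#'   `1 + n_mutations`; the remainder are random combinations).
#' @param seed Integer seed; the landscape is a deterministic function of its
#'   arguments and the seed.
#' @param config [spectrum_config()] used for the generating features.
#' @param activity_floor Smallest true activity in minutes.
#' @return An object of class `synthetic_landscape`: list with `wt`,
#'   `mutations` (a `mutation_set`), `index`, `coefficients` (the projected
#'   true coefficient vector, full spectrum length), `active_bins` (bins of
#'   the sparse seed), `n_latent_dims` (effective latent dimension),
#'   `intercept`, `sigma`, `seed`, `config`, `truth` (data frame: `variant`,
#'   `n_mutations`, `activity` for all `2^n` variants) and `records` (an
#'   `activity_table` of the noisy labeled subsample).
#' @export
generate_landscape <- function(length = 325L, n_mutations = 6L, index = NULL,
                               n_active_features = 5L, n_latent_dims = 3L,
                               effect_scale = 12,
                               sigma = 0.7, n_records = 13L, seed,
                               config = spectrum_config(),
                               activity_floor = 5) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  stopifnot(length >= n_mutations, n_mutations >= 1L, sigma >= 0,
            n_records >= 1L + n_mutations, n_records <= 2^n_mutations,
            inherits(config, "spectrum_config"))
  set.seed(as.integer(seed))

  wt_res <- sample(STANDARD_RESIDUES, length, replace = TRUE)
  wt <- paste(wt_res, collapse = "")
  pos <- sort(sample.int(length, n_mutations))
  mut_res <- vapply(pos, function(p) {
    sample(setdiff(STANDARD_RESIDUES, wt_res[p]), 1L)
  }, character(1))
  mutations <- mutation_set(wt_res[pos], pos, mut_res)

  if (is.null(index)) index <- random_aaindex(1L, "SYNTH00001")[[1L]]
  stopifnot(inherits(index, "aa_index"))

  library <- enumerate_library(mutations)
  seqs <- lapply(library, function(ms) apply_variant(wt, ms))
  X <- spectra_matrix(seqs, index, config)
  p <- ncol(X)
  n_mut_per_variant <- vapply(library, nrow, integer(1))

  # labeled design: WT + every single + random multi-mutation combinations
  wt_row <- which(n_mut_per_variant == 0L)
  singles <- which(n_mut_per_variant == 1L)
  multis <- which(n_mut_per_variant >= 2L)
  n_extra <- n_records - 1L - n_mutations
  extra <- if (n_extra > 0L) sample(multis, n_extra) else integer(0)
  design <- c(wt_row, singles, sort(extra))

  # true coefficients: sparse random seed projected onto the leading
  # principal directions of the design's centered spectra, so the truth is
  # identifiable from the labeled records (see Details)
  if (n_active_features < 1L || n_active_features > p) {
    stop("n_active_features must be in 1..", p, call. = FALSE)
  }
  active_bins <- sort(sample.int(p, n_active_features))
  beta_seed <- numeric(p)
  beta_seed[active_bins] <- stats::rnorm(n_active_features)
  Xd <- X[design, , drop = FALSE]
  Xd <- sweep(Xd, 2L, colMeans(Xd), "-")
  sv <- svd(Xd)
  rank_d <- sum(sv$d > 1e-8 * sv$d[1L])
  k <- min(as.integer(n_latent_dims), rank_d)
  if (k < 1L) stop("degenerate design: spectra have no variation", call. = FALSE)
  V <- sv$v[, seq_len(k), drop = FALSE]
  coefficients <- drop(V %*% crossprod(V, beta_seed))

  scores <- drop(X %*% coefficients)
  s <- stats::sd(scores)
  if (s == 0) stop("degenerate landscape: constant scores", call. = FALSE)
  coefficients <- coefficients * effect_scale / s
  scores <- scores * effect_scale / s
  intercept <- activity_floor - min(scores)
  truth_activity <- intercept + scores

  truth <- data.frame(
    variant = names(library),
    n_mutations = n_mut_per_variant,
    activity = truth_activity,
    stringsAsFactors = FALSE
  )
  rownames(truth) <- NULL

  noise <- if (sigma > 0) stats::rnorm(length(design), 0, sigma) else
    numeric(length(design))

  ids <- c("WT",
           sprintf("M%d", seq_along(singles)),
           if (n_extra > 0L) sprintf("C%d", seq_len(n_extra)))
  records <- data.frame(
    variant_id = ids,
    mutations = truth$variant[design],
    activity = truth$activity[design] + noise,
    labeled = TRUE,
    stringsAsFactors = FALSE
  )
  sets <- library[design]
  names(sets) <- ids
  attr(records, "mutation_sets") <- sets
  class(records) <- c("activity_table", "data.frame")

  structure(
    list(
      wt = wt,
      mutations = mutations,
      index = index,
      coefficients = coefficients,
      active_bins = active_bins,
      n_latent_dims = k,
      intercept = intercept,
      effect_scale = effect_scale,
      sigma = sigma,
      seed = as.integer(seed),
      config = config,
      truth = truth,
      records = records
    ),
    class = "synthetic_landscape"
  )
}

#' @export
print.synthetic_landscape <- function(x, ...) {
  cat("<synthetic_landscape> ", nchar(x$wt), " residues, ",
      nrow(x$mutations), " mutations (", nrow(x$truth), " variants), ",
      nrow(x$records), " labeled records, sigma = ", x$sigma,
      ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Recompute a variant's true activity from the landscape definition
#'
#' The ground truth is a deterministic function of the wild type, the
#' generating index and the coefficient vector; this recomputes it from
#' those components alone (no lookup in the stored truth table).
#'
#' @param landscape A `synthetic_landscape`.
#' @param mutations A `mutation_set` (or signature string).
#' @return The true activity in minutes.
#' @export
true_activity <- function(landscape, mutations) {
  stopifnot(inherits(landscape, "synthetic_landscape"))
  if (is.character(mutations)) mutations <- parse_variant_spec(mutations)
  seq <- apply_variant(landscape$wt, mutations)
  spec <- make_feature_vector(seq, landscape$index, landscape$config)
  landscape$intercept + sum(spec$magnitudes * landscape$coefficients)
}

#' Write a synthetic landscape as a ready-to-run dataset directory
#'
#' Emits the same FASTA + CSV formats the modelling pipeline reads: the
#' wild-type sequence, the labeled variant table, the generating index in
#' AAindex1 format and the full truth table.
#'
#' @param landscape A `synthetic_landscape`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_landscape <- function(landscape, dir) {
  stopifnot(inherits(landscape, "synthetic_landscape"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    wt = file.path(dir, "wt.fasta"),
    records = file.path(dir, "train.csv"),
    index = file.path(dir, "index.aaindex1"),
    truth = file.path(dir, "truth.csv")
  )
  seqinr::write.fasta(list(strsplit(landscape$wt, "")[[1L]]), "WT",
                      file.out = paths[["wt"]])
  write_variant_table(landscape$records, paths[["records"]])
  write_aaindex_db(landscape$index, paths[["index"]])
  utils::write.csv(landscape$truth, paths[["truth"]], row.names = FALSE)
  invisible(paths)
}

#' Bundled transaminase thermostability dataset
#'
#' The measured panel of an (R)-selective omega-transaminase (325 residues,
#' from *Aspergillus terreus*) thermostability study: six candidate point
#' mutations (I77L, Q97E, H210N, N245D, G292D, I295V) and 13 labeled records
#' -- the wild type plus 12 mutants -- with half-life (`T_1/2`, minutes at
#' 40 degrees C) means and replicate SDs. The table is transcribed from the
#' published panel as-is; see the fixture README in
#' `system.file("extdata", package = "ftsar")` for a note on the variant
#' labels.
#'
#' The wild-type protein sequence is not part of the dataset (it was not
#' published alongside the panel), so spectrum-based modelling of this panel
#' requires a user-supplied FASTA.
#'
#' @return A list with `mutations` (a `mutation_set` of the six candidate
#'   substitutions) and `records` (an `activity_table` of the 13 labeled
#'   rows).
#' @export
transaminase_dataset <- function() {
  path <- system.file("extdata", "transaminase_t50.csv", package = "ftsar",
                      mustWork = TRUE)
  records <- read_variant_table(path)
  list(
    mutations = parse_variant_spec("I77L_Q97E_H210N_N245D_G292D_I295V"),
    records = records
  )
}
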