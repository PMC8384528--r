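#' Leave-one-out cross-validated predictions
#'
#' For each sample `i`, fits a PLSR model on all other samples and predicts
#' sample `i`. With only a handful of measured variants LOOCV is the standard
#' way to estimate out-of-sample error without sacrificing training data.
#'
#' @inheritParams fit_plsr
#' @param n_components Latent components per fold; must satisfy
#'   `n_components <= nrow(X) - 2` so every fold respects the fitting bound.
#' @return Numeric vector of held-out predictions, same length as `y`.
#' @export
loocv_predictions <- function(X, y, n_components, scale_x = FALSE) {
  grid <- loocv_grid(X, y, max_components = n_components, scale_x = scale_x)
  grid[, n_components]
}

# Held-out predictions for every component count 1..max_components in one
# pass: each fold is fitted once at the deepest count and the coefficient
# path supplies the truncated predictions. Returns an n x max_components
# matrix.
loocv_grid <- function(X, y, max_components, scale_x = FALSE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (n < 3L) stop("LOOCV needs at least 3 samples", call. = FALSE)
  max_allowed <- min(n - 2L, ncol(X))
  if (max_components < 1L || max_components > max_allowed) {
    stop("n_components must be in 1..", max_allowed,
         " (min(n_samples - 2, n_features)) for LOOCV", call. = FALSE)
  }
  preds <- matrix(NA_real_, n, max_components)
  for (i in seq_len(n)) {
    fit <- fit_plsr(X[-i, , drop = FALSE], y[-i], max_components,
                    scale_x = scale_x, allow_degenerate = TRUE)
    for (a in seq_len(max_components)) {
      preds[i, a] <- predict_plsr(fit, X[i, , drop = FALSE], n_components = a)
    }
  }
  preds
}

#' Coefficient of determination between observed and predicted activities
#'
#' The squared sample Pearson correlation between `y` and `y_hat`, the
#' goodness-of-fit statistic reported alongside cvRMSE. Always in `[0, 1]`;
#' undefined (an error) when either vector has zero variance.
#'
#' @param y Observed activities.
#' @param y_hat Predicted activities, same length.
#' @return A number in `[0, 1]`.
#' @export
r_squared <- function(y, y_hat) {
  y <- as.numeric(y)
  y_hat <- as.numeric(y_hat)
  if (length(y) != length(y_hat)) stop("length mismatch", call. = FALSE)
  if (length(y) < 2L) stop("need at least 2 observations", call. = FALSE)
  if (stats::var(y) == 0 || stats::var(y_hat) == 0) {
    stop("zero variance in y or y_hat: correlation undefined", call. = FALSE)
  }
  stats::cor(y, y_hat)^2
}

#' Root-mean-square error of cross-validated predictions
#'
#' `sqrt(mean((y - y_hat)^2))`: the primary model-ranking criterion of the
#' index scan (lower is better). Usually applied to LOOCV predictions, hence
#' the name, but it is a plain RMSE of any prediction vector.
#'
#' @inheritParams r_squared
#' @return A non-negative number, in the units of `y`.
#' @export
cv_rmse <- function(y, y_hat) {
  y <- as.numeric(y)
  y_hat <- as.numeric(y_hat)
  if (length(y) != length(y_hat)) stop("length mismatch", call. = FALSE)
  if (length(y) == 0L) stop("empty vectors", call. = FALSE)
  sqrt(mean((y - y_hat)^2))
}

#' Choose the PLSR component count by LOOCV
#'
#' Evaluates the LOOCV cvRMSE for every component count from 1 up to
#' `min(max_components, n_samples - 2, n_features)` and returns the count
#' with the smallest cvRMSE, ties broken toward fewer components. The
#' returned evaluation reuses the winning grid entry; no second nesting level
#' of cross-validation is applied (with a dozen samples a doubly nested CV is
#' too unstable to be informative, at the price of some selection optimism in
#' the reported metrics).
#'
#' @inheritParams fit_plsr
#' @param max_components Upper bound of the search grid (default 10).
#' @return A list with `n_components` (the selected count) and `evaluation`,
#'   a `model_evaluation` object: `index_accession`, `n_components`, `r2`
#'   (squared correlation of LOOCV predictions with `y`; `NA` if undefined),
#'   `cv_rmse`, `n_samples` and `loocv_predictions`. The full grid of
#'   per-count cvRMSE values is attached as the `"grid"` attribute of the
#'   evaluation.
#' @export
select_n_components <- function(X, y, max_components = 10L,
                                index_accession = NA_character_,
                                scale_x = FALSE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (max_components < 1L) stop("max_components must be >= 1", call. = FALSE)
  a_max <- min(as.integer(max_components), nrow(X) - 2L, ncol(X))
  if (a_max < 1L) stop("too few samples/features for LOOCV selection",
                       call. = FALSE)
  grid_preds <- loocv_grid(X, y, a_max, scale_x = scale_x)
  grid_rmse <- apply(grid_preds, 2L, function(yh) cv_rmse(y, yh))
  best <- which.min(grid_rmse) # which.min returns the first (smallest) on ties
  yh <- grid_preds[, best]
  r2 <- tryCatch(r_squared(y, yh), error = function(e) NA_real_)
  evaluation <- structure(
    list(
      index_accession = index_accession,
      n_components = as.integer(best),
      r2 = r2,
      cv_rmse = grid_rmse[[best]],
      n_samples = nrow(X),
      loocv_predictions = yh
    ),
    class = "model_evaluation"
  )
  attr(evaluation, "grid") <- unname(grid_rmse)
  list(n_components = as.integer(best), evaluation = evaluation)
}

#' @export
print.model_evaluation <- function(x, ...) {
  cat("<model_evaluation>",
      if (!is.na(x$index_accession)) x$index_accession else "",
      "\n  components:", x$n_components,
      "\n  LOOCV R^2: ", if (is.na(x$r2)) "NA" else sprintf("%.4f", x$r2),
      "\n  cvRMSE:    ", sprintf("%.4g", x$cv_rmse),
      " (", x$n_samples, " samples)\n")
  invisible(x)
}

#' Scan amino-acid indices for the best sequence-activity model
#'
#' The index-selection phase of the pipeline: for every candidate index, all
#' labeled variant sequences are encoded into spectra, the component count is
#' chosen by LOOCV, and the model is summarized by its LOOCV R-squared and
#' cvRMSE. The output ranks indices by cvRMSE ascending (ties by R-squared
#' descending, then accession), mirroring a scan of a full AAindex release in
#' which every usable index yields one model. An index that fails to encode
#' the sequences is skipped with a warning rather than aborting the scan.
#'
#' Note that the top of the ranking is selected over many candidate indices
#' without any multiplicity correction, so its reported metrics carry
#' winner's-curse optimism; they describe model selection, not an unbiased
#' generalization estimate.
#'
#' @param records An `activity_table` (see [read_variant_table()]); at least
#'   3 labeled rows are required and only labeled rows are used.
#' @param wt Wild-type protein sequence.
#' @param indices List of [aa_index] objects (e.g. from
#'   [parse_aaindex_db()]).
#' @param config A [spectrum_config()].
#' @param max_components Component-count search bound per index.
#' @param scale_x Passed to [fit_plsr()].
#' @return A data frame of class `index_scan` with columns `accession`,
#'   `description`, `n_components`, `r2`, `cv_rmse`, sorted as described.
#'   Per-index `model_evaluation` objects are attached as the
#'   `"evaluations"` attribute; skipped accessions as `"skipped"`.
#' @export
scan_indices <- function(records, wt, indices, config = spectrum_config(),
                         max_components = 10L, scale_x = FALSE) {
  stopifnot(inherits(config, "spectrum_config"))
  if (inherits(indices, "aa_index")) indices <- list(indices)
  if (length(indices) < 1L) stop("no indices to scan", call. = FALSE)
  labeled <- labeled_records(records)
  if (nrow(labeled) < 3L) {
    stop("need at least 3 labeled records, got ", nrow(labeled),
         call. = FALSE)
  }
  seqs <- variant_sequences(wt, labeled)
  y <- labeled$activity

  evaluations <- list()
  skipped <- character(0)
  for (idx in indices) {
    stopifnot(inherits(idx, "aa_index"))
    ev <- tryCatch({
      Xi <- spectra_matrix(seqs, idx, config)
      sel <- select_n_components(Xi, y, max_components = max_components,
                                 index_accession = idx$accession,
                                 scale_x = scale_x)
      ev <- sel$evaluation
      attr(ev, "description") <- idx$description
      ev
    }, error = function(e) {
      warning("skipping index '", idx$accession, "': ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (is.null(ev)) {
      skipped <- c(skipped, idx$accession)
    } else {
      evaluations[[idx$accession]] <- ev
    }
  }
  if (length(evaluations) == 0L) {
    stop("no index could be evaluated", call. = FALSE)
  }

  out <- data.frame(
    accession = vapply(evaluations, `[[`, character(1), "index_accession"),
    description = vapply(evaluations, function(e) {
      d <- attr(e, "description")
      if (is.null(d)) "" else d
    }, character(1)),
    n_components = vapply(evaluations, `[[`, integer(1), "n_components"),
    r2 = vapply(evaluations, `[[`, numeric(1), "r2"),
    cv_rmse = vapply(evaluations, `[[`, numeric(1), "cv_rmse"),
    stringsAsFactors = FALSE
  )
  ord <- order(out$cv_rmse, -out$r2, out$accession)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "evaluations") <- evaluations[out$accession]
  attr(out, "skipped") <- skipped
  class(out) <- c("index_scan", "data.frame")
  out
}

#' Write an index-scan report as CSV
#'
#' @param scan An `index_scan` from [scan_indices()].
#' @param file Output path.
#' @param top_k Keep only the best `top_k` rows (default all).
#' @return Invisibly, the (possibly truncated) data frame written.
#' @export
write_scan_report <- function(scan, file, top_k = NULL) {
  df <- as.data.frame(scan)
  if (!is.null(top_k)) df <- utils::head(df, top_k)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(df)
}

# labeled subset of an activity table, with parsed mutation sets aligned
labeled_records <- function(records) {
  stopifnot(inherits(records, "activity_table"))
  sets <- attr(records, "mutation_sets")
  keep <- records$labeled
  out <- records[keep, , drop = FALSE]
  attr(out, "mutation_sets") <- sets[keep]
  class(out) <- c("activity_table", "data.frame")
  out
}

# build each record's full-length sequence from the wild type
variant_sequences <- function(wt, records) {
  sets <- attr(records, "mutation_sets")
  lapply(sets, function(ms) apply_variant(wt, ms))
}
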