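#' Fit the final sequence-activity model on all labeled data
#'
#' After an index has been chosen (by [scan_indices()] or by the user), the
#' production model is fitted on every labeled record, with the latent
#' component count chosen by LOOCV unless given explicitly. The fitted model
#' carries the index and spectrum configuration so it can rebuild features
#' for new variants on its own.
#'
#' @param records An `activity_table`; only labeled rows are used.
#' @param wt Wild-type protein sequence.
#' @param index The [aa_index] to encode with.
#' @param config A [spectrum_config()].
#' @param max_components LOOCV search bound for the component count.
#' @param n_components Fix the component count instead of selecting it.
#' @param scale_x Passed to [fit_plsr()].
#' @return A `pls_model` with extra fields `index`, `config` and (when the
#'   count was selected) `selection`, the `model_evaluation` of the winning
#'   grid entry.
#' @export
fit_final_model <- function(records, wt, index, config = spectrum_config(),
                            max_components = 10L, n_components = NULL,
                            scale_x = FALSE) {
  stopifnot(inherits(index, "aa_index"), inherits(config, "spectrum_config"))
  labeled <- labeled_records(records)
  if (nrow(labeled) < 3L) {
    stop("need at least 3 labeled records", call. = FALSE)
  }
  seqs <- variant_sequences(wt, labeled)
  X <- spectra_matrix(seqs, index, config)
  y <- labeled$activity

  selection <- NULL
  if (is.null(n_components)) {
    sel <- select_n_components(X, y, max_components = max_components,
                               index_accession = index$accession,
                               scale_x = scale_x)
    n_components <- sel$n_components
    selection <- sel$evaluation
  }
  model <- fit_plsr(X, y, n_components, index_accession = index$accession,
                    scale_x = scale_x)
  model$index <- index
  model$config <- config
  model$selection <- selection
  model
}

#' Predict and rank the full combinatorial variant library
#'
#' Enumerates all `2^n` combinations of the given point mutations, builds
#' each variant's sequence and spectrum with the model's own index and
#' configuration, predicts its activity, and ranks the library by predicted
#' activity (descending; ties broken by fewer mutations, then by signature).
#' Measured activities from `records` are joined by mutation signature so
#' training-set rows are visible as such, and variants predicted to exceed
#' the best measured activity are flagged.
#'
#' Because a single substitution perturbs every frequency bin of the
#' spectrum, predictions are not additive across mutations: the predicted
#' effect of a combination is generally not the sum of its single-mutant
#' effects.
#'
#' @param model A `pls_model` from [fit_final_model()] (must carry `index`
#'   and `config`).
#' @param wt Wild-type protein sequence.
#' @param mutations A `mutation_set` of the `n` candidate point mutations.
#' @param records Optional `activity_table` of measurements to join.
#' @return A data frame of class `prediction_table` with columns `rank`,
#'   `variant` (signature), `n_mutations`, `predicted`, `measured` (`NA`
#'   where unmeasured), `is_training` and `exceeds_best_measured`.
#' @export
predict_library <- function(model, wt, mutations, records = NULL) {
  stopifnot(inherits(model, "pls_model"), inherits(mutations, "mutation_set"))
  if (is.null(model[["index"]]) || is.null(model[["config"]])) {
    stop("model carries no index/config; fit it with fit_final_model() ",
         "or attach them manually", call. = FALSE)
  }
  library <- enumerate_library(mutations)
  seqs <- lapply(library, function(ms) apply_variant(wt, ms))
  X <- spectra_matrix(seqs, model[["index"]], model[["config"]])
  predicted <- predict_plsr(model, X)

  measured <- rep(NA_real_, length(library))
  if (!is.null(records)) {
    labeled <- labeled_records(records)
    sig <- labeled$mutations
    hit <- match(names(library), sig)
    measured <- labeled$activity[hit]
  }

  df <- data.frame(
    variant = names(library),
    n_mutations = vapply(library, nrow, integer(1)),
    predicted = predicted,
    measured = measured,
    stringsAsFactors = FALSE
  )
  df$is_training <- !is.na(df$measured)
  best_measured <- if (any(df$is_training)) max(df$measured, na.rm = TRUE) else NA_real_
  df$exceeds_best_measured <- if (is.na(best_measured)) {
    rep(NA, nrow(df))
  } else {
    df$predicted > best_measured
  }
  ord <- order(-df$predicted, df$n_mutations, df$variant)
  df <- df[ord, , drop = FALSE]
  df <- cbind(rank = seq_len(nrow(df)), df)
  rownames(df) <- NULL
  attr(df, "best_measured") <- best_measured
  class(df) <- c("prediction_table", "data.frame")
  df
}

#' @export
print.prediction_table <- function(x, n = 10L, ...) {
  cat("<prediction_table> ", nrow(x), " variants ranked by predicted activity\n",
      sep = "")
  df <- utils::head(as.data.frame(x), n)
  df$predicted <- sprintf("%.2f", df$predicted)
  print(df, row.names = FALSE)
  if (nrow(x) > n) cat("... and ", nrow(x) - n, " more rows\n", sep = "")
  invisible(x)
}

#' Write a prediction table as CSV
#'
#' Predicted activities are written at full precision.
#'
#' @param table A `prediction_table`.
#' @param file Output path.
#' @return Invisibly, `table`.
#' @export
write_prediction_table <- function(table, file) {
  utils::write.csv(as.data.frame(table), file, row.names = FALSE, na = "")
  invisible(table)
}
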