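#' Fit a partial least squares regression model
#'
#' PLS1 regression fitted by NIPALS: latent components are extracted
#' sequentially, each maximizing covariance between the (deflated) predictors
#' and the response, which makes the method well suited to spectral problems
#' with far more features than samples (e.g. 13 variants x 257 frequency
#' bins). Predictor columns are mean-centered (not variance-scaled by
#' default: many padded-spectrum columns have near-zero variance, and
#' dividing by it would amplify noise) and the response is centered.
#'
#' Component extraction stops early if the response is fully deflated
#' (remaining covariance below `1e-12` relative to the first component), so
#' the effective component count can be lower than requested; the model
#' records both.
#'
#' @param X Numeric matrix, one row per sample (e.g. spectrum magnitudes).
#' @param y Numeric response vector (e.g. half-life in minutes).
#' @param n_components Number of latent components, between 1 and
#'   `min(nrow(X) - 1, ncol(X))`.
#' @param index_accession Optional accession of the index used to build `X`,
#'   carried as metadata.
#' @param scale_x If `TRUE`, scale columns to unit variance after centering
#'   (columns with near-zero variance are left unscaled).
#' @param allow_degenerate If `TRUE`, a zero-variance response yields the
#'   constant model (all coefficients zero) instead of an error.
#'
#' @return An object of class `pls_model`: list with `index_accession`,
#'   `n_components` (effective), `n_components_requested`, `x_mean`,
#'   `x_scale`, `y_mean`, `coefficients` (length `ncol(X)`),
#'   `explained_variance` (fraction of response variance captured per
#'   component) and `coef_path` (matrix of coefficient vectors for 1..A
#'   components, used by the cross-validation grid).
#'
#' @seealso [predict_plsr()], [select_n_components()]
#' @export
fit_plsr <- function(X, y, n_components,
                     index_accession = NA_character_,
                     scale_x = FALSE,
                     allow_degenerate = FALSE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  p <- ncol(X)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  if (length(y) != n) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (any(!is.finite(X)) || any(!is.finite(y))) {
    stop("X and y must be finite", call. = FALSE)
  }
  max_comp <- min(n - 1L, p)
  if (n_components < 1L || n_components > max_comp) {
    stop("n_components must be in 1..", max_comp,
         " (min(n_samples - 1, n_features))", call. = FALSE)
  }
  if (stats::var(y) == 0) {
    if (!allow_degenerate) {
      stop("response has zero variance (degenerate)", call. = FALSE)
    }
  }

  x_mean <- colMeans(X)
  E <- sweep(X, 2L, x_mean, "-")
  x_scale <- rep(1, p)
  if (scale_x) {
    s <- apply(E, 2L, stats::sd)
    x_scale <- ifelse(s > 1e-10, s, 1)
    E <- sweep(E, 2L, x_scale, "/")
  }
  y_mean <- mean(y)
  f <- y - y_mean
  ss_y <- sum(f^2)

  A <- as.integer(n_components)
  W <- matrix(0, p, A)
  P <- matrix(0, p, A)
  q <- numeric(A)
  expl <- numeric(A)
  nw0 <- NA_real_
  a_eff <- 0L
  for (a in seq_len(A)) {
    w <- drop(crossprod(E, f)) # for a univariate response NIPALS converges
    nw <- sqrt(sum(w^2))       # in a single step to w ~ X'y
    if (is.na(nw0)) nw0 <- nw
    if (nw <= 1e-12 * max(nw0, 1e-300)) break
    w <- w / nw
    t_a <- drop(E %*% w)
    tt <- sum(t_a^2)
    if (tt <= 1e-12 * max(1, sum(E^2))) break
    p_a <- drop(crossprod(E, t_a)) / tt
    q_a <- sum(f * t_a) / tt
    E <- E - tcrossprod(t_a, p_a)
    f <- f - q_a * t_a
    a_eff <- a
    W[, a] <- w
    P[, a] <- p_a
    q[a] <- q_a
    expl[a] <- if (ss_y > 0) q_a^2 * tt / ss_y else 0
  }

  coef_path <- matrix(0, p, max(a_eff, 1L))
  if (a_eff > 0L) {
    for (a in seq_len(a_eff)) {
      Wa <- W[, seq_len(a), drop = FALSE]
      Pa <- P[, seq_len(a), drop = FALSE]
      # B_a = W_a (P_a' W_a)^{-1} q_{1:a}; P'W is unit upper triangular
      coef_path[, a] <- drop(Wa %*% solve(crossprod(Pa, Wa), q[seq_len(a)]))
    }
  }

  structure(
    list(
      index_accession = index_accession,
      n_components = max(a_eff, 1L),
      n_components_requested = A,
      x_mean = x_mean,
      x_scale = x_scale,
      y_mean = y_mean,
      coefficients = coef_path[, ncol(coef_path)],
      explained_variance = expl[seq_len(max(a_eff, 1L))],
      coef_path = coef_path
    ),
    class = "pls_model"
  )
}

#' @export
print.pls_model <- function(x, ...) {
  cat("<pls_model>", if (!is.na(x$index_accession)) x$index_accession else "",
      "\n  components:", x$n_components,
      if (x$n_components < x$n_components_requested) {
        paste0(" (", x$n_components_requested, " requested; response deflated)")
      } else "",
      "\n  features:  ", length(x$coefficients),
      "\n  response variance explained:",
      sprintf("%.3f", sum(x$explained_variance)), "\n")
  invisible(x)
}

#' Predict activities with a fitted PLSR model
#'
#' Applies the model's affine map `y_mean + (x - x_mean) . b` row-wise.
#' Predictions are unbounded reals; negative predicted activities are
#' reported as-is.
#'
#' @param model A `pls_model`.
#' @param X_new Numeric matrix (or single vector) with `length(coefficients)`
#'   columns.
#' @param n_components Predict with a truncated coefficient vector using only
#'   the first `n_components` components (must not exceed the fitted count);
#'   default uses all fitted components.
#' @return Numeric vector of predictions, one per row of `X_new`.
#' @export
predict_plsr <- function(model, X_new, n_components = NULL) {
  stopifnot(inherits(model, "pls_model"))
  if (is.null(dim(X_new))) X_new <- matrix(X_new, nrow = 1L)
  X_new <- as.matrix(X_new)
  p <- length(model$coefficients)
  if (ncol(X_new) != p) {
    stop("X_new has ", ncol(X_new), " columns; model expects ", p,
         call. = FALSE)
  }
  b <- if (is.null(n_components)) {
    model$coefficients
  } else {
    # a request beyond the deflation point reuses the deepest fitted column
    # (further components carry no response covariance, predictions unchanged)
    model$coef_path[, min(n_components, ncol(model$coef_path))]
  }
  Xc <- sweep(sweep(X_new, 2L, model$x_mean, "-"), 2L, model$x_scale, "/")
  drop(model$y_mean + Xc %*% b)
}

#' Save a PLSR model as structured text
#'
#' Writes the model (and, when present, the attached amino-acid index and
#' spectrum configuration from [fit_final_model()]) as JSON so a prediction
#' run can be reproduced later without refitting.
#'
#' @param model A `pls_model`.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_pls_model <- function(model, file) {
  stopifnot(inherits(model, "pls_model"))
  payload <- list(
    format = "ftsar_pls_model",
    version = 1L,
    index_accession = model$index_accession,
    n_components = model$n_components,
    n_components_requested = model$n_components_requested,
    x_mean = model$x_mean,
    x_scale = model$x_scale,
    y_mean = model$y_mean,
    coefficients = model$coefficients,
    explained_variance = model$explained_variance
  )
  if (!is.null(model[["index"]])) {
    payload$index <- list(
      accession = model[["index"]]$accession,
      description = model[["index"]]$description,
      values = as.list(model[["index"]]$values)
    )
  }
  if (!is.null(model[["config"]])) {
    payload$config <- list(spectrum = model[["config"]]$spectrum,
                           standardize = model[["config"]]$standardize)
  }
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}

#' Load a PLSR model written by [write_pls_model()]
#'
#' @param file Path to the JSON model file.
#' @return A `pls_model` (with `index` and `config` restored when present).
#' @export
read_pls_model <- function(file) {
  payload <- jsonlite::read_json(file, simplifyVector = TRUE)
  if (!identical(payload$format, "ftsar_pls_model")) {
    stop("'", file, "' is not a ftsar PLSR model file", call. = FALSE)
  }
  model <- structure(
    list(
      index_accession = payload$index_accession,
      n_components = as.integer(payload$n_components),
      n_components_requested = as.integer(payload$n_components_requested),
      x_mean = as.numeric(payload$x_mean),
      x_scale = as.numeric(payload$x_scale),
      y_mean = as.numeric(payload$y_mean),
      coefficients = as.numeric(payload$coefficients),
      explained_variance = as.numeric(payload$explained_variance),
      coef_path = matrix(as.numeric(payload$coefficients), ncol = 1L)
    ),
    class = "pls_model"
  )
  if (!is.null(payload[["index"]])) {
    model$index <- aa_index(
      payload[["index"]]$accession,
      unlist(payload[["index"]]$values),
      payload[["index"]]$description
    )
  }
  if (!is.null(payload[["config"]])) {
    model$config <- spectrum_config(payload[["config"]]$spectrum,
                                    payload[["config"]]$standardize)
  }
  model
}
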