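#' Fit a per-variable covariate residualizer with standardization
#'
#' For each column of `X`, fits an ordinary least-squares regression on an
#' intercept plus the supplied nuisance covariates (age, sex, smoking by
#' convention), and records the post-residual mean and sample standard
#' deviation (n-1 divisor). The resulting model transforms new subjects with
#' the training coefficients, which is what makes leakage-free
#' cross-validation possible.
#'
#' @param X numeric matrix (`n x p`), columns named.
#' @param covariates data.frame/matrix of nuisance covariates (`n x q`);
#'   may have zero columns, in which case the transform just centers and
#'   scales.
#' @return An object of class `residualizer` storing per-variable
#'   coefficients (intercept + covariates), post-residual means and scales.
#' @export
fit_residualizer <- function(X, covariates) {
  X <- as.matrix(X)
  n <- nrow(X)
  C <- as.matrix(as.data.frame(covariates))
  if (nrow(C) != n) stop("covariates and X disagree on n", call. = FALSE)
  q <- ncol(C)
  if (n <= q + 1)
    stop("need n > q + 1 observations to residualize", call. = FALSE)
  D <- cbind(`(Intercept)` = 1, C)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    drop_idx <- qrD$pivot[seq.int(qrD$rank + 1L, ncol(D))]
    stop("collinear covariate column(s): ",
         paste(colnames(D)[drop_idx], collapse = ", "), call. = FALSE)
  }
  coefs <- qr.coef(qrD, X)                    # (q+1) x p
  resid <- X - D %*% coefs
  mu <- colMeans(resid)                        # ~0 by construction
  sc <- apply(resid, 2L, stats::sd)
  if (any(sc < 1e-12)) {
    bad <- colnames(X)[sc < 1e-12] %||% which(sc < 1e-12)
    stop("zero post-residual variance for: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(coefficients = coefs, covariate_names = colnames(C),
         variable_names = colnames(X), center = mu, scale = sc, n_fit = n),
    class = "residualizer"
  )
}

#' Apply a fitted residualizer
#'
#' Computes `(X - prediction from training coefficients - stored mean) /
#' stored scale`. On the data the model was fit on, columns come out with
#' mean 0 and unit sample standard deviation; on new subjects the training
#' model is reused, never refit.
#'
#' @param model a [fit_residualizer()] result.
#' @param X matrix with the same columns the model was fit on.
#' @param covariates covariate table matching the model's covariates.
#' @return Standardized residual matrix, same shape as `X`.
#' @export
transform_residualizer <- function(model, X, covariates) {
  stopifnot(inherits(model, "residualizer"))
  X <- as.matrix(X)
  if (!is.null(model$variable_names) && !is.null(colnames(X)) &&
      !identical(colnames(X), model$variable_names))
    stop("columns of X do not match the fitted model", call. = FALSE)
  C <- as.matrix(as.data.frame(covariates))
  if (!identical(colnames(C), model$covariate_names))
    stop("covariate columns do not match the fitted model", call. = FALSE)
  D <- cbind(1, C)
  resid <- X - D %*% model$coefficients
  sweep(sweep(resid, 2L, model$center, `-`), 2L, model$scale, `/`)
}

#' @export
predict.residualizer <- function(object, X, covariates, ...) {
  transform_residualizer(object, X, covariates)
}

#' Residualize and standardize every block of a dataset
#'
#' Convenience wrapper applying [fit_residualizer()] per block. When
#' `models` is supplied (e.g. fit on a training fold), blocks are
#' transformed with those models instead of refitting — the leakage-free
#' path used inside cross-validation.
#'
#' @param dataset a [multiblock_dataset()].
#' @param models optional named list of `residualizer` objects (one per
#'   block) from a previous call.
#' @param use_covariates if `FALSE`, residualization degenerates to
#'   centering/scaling only (global-standardization mode).
#' @return list with `dataset` (transformed blocks; phenotype/covariates
#'   untouched) and `models`.
#' @export
preprocess_dataset <- function(dataset, models = NULL, use_covariates = TRUE) {
  stopifnot(inherits(dataset, "multiblock_dataset"))
  cov_tab <- if (use_covariates) dataset$covariates else
    dataset$covariates[, 0, drop = FALSE]
  if (is.null(models)) {
    models <- lapply(dataset$blocks, fit_residualizer, covariates = cov_tab)
  }
  blocks <- lapply(names(dataset$blocks), function(nm) {
    transform_residualizer(models[[nm]], dataset$blocks[[nm]], cov_tab)
  })
  names(blocks) <- names(dataset$blocks)
  out <- dataset
  out$blocks <- blocks
  list(dataset = out, models = models)
}

#' Serialize a residualizer to JSON (reproducibility aid)
#' @param model a `residualizer`.
#' @param path file path to write; if `NULL`, the JSON string is returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
residualizer_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "residualizer"))
  x <- list(coefficients = as.data.frame(model$coefficients),
            covariate_names = model$covariate_names,
            variable_names = model$variable_names,
            center = model$center, scale = model$scale, n_fit = model$n_fit)
  if (is.null(path))
    return(jsonlite::toJSON(x, digits = NA, auto_unbox = TRUE))
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
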