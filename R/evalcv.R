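#' Two-class linear discriminant analysis on component scores
#'
#' Closed-form two-class LDA: the decision weight is the pooled-covariance
#' inverse times the class-mean difference, with the threshold set from the
#' class means and priors. When the pooled covariance is singular (or nearly
#' so) a ridge of `1e-6 * trace / d` is added and recorded on the model.
#'
#' @param scores numeric `n x d` matrix of features (here, latent component
#'   scores).
#' @param labels vector with exactly two classes present.
#' @return An `lda_model`: class means, pooled covariance, priors, decision
#'   weights `w`, threshold `c` (predict class 1 when `w'x > c`), `ridge`
#'   flag, class `levels`.
#' @export
lda_fit <- function(scores, labels) {
  scores <- as.matrix(scores)
  d <- ncol(scores)
  if (d < 1L) stop("need at least one feature", call. = FALSE)
  f <- factor(labels)
  if (nlevels(f) != 2L)
    stop("both classes must be present in the training labels",
         call. = FALSE)
  lv <- levels(f)
  n <- nrow(scores)
  i0 <- which(f == lv[1]); i1 <- which(f == lv[2])
  mu0 <- colMeans(scores[i0, , drop = FALSE])
  mu1 <- colMeans(scores[i1, , drop = FALSE])
  cov_or_zero <- function(x) if (nrow(x) > 1) stats::cov(x) else
    matrix(0, d, d)
  S <- ((length(i0) - 1) * cov_or_zero(scores[i0, , drop = FALSE]) +
        (length(i1) - 1) * cov_or_zero(scores[i1, , drop = FALSE])) /
    max(1, n - 2)
  ridge <- 0
  ok <- tryCatch({chol(S); TRUE}, error = function(e) FALSE)
  if (!ok || rcond(S) < 1e-10) {
    ridge <- 1e-6 * max(sum(diag(S)), 1e-12) / d
    S <- S + ridge * diag(d)
    message("lda_fit: singular pooled covariance; ridge ", signif(ridge, 3),
            " added")
  }
  w <- solve(S, mu1 - mu0)
  priors <- c(length(i0), length(i1)) / n
  thr <- sum(w * (mu0 + mu1)) / 2 - log(priors[2] / priors[1])
  structure(
    list(means = rbind(mu0, mu1), pooled_cov = S, priors = priors,
         weights = w, threshold = thr, ridge = ridge, levels = lv),
    class = "lda_model"
  )
}

#' @rdname lda_fit
#' @param model an `lda_model`.
#' @param scores feature matrix to classify.
#' @return `lda_predict`: predicted labels on the training label scale.
#' @export
lda_predict <- function(model, scores) {
  stopifnot(inherits(model, "lda_model"))
  scores <- as.matrix(scores)
  s <- as.vector(scores %*% model$weights)
  model$levels[ifelse(s > model$threshold, 2L, 1L)]
}

# Stratified fold assignment: each class is split as evenly as possible.
make_folds <- function(labels, k, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

# Default sparsity grid: log-spaced s values per penalized block
default_sparsity_grid <- function(p, n_values = 5L) {
  lo <- 1 / sqrt(p)
  exp(seq(log(lo), log(1), length.out = n_values))
}

# All grid combinations over the penalized blocks, ordered sparsest-first
# (sum of effective L1 bounds ascending) so ties break toward sparser.
sparsity_combos <- function(grids, p) {
  combos <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
  bound_sum <- as.matrix(combos) %*% sqrt(p[names(grids)])
  combos[order(bound_sum), , drop = FALSE]
}

# Assemble the standardized block list (+ DX block) fed to sgcca_fit.
# The phenotype block is the 0/1 diagnosis standardized like any variable,
# using training mean/sd when supplied.
dx_block <- function(phenotype, center = NULL, scale = NULL) {
  center <- center %||% mean(phenotype)
  scale <- scale %||% stats::sd(phenotype)
  matrix((phenotype - center) / scale, ncol = 1,
         dimnames = list(NULL, "diagnosis"))
}

#' Externally cross-validated SGCCA + LDA
#'
#' The evaluation loop: stratified k-fold split; per fold, residualization
#' and standardization are fit on the training subjects only (when
#' `residualize_in_fold = TRUE`), the per-block sparsity is tuned by an
#' inner cross-validation on the training fold, SGCCA is fit on the training
#' fold, and a two-class LDA on the RNA and IMG component scores predicts
#' the held-out subjects. Fold weight vectors are aggregated into
#' per-variable occurrence counts and mean absolute loadings.
#'
#' @param dataset a [multiblock_dataset()] with blocks `RNA` and `IMG` (raw,
#'   unstandardized; preprocessing happens inside the folds).
#' @param design a [build_design()] over blocks (RNA, IMG, DX).
#' @param scheme scheme function, default `"centroid"`.
#' @param sparsity_grid named list of candidate `s` values per penalized
#'   block (defaults: 5 log-spaced values from `1/sqrt(p_j)` to 1 for RNA
#'   and IMG).
#' @param k outer fold count (default 5).
#' @param inner_k inner tuning fold count (default 3).
#' @param seed integer seed driving fold assignment and fit initialization.
#' @param residualize_in_fold fit confound models within training folds
#'   (default) or once globally beforehand.
#' @param robust_min occurrence threshold for the robust flag (default 3).
#' @return A `cv_report`: per-fold records (test indices, chosen sparsity,
#'   fit, test error), `error_rates` (length k), and per-block `signature`
#'   tables (variable, meanf, occurrence, robust, per-fold absolute
#'   loadings).
#' @export
cross_validate <- function(dataset, design, scheme = "centroid",
                           sparsity_grid = NULL, k = 5L, inner_k = 3L,
                           seed = 1, residualize_in_fold = TRUE,
                           robust_min = 3L) {
  stopifnot(inherits(dataset, "multiblock_dataset"))
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  pheno <- dataset$phenotype
  p <- vapply(dataset$blocks, ncol, integer(1))
  if (is.null(sparsity_grid))
    sparsity_grid <- lapply(p, default_sparsity_grid)
  combos <- sparsity_combos(sparsity_grid, p)
  fold <- make_folds(pheno, k, seed)
  seeds <- derive_seeds(seed, k, stream = 1L)

  if (!residualize_in_fold) {
    dataset <- preprocess_dataset(dataset)$dataset
  }

  folds <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- which(fold == f)
    train_idx <- which(fold != f)
    train <- subset_dataset(dataset, train_idx)
    test <- subset_dataset(dataset, test_idx)
    if (length(unique(train$phenotype)) < 2L)
      stop("fold ", f, " training split lost a class; use smaller k",
           call. = FALSE)
    if (residualize_in_fold) {
      pp <- tryCatch(preprocess_dataset(train), error = function(e)
        stop("fold ", f, " too small for preprocessing (", conditionMessage(e),
             "); use a smaller k", call. = FALSE))
      Xtr <- pp$dataset$blocks
      Xte <- preprocess_dataset(test, models = pp$models)$dataset$blocks
    } else {
      Xtr <- train$blocks
      Xte <- test$blocks
    }
    dx_c <- mean(train$phenotype); dx_s <- stats::sd(train$phenotype)
    blocks_tr <- c(Xtr, list(DX = dx_block(train$phenotype, dx_c, dx_s)))

    tuned <- tune_sparsity(blocks_tr, train$phenotype, design, scheme,
                           combos, inner_k, seeds[f])
    fit <- sgcca_fit(blocks_tr, design, scheme = scheme,
                     sparsity = tuned, seed = seeds[f])
    tr_scores <- fit$components[, c("RNA", "IMG"), drop = FALSE]
    lda <- lda_fit(tr_scores, train$phenotype)
    te_scores <- cbind(
      RNA = as.vector(Xte$RNA %*% fit$weights$RNA),
      IMG = as.vector(Xte$IMG %*% fit$weights$IMG))
    pred <- lda_predict(lda, te_scores)
    err <- mean(as.numeric(pred) != test$phenotype)
    folds[[f]] <- list(test_idx = test_idx, train_idx = train_idx,
                       sparsity = tuned, fit = fit, lda = lda,
                       test_error = err)
  }

  signature <- lapply(c("RNA", "IMG"), function(nm) {
    L <- do.call(rbind, lapply(folds, function(fd)
      abs(fd$fit$weights[[nm]])))
    stability_from_loadings(L, robust_min)
  })
  names(signature) <- c("RNA", "IMG")
  structure(
    list(k = k, folds = folds,
         error_rates = vapply(folds, `[[`, numeric(1), "test_error"),
         signature = signature, robust_min = robust_min,
         settings = list(design = design$name, scheme = scheme, seed = seed,
                         residualize_in_fold = residualize_in_fold)),
    class = "cv_report"
  )
}

# Inner tuning loop: mean LDA error over inner folds per sparsity combo;
# combos arrive sparsest-first, so which.min breaks ties toward sparser.
tune_sparsity <- function(blocks_tr, pheno, design, scheme, combos,
                          inner_k, seed) {
  if (nrow(combos) == 1L)
    return(stats::setNames(as.numeric(combos[1L, ]), colnames(combos)))
  ifold <- make_folds(pheno, inner_k, seed + 1)
  err <- matrix(NA_real_, nrow(combos), inner_k)
  for (g in seq_len(inner_k)) {
    tr <- which(ifold != g); te <- which(ifold == g)
    if (length(unique(pheno[tr])) < 2L) next
    btr <- lapply(blocks_tr, function(b) b[tr, , drop = FALSE])
    btr$DX <- dx_block(pheno[tr])
    for (ci in seq_len(nrow(combos))) {
      sp <- stats::setNames(as.numeric(combos[ci, ]), colnames(combos))
      fit <- sgcca_fit(btr, design, scheme = scheme, sparsity = sp,
                       seed = seed)
      lda <- lda_fit(fit$components[, c("RNA", "IMG"), drop = FALSE],
                     pheno[tr])
      te_sc <- cbind(
        RNA = as.vector(blocks_tr$RNA[te, , drop = FALSE] %*%
                          fit$weights$RNA),
        IMG = as.vector(blocks_tr$IMG[te, , drop = FALSE] %*%
                          fit$weights$IMG))
      err[ci, g] <- mean(as.numeric(lda_predict(lda, te_sc)) != pheno[te])
    }
  }
  mean_err <- rowMeans(err, na.rm = TRUE)
  best <- which.min(mean_err)
  stats::setNames(as.numeric(combos[best, ]), colnames(combos))
}

# Core Table-2-style aggregation from a k x p matrix of absolute loadings.
stability_from_loadings <- function(loadings, robust_min = 3L,
                                    zero_tol = 1e-12) {
  L <- abs(as.matrix(loadings))
  vars <- colnames(L) %||% paste0("V", seq_len(ncol(L)))
  occurrence <- colSums(L > zero_tol)
  meanf <- colMeans(L)
  tab <- data.frame(variable = vars, meanf = meanf,
                    occurrence = as.integer(occurrence),
                    robust = occurrence >= robust_min,
                    stringsAsFactors = FALSE)
  folds <- as.data.frame(t(L))
  names(folds) <- paste0("fold", seq_len(nrow(L)))
  tab <- cbind(tab, folds)
  tab <- tab[order(-tab$meanf), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Fold-stability signature selection
#'
#' Aggregates per-fold weight vectors into the per-variable occurrence count
#' (number of folds with a nonzero loading, nonzero meaning `> 1e-12` in
#' absolute value), the mean of the k absolute loadings (zeros included),
#' and a robust flag set when the occurrence reaches `robust_min`. Rows are
#' sorted descending by mean absolute loading.
#'
#' @param x a `cv_report` or a `k x p` matrix of (absolute) fold loadings.
#' @param robust_min minimum occurrence for the robust flag (default 3).
#' @param ... unused.
#' @return For a matrix: one signature data.frame. For a `cv_report`: a
#'   named list of signature tables, one per penalized block.
#' @export
stability_summary <- function(x, robust_min = 3L, ...) {
  UseMethod("stability_summary")
}

#' @export
stability_summary.matrix <- function(x, robust_min = 3L, ...) {
  stability_from_loadings(x, robust_min)
}

#' @export
stability_summary.cv_report <- function(x, robust_min = 3L, ...) {
  out <- lapply(c("RNA", "IMG"), function(nm) {
    L <- do.call(rbind, lapply(x$folds, function(fd)
      abs(fd$fit$weights[[nm]])))
    stability_from_loadings(L, robust_min)
  })
  names(out) <- c("RNA", "IMG")
  out
}

#' Compare block designs by cross-validated error
#'
#' Runs [cross_validate()] for each candidate design over a set of seeds and
#' collects the fold-level test errors — the data behind a design-comparison
#' boxplot — flagging the design with the smallest mean error.
#'
#' @param dataset a [multiblock_dataset()].
#' @param designs list of [build_design()] objects (or design names).
#' @param seeds integer vector of replicate seeds.
#' @param ... passed to [cross_validate()] (scheme, k, sparsity_grid, ...).
#' @return A `design_comparison`: `errors` data.frame (design, seed, fold,
#'   error), `summary` (mean error per design), `best` (name), and `reports`
#'   (nested list of `cv_report`s).
#' @export
compare_designs <- function(dataset, designs, seeds = 1, ...) {
  if (length(designs) < 2L && length(designs) != 1L)
    stop("supply at least one design", call. = FALSE)
  designs <- lapply(designs, function(d)
    if (inherits(d, "design_spec")) d else build_design(d))
  names(designs) <- vapply(designs, `[[`, character(1), "name")
  rows <- list()
  reports <- list()
  for (dn in names(designs)) {
    reports[[dn]] <- list()
    for (s in seeds) {
      rep_ <- cross_validate(dataset, designs[[dn]], seed = s, ...)
      reports[[dn]][[as.character(s)]] <- rep_
      rows[[length(rows) + 1L]] <- data.frame(
        design = dn, seed = s, fold = seq_len(rep_$k),
        error = rep_$error_rates, stringsAsFactors = FALSE)
    }
  }
  errors <- do.call(rbind, rows)
  summary <- stats::aggregate(error ~ design, errors, mean)
  best <- summary$design[which.min(summary$error)]
  structure(list(errors = errors, summary = summary, best = best,
                 reports = reports),
            class = "design_comparison")
}

#' @export
print.design_comparison <- function(x, ...) {
  cat("Design comparison (mean test error):\n")
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %-20s %.3f%s\n", x$summary$design[i], x$summary$error[i],
                if (x$summary$design[i] == x$best) "  <- best" else ""))
  invisible(x)
}

#' Write signature tables and error-rate samples as TSV
#' @param report a `cv_report` or `design_comparison`.
#' @param dir output directory (created if needed).
#' @return written paths, invisibly.
#' @export
write_cv_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  if (inherits(report, "cv_report")) {
    for (nm in names(report$signature)) {
      pth <- file.path(dir, paste0("signature_", nm, ".tsv"))
      utils::write.table(report$signature[[nm]], pth, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      paths <- c(paths, pth)
    }
    pth <- file.path(dir, "error_rates.tsv")
    utils::write.table(
      data.frame(fold = seq_len(report$k), error = report$error_rates),
      pth, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, pth)
  } else if (inherits(report, "design_comparison")) {
    pth <- file.path(dir, "error_rates.tsv")
    utils::write.table(report$errors, pth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, pth)
  } else stop("unsupported report type", call. = FALSE)
  invisible(paths)
}
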