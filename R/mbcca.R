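#' Build a block design matrix
#'
#' The design matrix `C` is the binary, symmetric, zero-diagonal matrix
#' declaring which block pairs are hypothesized to be connected. Three named
#' designs over the conventional block order (RNA, IMG, DX) encode competing
#' causal hypotheses:
#'
#' * `sequential`: RNA -- IMG -- DX (imaging intermediate between
#'   transcription and diagnosis),
#' * `complete`: all three pairs connected,
#' * `reversed_sequential`: IMG -- RNA -- DX (transcription intermediate).
#'
#' @param name one of `"sequential"`, `"complete"`, `"reversed_sequential"`,
#'   or `"custom"` (then supply `C`).
#' @param block_order character vector of block names; the named designs
#'   require exactly three, interpreted positionally as (RNA, IMG, DX).
#' @param C for `name = "custom"`: a symmetric 0/1 matrix with zero
#'   diagonal, at least one edge, and a connected graph.
#' @return A `design_spec`: list with `C` (named matrix), `name`,
#'   `block_order`.
#' @export
build_design <- function(name = c("sequential", "complete",
                                  "reversed_sequential", "custom"),
                         block_order = c("RNA", "IMG", "DX"), C = NULL) {
  name <- tryCatch(match.arg(name), error = function(e)
    stop("unknown design '", name[1], "'; valid names: sequential, ",
         "complete, reversed_sequential, custom", call. = FALSE))
  J <- length(block_order)
  if (name != "custom") {
    if (J != 3L)
      stop("named designs require exactly 3 blocks", call. = FALSE)
    C <- switch(name,
      sequential = rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)),
      complete = rbind(c(0, 1, 1), c(1, 0, 1), c(1, 1, 0)),
      reversed_sequential = rbind(c(0, 1, 1), c(1, 0, 0), c(1, 0, 0))
    )
  } else {
    if (is.null(C)) stop("custom design needs a C matrix", call. = FALSE)
    C <- as.matrix(C)
  }
  dimnames(C) <- list(block_order, block_order)
  validate_design(C)
  structure(list(C = C, name = name, block_order = block_order),
            class = "design_spec")
}

validate_design <- function(C) {
  if (nrow(C) != ncol(C) || !isTRUE(all.equal(C, t(C))))
    stop("design matrix must be square and symmetric", call. = FALSE)
  if (any(diag(C) != 0))
    stop("design matrix must have a zero diagonal", call. = FALSE)
  if (!all(C %in% c(0, 1)))
    stop("design matrix entries must be 0/1", call. = FALSE)
  if (sum(C) == 0)
    stop("design matrix needs at least one connection", call. = FALSE)
  # connectivity via reachability
  J <- nrow(C)
  reach <- diag(J) + C
  for (i in seq_len(J)) reach <- pmin(reach %*% (diag(J) + C), 1)
  if (any(reach == 0))
    stop("design graph is not connected; a joint fit is undefined",
         call. = FALSE)
  invisible(C)
}

# Scheme function g and its derivative weighting w(g, cov)
scheme_g <- function(scheme) {
  switch(scheme,
         horst = function(x) x,
         factorial = function(x) x^2,
         centroid = function(x) abs(x),
         stop("unknown scheme '", scheme, "'", call. = FALSE))
}
scheme_w <- function(scheme) {
  switch(scheme,
         horst = function(x) rep(1, length(x)),
         factorial = function(x) 2 * x,
         centroid = function(x) sign(x))
}

#' Multiblock covariance criterion
#'
#' Evaluates `sum_{j,k} C[j,k] g(cov(X_j a_j, X_k a_k))` with the covariance
#' taken with the n-1 divisor. Both orientations of each connected pair are
#' counted (the double sum), i.e. the value is twice the upper-triangle sum.
#'
#' @param blocks named list of `n x p_j` matrices.
#' @param weights list of weight vectors `a_j`, matching `blocks`.
#' @param design a `design_spec` (or bare C matrix in block order).
#' @param scheme `"horst"` (identity), `"factorial"` (square) or
#'   `"centroid"` (absolute value).
#' @return scalar criterion value.
#' @export
sgcca_criterion <- function(blocks, weights, design,
                            scheme = c("centroid", "horst", "factorial")) {
  scheme <- match.arg(scheme)
  C <- if (inherits(design, "design_spec")) design$C else as.matrix(design)
  Y <- vapply(seq_along(blocks),
              function(j) as.vector(blocks[[j]] %*% weights[[j]]),
              numeric(nrow(blocks[[1L]])))
  V <- stats::cov(Y)  # n-1 divisor
  g <- scheme_g(scheme)
  sum(C * g(V))
}

#' Project onto the intersection of the L2 ball and an L1 ball
#'
#' Returns `argmax_w v'w` subject to `||w||_2 <= 1` and `||w||_1 <= bound`,
#' computed by soft-thresholding `S(v, lambda) / ||S(v, lambda)||_2` with
#' `lambda` found by bisection (`lambda = 0` when the unconstrained
#' direction is already feasible). With `bound = 1` the solution is the
#' signed one-hot at the largest `|v_i|`; with `bound >= sqrt(p)` the L1
#' constraint is vacuous.
#'
#' @param v numeric vector, not all zero.
#' @param bound L1 bound, `>= 1`.
#' @return unit-L2 vector satisfying both constraints.
#' @export
project_l1_l2 <- function(v, bound) {
  if (all(v == 0)) stop("direction undefined for an all-zero vector",
                        call. = FALSE)
  if (bound < 1) stop("L1 bound must be >= 1", call. = FALSE)
  u <- v / sqrt(sum(v^2))
  if (sum(abs(u)) <= bound + 1e-12) return(u)
  soft <- function(lambda) {
    s <- sign(v) * pmax(abs(v) - lambda, 0)
    nrm <- sqrt(sum(s^2))
    if (nrm == 0) return(NULL)
    s / nrm
  }
  l1_of <- function(lambda) {
    s <- soft(lambda)
    if (is.null(s)) return(0)
    sum(abs(s))
  }
  lo <- 0
  hi <- max(abs(v))
  # l1_of is nonincreasing in lambda: from ||u||_1 (> bound) down to 1
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (l1_of(mid) > bound) lo <- mid else hi <- mid
    if (hi - lo < 1e-14 * max(1, max(abs(v)))) break
  }
  w <- soft(hi)
  if (is.null(w)) { # numerical corner: fall back to the one-hot solution
    i <- which.max(abs(v))
    w <- numeric(length(v))
    w[i] <- sign(v[i])
  }
  w
}

# Project a gradient direction onto a block's constraint set.
# Regularized mode: a = Minv v / sqrt(v' Minv v); sparse mode: L1 inside L2.
project_block <- function(v, constraint) {
  if (constraint$mode == "regularized") {
    z <- constraint$Minv %*% v
    denom <- sqrt(sum(v * z))
    if (denom < 1e-300) return(NULL)
    as.vector(z / denom)
  } else {
    if (all(v == 0)) return(NULL)
    project_l1_l2(v, constraint$bound)
  }
}

#' Fit regularized / sparse generalized canonical correlation
#'
#' Block-relaxation (Gauss-Seidel) maximization of the multiblock covariance
#' criterion `sum_{j,k} C[j,k] g(cov(X_j a_j, X_k a_k))`. Each sweep updates
#' one block at a time: the inner component `z_j = sum_k C[j,k] w(cov_jk)
#' y_k` (with `w` the derivative weighting of the scheme: 1 for horst,
#' `2 cov` for factorial, `sign(cov)` for centroid) gives the ascent
#' direction `X_j' z_j`, which is projected back onto the block's constraint
#' set. Constraints are either the shrinkage ellipsoid
#' `a' M_j a <= 1` with `M_j = tau_j I + (1 - tau_j) X_j'X_j / n`
#' (regularized mode) or `||a||_2 <= 1, ||a||_1 <= s_j sqrt(p_j)` (sparse
#' mode). The criterion trace is nondecreasing; non-convergence within
#' `max_iter` yields a warning and `converged = FALSE`, never an error.
#'
#' @param blocks named list of standardized `n x p_j` matrices (run
#'   [preprocess_dataset()] first).
#' @param design a [build_design()] result whose block order matches
#'   `names(blocks)`.
#' @param scheme scheme function: `"centroid"` (default), `"horst"`,
#'   `"factorial"`.
#' @param tau per-block shrinkage in `[0, 1]` (regularized mode);
#'   default 1 for all blocks (pure covariance criterion).
#' @param sparsity optional per-block `s_j` in `[1/sqrt(p_j), 1]`
#'   (named vector or single value recycled over penalized blocks);
#'   effective L1 bound is `s_j * sqrt(p_j)`. Blocks absent from a named
#'   vector (e.g. a single-column phenotype block) get a plain unit-L2
#'   constraint. Supplying `sparsity` selects sparse mode.
#' @param init `"random"` (seed-deterministic normal directions) or a list
#'   of starting weight vectors.
#' @param tol convergence tolerance on the criterion gain (default 1e-8).
#' @param max_iter maximum sweeps (default 1000).
#' @param seed integer seed for the random initialization.
#' @return An `sgcca_fit`: list with `weights` (named, per block),
#'   `components` (`y_j = X_j a_j`), `crit` (per-sweep trace), `converged`,
#'   `iterations`, and a `spec` echo (design, scheme, mode, tau/sparsity,
#'   seed).
#' @export
sgcca_fit <- function(blocks, design, scheme = c("centroid", "horst",
                                                 "factorial"),
                      tau = NULL, sparsity = NULL, init = "random",
                      tol = 1e-8, max_iter = 1000L, seed = 1) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(design, "design_spec"))
  J <- length(blocks)
  if (J != length(design$block_order) ||
      (!is.null(names(blocks)) &&
       !identical(names(blocks), design$block_order)))
    stop("blocks do not match the design's block order", call. = FALSE)
  n <- nrow(blocks[[1L]])
  p <- vapply(blocks, ncol, integer(1))
  C <- design$C

  mode <- if (!is.null(sparsity)) "sparse" else "regularized"
  constraints <- vector("list", J)
  if (mode == "regularized") {
    tau <- tau %||% rep(1, J)
    if (length(tau) == 1L) tau <- rep(tau, J)
    if (any(tau < 0 | tau > 1)) stop("tau must lie in [0, 1]", call. = FALSE)
    for (j in seq_len(J)) {
      M <- tau[j] * diag(p[j]) +
        (1 - tau[j]) * crossprod(blocks[[j]]) / n
      Minv <- tryCatch(chol2inv(chol(M)), error = function(e)
        stop("shrinkage matrix for block '", names(blocks)[j],
             "' is not positive definite; increase tau", call. = FALSE))
      constraints[[j]] <- list(mode = "regularized", Minv = Minv)
    }
  } else {
    s <- sparsity
    if (is.null(names(s))) {
      s <- stats::setNames(rep_len(s, J), names(blocks))
    }
    for (j in seq_len(J)) {
      nm <- names(blocks)[j]
      if (nm %in% names(s) && !is.na(s[nm])) {
        sj <- as.numeric(s[nm])
        if (sj < 1 / sqrt(p[j]) - 1e-12 || sj > 1 + 1e-12)
          stop("sparsity for block '", nm, "' must lie in [1/sqrt(p_j), 1]",
               call. = FALSE)
        constraints[[j]] <- list(mode = "sparse",
                                 bound = max(1, sj * sqrt(p[j])))
      } else {
        constraints[[j]] <- list(mode = "sparse", bound = sqrt(p[j]))
      }
    }
  }

  # Initialization: seed-deterministic random directions on the constraint set
  a <- if (is.list(init)) {
    lapply(seq_len(J), function(j) {
      w <- project_block(as.numeric(init[[j]]), constraints[[j]])
      if (is.null(w)) stop("invalid initial weights", call. = FALSE)
      w
    })
  } else {
    with_seed(seed, lapply(seq_len(J), function(j) {
      project_block(stats::rnorm(p[j]), constraints[[j]])
    }))
  }
  Y <- vapply(seq_len(J), function(j) as.vector(blocks[[j]] %*% a[[j]]),
              numeric(n))

  wfun <- scheme_w(scheme)
  crit_fun <- function() sgcca_criterion(blocks, a, C, scheme)
  crit <- crit_fun()
  trace <- crit
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    for (j in seq_len(J)) {
      nbrs <- which(C[j, ] != 0)
      covs <- vapply(nbrs, function(k) sum(Y[, j] * Y[, k]) / (n - 1) -
                       mean(Y[, j]) * mean(Y[, k]) * n / (n - 1),
                     numeric(1))
      iw <- wfun(covs)
      if (all(iw == 0)) next  # centroid with all-zero covariances
      z <- Y[, nbrs, drop = FALSE] %*% iw
      v <- crossprod(blocks[[j]], z)
      anew <- project_block(as.vector(v), constraints[[j]])
      if (is.null(anew)) next
      a[[j]] <- anew
      Y[, j] <- blocks[[j]] %*% anew
    }
    newcrit <- crit_fun()
    trace <- c(trace, newcrit)
    if (newcrit - crit < tol) {
      converged <- TRUE
      crit <- newcrit
      break
    }
    crit <- newcrit
  }
  if (!converged)
    warning("sgcca_fit did not converge in ", max_iter, " sweeps",
            call. = FALSE)

  # Canonical sign convention: make each block's largest-|entry| positive.
  # Safe per block for sign-invariant schemes; for horst only a global flip
  # preserves the criterion, anchored on the first block.
  if (scheme %in% c("centroid", "factorial")) {
    for (j in seq_len(J)) {
      i <- which.max(abs(a[[j]]))
      if (a[[j]][i] < 0) { a[[j]] <- -a[[j]]; Y[, j] <- -Y[, j] }
    }
  } else {
    i <- which.max(abs(a[[1L]]))
    if (a[[1L]][i] < 0) {
      for (j in seq_len(J)) { a[[j]] <- -a[[j]]; Y[, j] <- -Y[, j] }
    }
  }

  names(a) <- names(blocks)
  for (j in seq_len(J)) names(a[[j]]) <- colnames(blocks[[j]])
  colnames(Y) <- names(blocks)
  structure(
    list(weights = a, components = Y, crit = trace, converged = converged,
         iterations = iter,
         spec = list(design = design, scheme = scheme, mode = mode,
                     tau = if (mode == "regularized") tau else NULL,
                     sparsity = if (mode == "sparse") sparsity else NULL,
                     tol = tol, max_iter = max_iter, seed = seed)),
    class = "sgcca_fit"
  )
}

#' @export
print.sgcca_fit <- function(x, ...) {
  cat("SGCCA fit (", x$spec$mode, " mode, scheme = ", x$spec$scheme,
      ", design = ", x$spec$design$name, ")\n", sep = "")
  cat("  criterion:", format(utils::tail(x$crit, 1)), "after",
      x$iterations, "sweeps;",
      if (x$converged) "converged" else "NOT converged", "\n")
  for (nm in names(x$weights))
    cat("  block '", nm, "': ", sum(abs(x$weights[[nm]]) > 1e-12), "/",
        length(x$weights[[nm]]), " nonzero loadings\n", sep = "")
  invisible(x)
}

#' Block component scores
#'
#' Computes `y_j = X_j a_j` for each block from a fitted model, optionally
#' on new (test) data — the subject scores plotted against each other to
#' visualize cross-block structure.
#'
#' @param fit an `sgcca_fit`.
#' @param blocks named list of matrices with columns matching the fitted
#'   weights; defaults to returning the training components.
#' @return `n x J` matrix of component scores, one column per block.
#' @export
sgcca_components <- function(fit, blocks = NULL) {
  stopifnot(inherits(fit, "sgcca_fit"))
  if (is.null(blocks)) return(fit$components)
  out <- vapply(names(fit$weights), function(nm) {
    if (!nm %in% names(blocks))
      stop("block '", nm, "' missing from `blocks`", call. = FALSE)
    X <- blocks[[nm]]
    if (ncol(X) != length(fit$weights[[nm]]))
      stop("block '", nm, "' has ", ncol(X), " columns; fit expects ",
           length(fit$weights[[nm]]), call. = FALSE)
    as.vector(X %*% fit$weights[[nm]])
  }, numeric(nrow(blocks[[1L]])))
  colnames(out) <- names(fit$weights)
  out
}

#' Serialize an SGCCA fit to JSON
#' @param fit an `sgcca_fit`.
#' @param path file to write; if `NULL` the JSON string is returned.
#' @return `path` invisibly, or a JSON string.
#' @export
sgcca_to_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "sgcca_fit"))
  x <- list(weights = lapply(fit$weights, as.list),
            crit = fit$crit, converged = fit$converged,
            iterations = fit$iterations,
            design = list(name = fit$spec$design$name,
                          block_order = fit$spec$design$block_order,
                          C = as.data.frame(fit$spec$design$C)),
            scheme = fit$spec$scheme, mode = fit$spec$mode,
            tau = fit$spec$tau, sparsity = fit$spec$sparsity,
            seed = fit$spec$seed)
  if (is.null(path)) return(jsonlite::toJSON(x, digits = NA, auto_unbox = TRUE))
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Weight table for reporting
#' @param fit an `sgcca_fit`.
#' @return data.frame with columns `block`, `variable`, `loading`.
#' @export
sgcca_weight_table <- function(fit) {
  stopifnot(inherits(fit, "sgcca_fit"))
  do.call(rbind, lapply(names(fit$weights), function(nm) {
    data.frame(block = nm,
               variable = names(fit$weights[[nm]]) %||%
                 as.character(seq_along(fit$weights[[nm]])),
               loading = unname(fit$weights[[nm]]),
               stringsAsFactors = FALSE)
  }))
}
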