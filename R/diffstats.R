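#' Univariate differential screening with covariate adjustment
#'
#' For every variable in every block, fits an ordinary least-squares model
#' `variable ~ group + age + sex + smoking` and reports the group
#' coefficient with its two-sided t-test p-value. This is the gene-by-gene /
#' ROI-by-ROI baseline analysis that precedes the multivariate modelling.
#'
#' @param dataset a [multiblock_dataset()]; its `covariates` columns are all
#'   entered as nuisance terms.
#' @param adjust_m family size for the Benjamini-Hochberg adjustment;
#'   default the number of tests performed. May exceed it when some family
#'   members are not supplied.
#' @return A `differential_table`: data.frame with columns `variable`,
#'   `block`, `coef`, `raw_p`, `adj_p`, sorted ascending by `raw_p`, with
#'   attributes `family_size` and `method`.
#' @export
fit_group_models <- function(dataset, adjust_m = NULL) {
  stopifnot(inherits(dataset, "multiblock_dataset"))
  if (length(unique(dataset$phenotype)) < 2L)
    stop("both groups must be present (single-group data)", call. = FALSE)
  if (dataset$n <= 5L)
    stop("need n > 5 subjects", call. = FALSE)
  D <- cbind(group = dataset$phenotype,
             as.matrix(dataset$covariates))
  rows <- lapply(names(dataset$blocks), function(bl) {
    X <- dataset$blocks[[bl]]
    do.call(rbind, lapply(colnames(X), function(v) {
      fit <- stats::lm(X[, v] ~ D)
      cf <- summary(fit)$coefficients["Dgroup", ]
      data.frame(variable = v, block = bl, coef = unname(cf["Estimate"]),
                 raw_p = unname(cf["Pr(>|t|)"]), stringsAsFactors = FALSE)
    }))
  })
  tab <- do.call(rbind, rows)
  m <- adjust_m %||% nrow(tab)
  tab$adj_p <- adjust_bh(tab$raw_p, m = m)
  tab <- tab[order(tab$raw_p), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, family_size = m, method = "OLS group t-test + BH",
            class = c("differential_table", "data.frame"))
}

#' Benjamini-Hochberg step-up adjustment with explicit family size
#'
#' Step-up FDR adjustment: for ascending rank `i`,
#' `adj_i = min(1, min_{j >= i} m * p_j / j)`. When `m` exceeds the number
#' of supplied p-values, the missing family members are assumed to occupy
#' the largest ranks (the convention of [stats::p.adjust()] with `n = m`,
#' which backs this function).
#'
#' @param raw_p numeric vector of p-values in `[0, 1]`.
#' @param m family size, `>= length(raw_p)`.
#' @return Adjusted p-values in the input order.
#' @export
adjust_bh <- function(raw_p, m = length(raw_p)) {
  if (anyNA(raw_p) || any(raw_p < 0 | raw_p > 1))
    stop("raw p-values must lie in [0, 1]", call. = FALSE)
  if (!is_count(m) || m < length(raw_p))
    stop("family size m must be a count >= length(raw_p)", call. = FALSE)
  stats::p.adjust(raw_p, method = "BH", n = m)
}

#' Per-block MANCOVA
#'
#' Multivariate linear model of one block's variables on the group factor
#' plus the nuisance covariates; reports the multivariate statistic
#' (Pillai trace by default, Wilks lambda optionally), the approximate F and
#' its p-value for every model term. Refuses datasets where the variable
#' count leaves too few error degrees of freedom, rather than returning a
#' silently invalid fit.
#'
#' @param block numeric matrix of responses (`n x p`).
#' @param phenotype 0/1 group vector.
#' @param covariates covariate data.frame (age, sex, smoking).
#' @param statistic `"Pillai"` (default) or `"Wilks"`.
#' @return A `mancova_result` data.frame: `term`, `df`, `statistic`,
#'   `approx_f`, `num_df`, `den_df`, `p_value`.
#' @export
mancova <- function(block, phenotype, covariates,
                    statistic = c("Pillai", "Wilks")) {
  statistic <- match.arg(statistic)
  Y <- as.matrix(block)
  n <- nrow(Y)
  q <- ncol(as.data.frame(covariates))
  if (n <= ncol(Y) + q + 1)
    stop("MANCOVA infeasible: ", ncol(Y), " response variables with only ",
         n, " subjects exceeds the procedure's limit of validity",
         call. = FALSE)
  dat <- data.frame(group = factor(phenotype), as.data.frame(covariates))
  fml <- stats::as.formula(paste("Y ~", paste(names(dat), collapse = " + ")))
  fit <- stats::manova(fml, data = dat)
  sm <- summary(fit, test = statistic)$stats
  terms <- rownames(sm)[rownames(sm) != "Residuals"]
  out <- data.frame(
    term = terms,
    df = sm[terms, "Df"],
    statistic = sm[terms, statistic],
    approx_f = sm[terms, "approx F"],
    num_df = sm[terms, "num Df"],
    den_df = sm[terms, "den Df"],
    p_value = sm[terms, "Pr(>F)"],
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(out, statistic = statistic,
            class = c("mancova_result", "data.frame"))
}

#' Write a differential table as TSV
#' @param tab a `differential_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_differential_table <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
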