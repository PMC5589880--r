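#' Assemble an aligned multiblock dataset
#'
#' Bundles one or more subject-by-variable blocks (e.g. a gene-expression
#' block and an imaging block) with a binary phenotype and nuisance
#' covariates, enforcing that every table shares the same subjects in the
#' same order. This is the container every downstream stage (residualization,
#' differential screening, MANCOVA, multiblock canonical correlation,
#' cross-validation) consumes.
#'
#' @param blocks named list of numeric matrices, each `n x p_j`, with unique
#'   column names within each block. At least two blocks are required.
#' @param phenotype integer/numeric vector in `{0, 1}` (1 = patient),
#'   length `n`.
#' @param covariates data.frame with `n` rows; by convention columns
#'   `age` (years), `sex` (0/1) and `smoking` (0/1).
#' @param subject_ids character vector of unique subject identifiers,
#'   length `n`. Defaults to rownames of the first block or `S1..Sn`.
#'
#' @return An object of class `multiblock_dataset`: a list with elements
#'   `blocks`, `phenotype`, `covariates`, `subject_ids`, `n`.
#'
#' @details Missing values anywhere are rejected rather than imputed.
#' @export
multiblock_dataset <- function(blocks, phenotype, covariates,
                               subject_ids = NULL) {
  if (!is.list(blocks) || length(blocks) < 2L || is.null(names(blocks)) ||
      any(!nzchar(names(blocks))))
    stop("`blocks` must be a named list of at least two matrices",
         call. = FALSE)
  blocks <- lapply(blocks, function(b) {
    b <- as.matrix(b)
    storage.mode(b) <- "double"
    b
  })
  n <- nrow(blocks[[1L]])
  for (nm in names(blocks)) {
    b <- blocks[[nm]]
    if (nrow(b) != n)
      stop("block '", nm, "' has ", nrow(b), " rows; expected ", n,
           call. = FALSE)
    if (is.null(colnames(b)) || anyDuplicated(colnames(b)))
      stop("block '", nm, "' needs unique column names", call. = FALSE)
    if (anyNA(b))
      stop("block '", nm, "' contains missing values", call. = FALSE)
  }
  phenotype <- as.numeric(phenotype)
  if (length(phenotype) != n || anyNA(phenotype) ||
      !all(phenotype %in% c(0, 1)))
    stop("`phenotype` must be a length-", n, " vector of 0/1", call. = FALSE)
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != n || anyNA(covariates))
    stop("`covariates` must have ", n, " complete rows", call. = FALSE)
  if (is.null(subject_ids))
    subject_ids <- rownames(blocks[[1L]]) %||% paste0("S", seq_len(n))
  subject_ids <- as.character(subject_ids)
  if (length(subject_ids) != n || anyDuplicated(subject_ids))
    stop("`subject_ids` must be ", n, " unique identifiers", call. = FALSE)
  structure(
    list(blocks = blocks, phenotype = phenotype, covariates = covariates,
         subject_ids = subject_ids, n = n),
    class = "multiblock_dataset"
  )
}

#' @export
print.multiblock_dataset <- function(x, ...) {
  cat("Multiblock dataset:", x$n, "subjects,",
      sum(x$phenotype == 1), "patients /", sum(x$phenotype == 0),
      "controls\n")
  for (nm in names(x$blocks))
    cat("  block '", nm, "': ", ncol(x$blocks[[nm]]), " variables\n",
        sep = "")
  cat("  covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  invisible(x)
}

# Row-subset a dataset (used by the cross-validation folds).
subset_dataset <- function(dataset, idx) {
  multiblock_dataset(
    blocks = lapply(dataset$blocks, function(b) b[idx, , drop = FALSE]),
    phenotype = dataset$phenotype[idx],
    covariates = dataset$covariates[idx, , drop = FALSE],
    subject_ids = dataset$subject_ids[idx]
  )
}
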