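#' Read an aligned multiblock dataset from three TSV tables
#'
#' Expression and imaging tables are subject-by-variable with a header row
#' and the subject id in the first column; the phenotype table carries
#' `diagnosis` (0/1), `age`, `sex`, `smoking`. Subjects are aligned by id
#' across the three tables (row order is irrelevant); missing values,
#' duplicate ids, unaligned subject sets and non-binary diagnoses are
#' rejected.
#'
#' @param expression_path,imaging_path,phenotype_path TSV file paths.
#' @return A [multiblock_dataset()] with blocks `RNA` and `IMG`.
#' @export
read_dataset <- function(expression_path, imaging_path, phenotype_path) {
  read_tab <- function(path, what) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             check.names = FALSE)
    ids <- as.character(tab[[1L]])
    if (anyDuplicated(ids))
      stop("duplicate subject id(s) in ", what, " table: ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "),
           call. = FALSE)
    rownames(tab) <- ids
    tab[, -1L, drop = FALSE]
  }
  expr <- read_tab(expression_path, "expression")
  img <- read_tab(imaging_path, "imaging")
  pheno <- read_tab(phenotype_path, "phenotype")

  ids <- rownames(pheno)
  for (nm in c("expression", "imaging")) {
    other <- rownames(if (nm == "expression") expr else img)
    extra <- setdiff(other, ids)
    absent <- setdiff(ids, other)
    if (length(extra) || length(absent))
      stop("subject sets are not aligned; ", nm, " table ",
           if (length(absent)) paste0("is missing: ",
                                      paste(absent, collapse = ", ")) else "",
           if (length(extra)) paste0(" has extra: ",
                                     paste(extra, collapse = ", ")) else "",
           call. = FALSE)
  }
  ids <- sort(ids)
  expr <- as.matrix(expr[ids, , drop = FALSE])
  img <- as.matrix(img[ids, , drop = FALSE])
  pheno <- pheno[ids, , drop = FALSE]
  need <- c("diagnosis", "age", "sex", "smoking")
  if (!all(need %in% names(pheno)))
    stop("phenotype table must carry columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  if (!all(pheno$diagnosis %in% c(0, 1)))
    stop("diagnosis must be coded 0/1", call. = FALSE)
  multiblock_dataset(
    blocks = list(RNA = expr, IMG = img),
    phenotype = pheno$diagnosis,
    covariates = pheno[, c("age", "sex", "smoking")],
    subject_ids = ids
  )
}

#' Write a multiblock dataset as three TSV tables (+ truth sidecar)
#'
#' Inverse of [read_dataset()]: writes `expression.tsv`, `imaging.tsv`,
#' `phenotype.tsv` and, when the dataset carries planted synthetic truth,
#' a `truth.json` sidecar with the supports, latents and spec echo.
#'
#' @param dataset a [multiblock_dataset()].
#' @param dir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "multiblock_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, path) {
    utils::write.table(data.frame(subject = dataset$subject_ids, x,
                                  check.names = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  paths <- c(
    expression = wt(dataset$blocks$RNA, file.path(dir, "expression.tsv")),
    imaging = wt(dataset$blocks$IMG, file.path(dir, "imaging.tsv")),
    phenotype = wt(data.frame(diagnosis = dataset$phenotype,
                              dataset$covariates),
                   file.path(dir, "phenotype.tsv"))
  )
  truth <- attr(dataset, "truth")
  if (!is.null(truth)) {
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         digits = NA, auto_unbox = TRUE)
    paths <- c(paths, truth = file.path(dir, "truth.json"))
  }
  invisible(paths)
}

#' Run the full analysis pipeline
#'
#' Sequences the package's stages on one dataset: univariate differential
#' screening with BH adjustment, per-block MANCOVA, cross-validated design
#' comparison, fold-stability signatures under the best design, and
#' supervised/unsupervised component scores for scatter plotting. All
#' artifacts are written as TSV plus a JSON manifest; rerunning with the
#' same config and seed reproduces every table bit-identically.
#'
#' @param config named list or path to a YAML file with fields:
#'   `expression`/`imaging`/`phenotype` paths **or** `synthetic` (a list of
#'   [synthetic_spec()] arguments); `designs` (default all three named
#'   designs); `scheme`; `k`; `cv_seeds` (replicate seeds for the design
#'   comparison); `robust_min`; `bh_m` (BH family size); `seed` (mandatory);
#'   `out` (output directory); `residualize_in_fold`.
#' @return The output directory, invisibly; side effect: writes
#'   `differential_table.tsv`, `mancova.tsv`, `error_rates.tsv`,
#'   `signature_RNA.tsv`, `signature_IMG.tsv`, `components.tsv`,
#'   `run_manifest.json` under `config$out`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(config$seed)) stop("config$seed is mandatory", call. = FALSE)
  if (is.null(config$out)) stop("config$out is mandatory", call. = FALSE)
  out <- config$out
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  stage <- function(name, expr) {
    message("[", name, "] ...")
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  dataset <- stage("load", {
    if (!is.null(config$synthetic)) {
      spec_args <- config$synthetic
      spec_args$seed <- spec_args$seed %||% config$seed
      generate_multiblock(do.call(synthetic_spec, spec_args))
    } else {
      read_dataset(config$expression, config$imaging, config$phenotype)
    }
  })
  message("  dataset: n = ", dataset$n, "; blocks ",
          paste(sprintf("%s(%d)", names(dataset$blocks),
                        vapply(dataset$blocks, ncol, integer(1))),
                collapse = ", "))

  diff_tab <- stage("differential", {
    tab <- fit_group_models(dataset, adjust_m = config$bh_m)
    write_differential_table(tab, file.path(out, "differential_table.tsv"))
    tab
  })

  manc <- stage("mancova", {
    res <- lapply(names(dataset$blocks), function(nm) {
      r <- tryCatch(
        mancova(dataset$blocks[[nm]], dataset$phenotype, dataset$covariates),
        error = function(e) {
          warning("MANCOVA on block '", nm, "': ", conditionMessage(e),
                  call. = FALSE)
          NULL
        })
      if (is.null(r)) return(NULL)
      cbind(block = nm, as.data.frame(r))
    })
    res <- do.call(rbind, res)
    if (!is.null(res))
      utils::write.table(res, file.path(out, "mancova.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    res
  })

  designs <- config$designs %||% c("sequential", "complete",
                                   "reversed_sequential")
  cv_seeds <- config$cv_seeds %||% config$seed
  cmp <- stage("compare-designs", {
    cmp <- compare_designs(
      dataset, as.list(designs), seeds = cv_seeds,
      scheme = config$scheme %||% "centroid",
      k = config$k %||% 5L,
      robust_min = config$robust_min %||% 3L,
      residualize_in_fold = config$residualize_in_fold %||% TRUE)
    write_cv_report(cmp, out)
    cmp
  })

  stage("signatures", {
    best_rep <- cmp$reports[[cmp$best]][[1L]]
    for (nm in names(best_rep$signature))
      utils::write.table(best_rep$signature[[nm]],
                         file.path(out, paste0("signature_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  })

  stage("components", {
    pp <- preprocess_dataset(dataset)$dataset
    dsgn_sup <- build_design(if (cmp$best %in% c("sequential", "complete",
                                                 "reversed_sequential"))
      cmp$best else "sequential")
    blocks_sup <- c(pp$blocks, list(DX = dx_block(dataset$phenotype)))
    fit_sup <- sgcca_fit(blocks_sup, dsgn_sup,
                         scheme = config$scheme %||% "centroid",
                         seed = config$seed)
    dsgn_uns <- build_design("custom", block_order = c("RNA", "IMG"),
                             C = rbind(c(0, 1), c(1, 0)))
    fit_uns <- sgcca_fit(pp$blocks, dsgn_uns,
                         scheme = config$scheme %||% "centroid",
                         seed = config$seed)
    comp <- data.frame(subject = dataset$subject_ids,
                       diagnosis = dataset$phenotype,
                       rna_supervised = fit_sup$components[, "RNA"],
                       img_supervised = fit_sup$components[, "IMG"],
                       rna_unsupervised = fit_uns$components[, "RNA"],
                       img_unsupervised = fit_uns$components[, "IMG"])
    utils::write.table(comp, file.path(out, "components.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  })

  manifest <- list(
    config = config[setdiff(names(config), "out")],
    seed = config$seed,
    best_design = cmp$best,
    n_subjects = dataset$n,
    family_size = attr(diff_tab, "family_size"),
    mancova_blocks = if (is.null(manc)) character(0) else unique(manc$block),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("blocklink")),
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(out, "run_manifest.json"),
                       digits = NA, auto_unbox = TRUE, null = "null")
  invisible(out)
}
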