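#' Expression-intensity windows for reference-gene assignment
#'
#' The default windows partition the Ct axis into five expression-intensity
#' bands, each served by one reference gene of comparable abundance:
#' `Ct < 22`, `22 <= Ct < 24`, `24 <= Ct < 25.5`, `25.5 <= Ct < 28.5`, and
#' `Ct >= 30`. Boundaries are half-open `[low, high)`; the band between 28.5
#' and 30 is deliberately not covered, and targets falling there (or exactly
#' on an uncovered boundary) raise an error rather than being snapped to a
#' neighbour.
#'
#' @param bounds optional list of `c(low, high)` pairs (use `-Inf`/`Inf` for
#'   open ends); must be non-overlapping and ordered.
#' @return data.frame with columns `window`, `low`, `high`.
#' @export
ct_windows <- function(bounds = NULL) {
  if (is.null(bounds))
    bounds <- list(c(-Inf, 22), c(22, 24), c(24, 25.5), c(25.5, 28.5),
                   c(30, Inf))
  low <- vapply(bounds, `[`, numeric(1), 1)
  high <- vapply(bounds, `[`, numeric(1), 2)
  if (any(low >= high) || is.unsorted(low) ||
      any(low[-1] < high[-length(high)]))
    stop("windows must be ordered and non-overlapping", call. = FALSE)
  data.frame(window = paste0("W", seq_along(bounds)), low = low, high = high,
             stringsAsFactors = FALSE)
}

#' Assign a reference gene to each target by expression-intensity window
#'
#' Each target gene is mapped to the reference gene serving the window that
#' contains the target's cross-sample mean Ct. A proximity warning is raised
#' when the mean Ct gap between target and assigned reference is 2 cycles or
#' more (the quantification is designed for proximal levels).
#'
#' @param ct long-format Ct table: columns `sample`, `gene`, `replicate`,
#'   `ct`, `role` (`"target"`/`"reference"`), as produced by
#'   [generate_qpcr()] or [read_ct_table()].
#' @param reference_map named character vector mapping window names (`"W1"`
#'   ... per [ct_windows()]) to reference gene names present in `ct`.
#' @param windows window table from [ct_windows()].
#' @return named character vector: target gene -> reference gene.
#' @export
assign_reference <- function(ct, reference_map, windows = ct_windows()) {
  stopifnot(all(c("sample", "gene", "ct", "role") %in% names(ct)))
  if (any(ct$ct <= 0)) stop("Ct values must be positive", call. = FALSE)
  refs <- unique(ct$gene[ct$role == "reference"])
  missing_refs <- setdiff(reference_map, refs)
  if (length(missing_refs))
    stop("reference gene(s) absent from the table: ",
         paste(missing_refs, collapse = ", "), call. = FALSE)
  targets <- unique(ct$gene[ct$role == "target"])
  mean_ct <- vapply(targets, function(g) mean(ct$ct[ct$gene == g]),
                    numeric(1))
  out <- character(length(targets))
  names(out) <- targets
  for (g in targets) {
    w <- windows$window[windows$low <= mean_ct[g] & mean_ct[g] < windows$high]
    if (length(w) != 1L)
      stop("target '", g, "' (mean Ct ", round(mean_ct[g], 2),
           ") falls in a gap between intensity windows; no reference ",
           "assignable", call. = FALSE)
    if (!w %in% names(reference_map))
      stop("no reference gene configured for window ", w, call. = FALSE)
    out[g] <- reference_map[[w]]
    ref_mean <- mean(ct$ct[ct$gene == out[g]])
    if (abs(mean_ct[g] - ref_mean) >= 2)
      warning("target '", g, "' and reference '", out[g],
              "' differ by >= 2 mean Ct; quantification is not proximal",
              call. = FALSE)
  }
  out
}

# Triplicate aggregation: mean Ct after dropping a single replicate deviating
# more than 0.5 Ct from the triplicate median.
aggregate_replicates <- function(cts, outlier_ct = 0.5) {
  if (length(cts) < 2L)
    stop("need at least 2 replicates per (sample, gene)", call. = FALSE)
  if (length(cts) >= 3L) {
    dev <- abs(cts - stats::median(cts))
    worst <- which.max(dev)
    if (dev[worst] > outlier_ct) cts <- cts[-worst]
  }
  mean(cts)
}

#' Relative quantification by the 2^-ddCt method
#'
#' Per sample and target gene: `dCt = mean target Ct - mean reference Ct`
#' (reference chosen by [assign_reference()]; optionally the average of two
#' references), `ddCt = dCt - mean(dCt over the calibrator samples)`, and
#' `RQ = 2^-ddCt`. The calibrator is conventionally the set of control
#' samples, so the geometric mean RQ over calibrator samples is 1 for every
#' gene. Replicates are averaged after dropping a single replicate deviating
#' more than 0.5 Ct from the triplicate median.
#'
#' @param ct long-format Ct table (see [assign_reference()]).
#' @param reference named character vector target -> reference gene (or
#'   a list target -> up to two reference genes).
#' @param calibrator_samples character vector of sample ids forming the
#'   calibrator group (non-empty, present in `ct`).
#' @return An `rq_table`: data.frame `sample x gene` in long format with
#'   columns `sample`, `gene`, `dct`, `ddct`, `rq`, plus attributes
#'   `reference` and `calibrator`.
#' @export
relative_quantity <- function(ct, reference, calibrator_samples) {
  stopifnot(all(c("sample", "gene", "ct") %in% names(ct)))
  calibrator_samples <- as.character(calibrator_samples)
  if (!length(calibrator_samples))
    stop("calibrator sample set is empty", call. = FALSE)
  if (!all(calibrator_samples %in% ct$sample))
    stop("calibrator sample(s) not in the table: ",
         paste(setdiff(calibrator_samples, ct$sample), collapse = ", "),
         call. = FALSE)
  reference <- as.list(reference)
  samples <- unique(ct$sample)
  # mean Ct per (sample, gene) with outlier-dropped triplicates
  agg <- new.env(parent = emptyenv())
  mean_ct <- function(s, g) {
    key <- paste0(s, "\r", g)
    if (!is.null(agg[[key]])) return(agg[[key]])
    cts <- ct$ct[ct$sample == s & ct$gene == g]
    if (!length(cts))
      stop("missing Ct for sample '", s, "', gene '", g, "'", call. = FALSE)
    agg[[key]] <- aggregate_replicates(cts)
    agg[[key]]
  }
  rows <- list()
  for (g in names(reference)) {
    refs <- reference[[g]]
    if (length(refs) < 1L || length(refs) > 2L)
      stop("gene '", g, "' must map to one or two reference genes",
           call. = FALSE)
    dct <- vapply(samples, function(s) {
      ref_ct <- mean(vapply(refs, function(r) mean_ct(s, r), numeric(1)))
      mean_ct(s, g) - ref_ct
    }, numeric(1))
    cal <- mean(dct[samples %in% calibrator_samples])
    ddct <- dct - cal
    rows[[g]] <- data.frame(sample = samples, gene = g, dct = unname(dct),
                            ddct = unname(ddct), rq = 2^(-unname(ddct)),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, reference = reference, calibrator = calibrator_samples,
            class = c("rq_table", "data.frame"))
}

#' Pivot an RQ table into a samples-by-genes expression matrix
#' @param rq an `rq_table` from [relative_quantity()].
#' @return numeric matrix, samples in rows, genes in columns.
#' @export
rq_matrix <- function(rq) {
  stopifnot(inherits(rq, "rq_table"))
  samples <- unique(rq$sample)
  genes <- unique(rq$gene)
  m <- matrix(NA_real_, length(samples), length(genes),
              dimnames = list(samples, genes))
  m[cbind(match(rq$sample, samples), match(rq$gene, genes))] <- rq$rq
  m
}

#' Read / write long-format Ct tables
#' @param path TSV with columns `sample`, `gene`, `replicate`, `ct` and
#'   optionally `role`.
#' @return data.frame suitable for [assign_reference()].
#' @export
read_ct_table <- function(path) {
  ct <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "gene", "replicate", "ct")
  if (!all(need %in% names(ct)))
    stop("Ct table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  ct
}

#' @rdname read_ct_table
#' @param ct a Ct table data.frame.
#' @export
write_ct_table <- function(ct, path) {
  utils::write.table(ct, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
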