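#' Specify a synthetic multiblock study
#'
#' Defines the generative model for a two-block (gene expression + imaging)
#' case/control study with a planted latent causal chain. Each block carries
#' a small set of signal variables loading on a unit-variance block latent;
#' the latents are tied to the binary diagnosis according to the chosen
#' causal variant:
#'
#' * `sequential`: diagnosis -> imaging latent -> RNA latent (the classical
#'   imaging-genetics hypothesis, with brain activity intermediate),
#' * `reversed_sequential`: diagnosis -> RNA latent -> imaging latent,
#' * `complete`: diagnosis -> one shared latent feeding both blocks,
#' * `null`: no links anywhere (pure noise).
#'
#' The chain is linear-Gaussian with diagnosis entering as a +/-1 coded
#' exogenous variable. `beta_dx_img` is the path coefficient of the first
#' hop of the chain (diagnosis to the proximal block latent) and
#' `beta_img_rna` the second hop (proximal to distal latent); under the
#' reversed variant the proximal block is RNA, so the two coefficients apply
#' positionally along the chain. Block latents are rescaled to unit variance
#' after each hop, so a signal column `b * latent + N(0, noise_sd^2)` has
#' population correlation `b / sqrt(b^2 + noise_sd^2)` with its latent.
#'
#' @param n_case,n_control group sizes (`n_case + n_control >= 4`).
#' @param p_rna,p_img block widths (defaults 33 genes, 16 ROIs).
#' @param support_rna,support_img integer indices of the signal columns in
#'   each block.
#' @param beta_dx_img,beta_img_rna unitless path coefficients of the latent
#'   chain (first and second hop).
#' @param noise_sd standard deviation of the per-column Gaussian noise
#'   (also the scale of non-signal columns); must be positive.
#' @param covariate_effects named list/vector of per-covariate additive
#'   coefficients (`age`, `sex`, `smoking`) applied to every column of both
#'   blocks; default none.
#' @param causal_variant one of `"sequential"`, `"complete"`,
#'   `"reversed_sequential"`, `"null"`.
#' @param age_range age is drawn uniformly over this range (years).
#' @param seed integer seed; identical spec + seed gives bit-identical data.
#'
#' @return An object of class `synthetic_spec`.
#' @seealso [generate_multiblock()]
#' @export
synthetic_spec <- function(n_case, n_control, p_rna = 33, p_img = 16,
                           support_rna = seq_len(min(5, p_rna)),
                           support_img = seq_len(min(4, p_img)),
                           beta_dx_img = 1, beta_img_rna = 1,
                           noise_sd = 1, covariate_effects = NULL,
                           causal_variant = c("sequential", "complete",
                                              "reversed_sequential", "null"),
                           age_range = c(18, 65), seed = 1) {
  causal_variant <- match.arg(causal_variant)
  stopifnot(is_count(n_case), is_count(n_control), is_count(p_rna),
            is_count(p_img))
  if (n_case + n_control < 4)
    stop("need n_case + n_control >= 4", call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd <= 0)
    stop("`noise_sd` must be > 0", call. = FALSE)
  support_rna <- as.integer(support_rna)
  support_img <- as.integer(support_img)
  if (length(support_rna) && (min(support_rna) < 1 || max(support_rna) > p_rna))
    stop("`support_rna` indices outside 1..", p_rna, " (RNA block)",
         call. = FALSE)
  if (length(support_img) && (min(support_img) < 1 || max(support_img) > p_img))
    stop("`support_img` indices outside 1..", p_img, " (IMG block)",
         call. = FALSE)
  ce <- list(age = 0, sex = 0, smoking = 0)
  if (!is.null(covariate_effects)) {
    covariate_effects <- as.list(covariate_effects)
    bad <- setdiff(names(covariate_effects), names(ce))
    if (length(bad))
      stop("unknown covariate effect(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    ce[names(covariate_effects)] <- covariate_effects
  }
  structure(
    list(n_case = as.integer(n_case), n_control = as.integer(n_control),
         p_rna = as.integer(p_rna), p_img = as.integer(p_img),
         support_rna = support_rna, support_img = support_img,
         beta_dx_img = beta_dx_img, beta_img_rna = beta_img_rna,
         noise_sd = noise_sd, covariate_effects = ce,
         causal_variant = causal_variant, age_range = age_range,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic multiblock dataset with planted causal structure
#'
#' Realizes the latent chain described in [synthetic_spec()]: signal columns
#' equal the block's incoming path coefficient times the block latent plus
#' Gaussian noise, non-signal columns are pure noise, and configured
#' covariate effects are added to every column. The planted truth (supports,
#' latents, spec echo) is attached as `attr(, "truth")` for recovery tests
#' and is written as a JSON sidecar by [write_dataset()].
#'
#' @param spec a [synthetic_spec()].
#' @return A [multiblock_dataset()] with blocks `RNA` and `IMG`, plus a
#'   `truth` attribute (list with `support_rna`, `support_img`,
#'   `latent_rna`, `latent_img`, `diagnosis_pm1`, `spec`).
#' @export
generate_multiblock <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_case + spec$n_control
  with_seed(spec$seed, {
    dx01 <- c(rep(1, spec$n_case), rep(0, spec$n_control))
    d <- 2 * dx01 - 1  # +/-1 coding, exogenous
    age <- stats::runif(n, spec$age_range[1], spec$age_range[2])
    sex <- stats::rbinom(n, 1, 0.5)
    smoking <- stats::rbinom(n, 1, 0.5)

    unitize <- function(b, x) (b * x + stats::rnorm(n)) / sqrt(b^2 + 1)
    b1 <- spec$beta_dx_img
    b2 <- spec$beta_img_rna
    # Block latents and per-column loadings by causal variant
    if (spec$causal_variant == "sequential") {
      L_img <- unitize(b1, d)
      L_rna <- unitize(b2, L_img)
      load_img <- b1; load_rna <- b2
    } else if (spec$causal_variant == "reversed_sequential") {
      L_rna <- unitize(b1, d)
      L_img <- unitize(b2, L_rna)
      load_rna <- b1; load_img <- b2
    } else if (spec$causal_variant == "complete") {
      L <- unitize(b1, d)
      L_img <- L; L_rna <- L
      load_img <- b1; load_rna <- b1
    } else { # null
      L_img <- stats::rnorm(n)
      L_rna <- stats::rnorm(n)
      load_img <- 0; load_rna <- 0
    }

    make_block <- function(p, support, latent, loading, prefix) {
      X <- matrix(stats::rnorm(n * p, sd = spec$noise_sd), n, p)
      if (length(support))
        X[, support] <- X[, support] + loading * latent
      colnames(X) <- paste0(prefix, seq_len(p))
      X
    }
    rna <- make_block(spec$p_rna, spec$support_rna, L_rna, load_rna, "gene")
    img <- make_block(spec$p_img, spec$support_img, L_img, load_img, "roi")

    eff <- spec$covariate_effects
    contam <- eff$age * (age - mean(spec$age_range)) +
      eff$sex * sex + eff$smoking * smoking
    rna <- rna + contam
    img <- img + contam

    ids <- sprintf("S%03d", seq_len(n))
    rownames(rna) <- rownames(img) <- ids
    ds <- multiblock_dataset(
      blocks = list(RNA = rna, IMG = img),
      phenotype = dx01,
      covariates = data.frame(age = age, sex = sex, smoking = smoking),
      subject_ids = ids
    )
    attr(ds, "truth") <- list(
      support_rna = spec$support_rna, support_img = spec$support_img,
      latent_rna = L_rna, latent_img = L_img, diagnosis_pm1 = d,
      spec = unclass(spec)
    )
    ds
  })
}

#' Specify a synthetic qPCR plate
#'
#' Fixture generator for the relative-quantification module: a plate of Ct
#' triplicates for target genes falling in known expression-intensity
#' windows, plus one reference gene per window. Gene offsets are expressed
#' on the Ct scale (cycles; negative = higher expression, since Ct is
#' -log2 of template abundance) and are applied to the non-calibrator
#' (case) samples only, so the control samples define the calibrator
#' baseline.
#'
#' @param n_case,n_control sample counts; controls are the calibrator group.
#' @param gene_base_ct named numeric vector: per-target baseline mean Ct
#'   (places the gene in an intensity window).
#' @param ct_offsets named numeric vector (same names): Ct-scale shift of
#'   case samples relative to controls; `-1` means one cycle earlier, i.e.
#'   a two-fold expression increase.
#' @param reference_cts named numeric vector: per-reference-gene mean Ct
#'   (one reference per window, stable across samples).
#' @param replicate_sd technical replicate noise in Ct units (`>= 0`).
#' @param seed integer seed.
#' @return An object of class `qpcr_synthetic_spec`.
#' @export
qpcr_synthetic_spec <- function(n_case, n_control, gene_base_ct, ct_offsets,
                                reference_cts, replicate_sd = 0.1, seed = 1) {
  stopifnot(is_count(n_case), is_count(n_control))
  if (!is.numeric(replicate_sd) || replicate_sd < 0)
    stop("`replicate_sd` must be >= 0", call. = FALSE)
  if (is.null(names(gene_base_ct)) || is.null(names(reference_cts)))
    stop("`gene_base_ct` and `reference_cts` must be named", call. = FALSE)
  if (!setequal(names(gene_base_ct), names(ct_offsets)))
    stop("every gene must map to exactly one offset", call. = FALSE)
  ct_offsets <- ct_offsets[names(gene_base_ct)]
  structure(
    list(n_case = as.integer(n_case), n_control = as.integer(n_control),
         gene_base_ct = gene_base_ct, ct_offsets = ct_offsets,
         reference_cts = reference_cts, replicate_sd = replicate_sd,
         seed = as.integer(seed)),
    class = "qpcr_synthetic_spec"
  )
}

#' Generate a raw Ct triplicate table
#'
#' @param spec a [qpcr_synthetic_spec()].
#' @return A long-format data.frame with columns `sample`, `gene`,
#'   `replicate`, `ct`, `role` (`"target"`/`"reference"`) and `group`
#'   (`"case"`/`"control"`); seed-deterministic.
#' @export
generate_qpcr <- function(spec) {
  stopifnot(inherits(spec, "qpcr_synthetic_spec"))
  n <- spec$n_case + spec$n_control
  samples <- sprintf("P%03d", seq_len(n))
  group <- c(rep("case", spec$n_case), rep("control", spec$n_control))
  genes <- c(names(spec$gene_base_ct), names(spec$reference_cts))
  role <- c(rep("target", length(spec$gene_base_ct)),
            rep("reference", length(spec$reference_cts)))
  base <- c(spec$gene_base_ct, spec$reference_cts)
  with_seed(spec$seed, {
    grid <- expand.grid(replicate = 1:3, gene = genes, sample = samples,
                        stringsAsFactors = FALSE)
    gi <- match(grid$gene, genes)
    si <- match(grid$sample, samples)
    mu <- base[gi] +
      ifelse(role[gi] == "target" & group[si] == "case",
             spec$ct_offsets[grid$gene], 0)
    ct <- mu + stats::rnorm(nrow(grid), sd = spec$replicate_sd)
    data.frame(sample = grid$sample, gene = grid$gene,
               replicate = grid$replicate, ct = as.numeric(ct),
               role = role[gi], group = group[si],
               stringsAsFactors = FALSE)
  })
}
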