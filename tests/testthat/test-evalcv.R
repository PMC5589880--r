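# LDA, cross-validation machinery, stability selection, design comparison.

test_that("LDA weight vector matches the closed form and MASS::lda", {
  # 2-D toy with hand-specified class structure
  set.seed(71)
  n0 <- 60; n1 <- 40
  S_true <- rbind(c(1, 0.4), c(0.4, 2))
  L <- chol(S_true)
  x0 <- matrix(rnorm(n0 * 2), n0) %*% L
  x1 <- sweep(matrix(rnorm(n1 * 2), n1) %*% L, 2, c(1.5, -1), `+`)
  scores <- rbind(x0, x1)
  labels <- rep(c(0, 1), c(n0, n1))
  m <- lda_fit(scores, labels)
  mu0 <- colMeans(x0); mu1 <- colMeans(x1)
  Sp <- ((n0 - 1) * cov(x0) + (n1 - 1) * cov(x1)) / (n0 + n1 - 2)
  expect_equal(unname(m$weights), unname(solve(Sp, mu1 - mu0)),
               tolerance = 1e-10)
  # independent cross-check: same predictions as MASS::lda
  ref <- MASS::lda(scores, grouping = labels)
  pred_ref <- as.character(predict(ref, scores)$class)
  expect_identical(lda_predict(m, scores), pred_ref)
})

test_that("LDA degenerate cases follow the documented contracts", {
  set.seed(73)
  # two spherical clusters 10 sds apart: zero training error
  x <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40) + 10, 20))
  y <- rep(c("a", "b"), each = 20)
  m <- lda_fit(x, y)
  expect_identical(lda_predict(m, x), y)
  # identical class means: collapse to the larger-prior class
  x2 <- matrix(rnorm(90 * 2), 90)
  y2 <- rep(c(0, 1), c(30, 60))
  m2 <- lda_fit(x2, y2)
  pred <- lda_predict(m2, matrix(0, 1, 2))
  expect_identical(pred, "1")
  # singular pooled covariance triggers a recorded ridge
  x3 <- cbind(c(1, 1, 2, 2, 3, 3), c(2, 2, 4, 4, 6, 6))  # collinear
  expect_message(m3 <- lda_fit(x3, rep(c(0, 1), 3)), "ridge")
  expect_gt(m3$ridge, 0)
  expect_error(lda_fit(x2, rep(0, 90)), "both classes")
})

test_that("folds partition subjects and are stratified and reproducible", {
  ds <- make_signal_dataset(n_case = 21, n_control = 24, seed = 8)
  cv <- cross_validate(ds, build_design("sequential"), k = 5, seed = 42)
  expect_identical(cv$k, 5L)
  test_sets <- lapply(cv$folds, `[[`, "test_idx")
  expect_identical(sort(unlist(test_sets)), 1:45)
  expect_identical(anyDuplicated(unlist(test_sets)), 0L)
  # each training split saw both classes
  for (fd in cv$folds)
    expect_identical(sort(unique(ds$phenotype[fd$train_idx])), c(0, 1))
  # reproducibility at fixed seed
  cv2 <- cross_validate(ds, build_design("sequential"), k = 5, seed = 42)
  expect_identical(cv$error_rates, cv2$error_rates)
  expect_identical(cv$signature, cv2$signature)
})

test_that("stability summary reproduces the published aggregation rows", {
  tab <- stability_summary(t(published_loadings))
  s100 <- tab[tab$variable == "S100A10", ]
  expect_equal(round(s100$meanf, 2), 0.40)
  expect_identical(s100$occurrence, 4L)
  expect_true(s100$robust)
  stg <- tab[tab$variable == "right_STG", ]
  expect_equal(round(stg$meanf, 2), 0.57)
  expect_identical(stg$occurrence, 5L)
  mtm <- tab[tab$variable == "MTMR6", ]
  expect_equal(mtm$meanf, 0.35, tolerance = 1e-12)
  expect_identical(mtm$occurrence, 4L)
  # all-zero loadings: mean 0, occurrence 0, not robust
  z <- stability_summary(matrix(0, 5, 2,
                                dimnames = list(NULL, c("u", "v"))))
  expect_equal(z$meanf, c(0, 0))
  expect_identical(z$occurrence, c(0L, 0L))
  expect_false(any(z$robust))
  # occurrence-3 variables count as robust at the default threshold
  three <- stability_summary(rbind(c(0.3), c(0.2), c(0.1), c(0), c(0)))
  expect_true(three$robust)
})

test_that("Meanf recomputed from stored fold weights satisfies the identity", {
  ds <- make_signal_dataset(seed = 9)
  cv <- cross_validate(ds, build_design("sequential"), seed = 3)
  for (nm in c("RNA", "IMG")) {
    L <- do.call(rbind, lapply(cv$folds, function(fd)
      abs(fd$fit$weights[[nm]])))
    tab <- cv$signature[[nm]]
    expect_equal(tab$meanf[match(colnames(L), tab$variable)],
                 unname(colMeans(L)), tolerance = 1e-12)
    expect_true(all(tab$occurrence >= 0 & tab$occurrence <= cv$k))
    expect_true(all(tab$meanf >= 0))
  }
  expect_true(all(cv$error_rates >= 0 & cv$error_rates <= 1))
})

test_that("corrupting a fold's test rows never changes its fitted weights", {
  ds <- make_signal_dataset(n_case = 20, n_control = 20, seed = 10)
  cv <- cross_validate(ds, build_design("sequential"), k = 2, seed = 11)
  test1 <- cv$folds[[1]]$test_idx
  ds2 <- ds
  ds2$blocks$RNA[test1, ] <- 50 * matrix(rnorm(length(test1) *
                                                 ncol(ds$blocks$RNA)),
                                         length(test1))
  ds2$blocks$IMG[test1, ] <- -99 + matrix(rnorm(length(test1) *
                                                  ncol(ds$blocks$IMG)),
                                          length(test1))
  cv2 <- cross_validate(ds2, build_design("sequential"), k = 2, seed = 11)
  expect_identical(cv2$folds[[1]]$test_idx, test1)
  expect_equal(cv2$folds[[1]]$fit$weights, cv$folds[[1]]$fit$weights,
               tolerance = 1e-12)
  expect_identical(cv2$folds[[1]]$sparsity, cv$folds[[1]]$sparsity)
})

test_that("label permutation drives the error estimate to chance", {
  errs <- vapply(1:6, function(s) {
    ds <- make_signal_dataset(n_case = 30, n_control = 30, seed = 300 + s)
    perm <- blocklink:::with_seed(s, sample(ds$n))
    ds$phenotype <- ds$phenotype[perm]
    mean(cross_validate(ds, build_design("sequential"), seed = s,
                        k = 4)$error_rates)
  }, numeric(1))
  expect_gte(mean(errs), 0.35)
  expect_lte(mean(errs), 0.65)
})

test_that("design comparison is deterministic and degenerates gracefully", {
  ds <- make_signal_dataset(n_case = 20, n_control = 20, seed = 16)
  cmp <- compare_designs(ds, list("sequential", "sequential"), seeds = 5,
                         k = 3)
  # identical design twice with the same seed: identical distributions
  expect_identical(nrow(cmp$errors), 6L)
  expect_identical(cmp$errors$error[1:3], cmp$errors$error[4:6])
  one <- compare_designs(ds, list("complete"), seeds = 5, k = 3)
  expect_identical(sort(unique(one$errors$design)), "complete")
  expect_identical(one$best, "complete")
  expect_identical(
    one$errors$error,
    cross_validate(ds, build_design("complete"), seed = 5, k = 3)$error_rates)
})

test_that("strong sequential signal yields low error and support recovery", {
  ds <- make_signal_dataset(n_case = 40, n_control = 40, seed = 18)
  cv <- cross_validate(ds, build_design("sequential"), seed = 21)
  expect_lte(mean(cv$error_rates), 0.25)
  truth <- attr(ds, "truth")
  sig <- cv$signature$IMG
  occ <- sig$occurrence[match(paste0("roi", truth$support_img),
                              sig$variable)]
  expect_gte(stats::median(occ), 4)
})
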