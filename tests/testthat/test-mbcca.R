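# SGCCA core: designs, criterion, projection, fit oracles, invariants.

test_that("named designs encode the three causal hypotheses", {
  expect_equal(unname(build_design("sequential")$C),
               rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
  expect_equal(unname(build_design("complete")$C),
               rbind(c(0, 1, 1), c(1, 0, 1), c(1, 1, 0)))
  expect_equal(unname(build_design("reversed_sequential")$C),
               rbind(c(0, 1, 1), c(1, 0, 0), c(1, 0, 0)))
  expect_error(build_design("circular"), "sequential")
  expect_error(build_design("custom", c("A", "B"),
                            C = rbind(c(0, 0), c(0, 0))), "connection")
  expect_error(build_design("custom", c("A", "B", "C"),
                            C = rbind(c(0, 1, 0), c(1, 0, 0), c(0, 0, 0))),
               "not connected")
})

test_that("criterion matches direct arithmetic on a fixed toy", {
  X1 <- matrix(c(1, 2, 3, 4, 5,
                 2, 1, 4, 3, 5), 5, 2)
  X2 <- matrix(c(5, 3, 4, 1, 2), 5, 1)
  a1 <- c(0.6, 0.8); a2 <- 1
  C <- rbind(c(0, 1), c(1, 0))
  y1 <- X1 %*% a1; y2 <- X2 %*% a2
  cov12 <- sum((y1 - mean(y1)) * (y2 - mean(y2))) / 4
  expect_equal(sgcca_criterion(list(X1, X2), list(a1, a2), C, "horst"),
               2 * cov12, tolerance = 1e-12)
  expect_equal(sgcca_criterion(list(X1, X2), list(a1, a2), C, "factorial"),
               2 * cov12^2, tolerance = 1e-12)
  expect_equal(sgcca_criterion(list(X1, X2), list(a1, a2), C, "centroid"),
               2 * abs(cov12), tolerance = 1e-12)
  # all-zero design gives 0; identical unit-variance blocks give 2
  expect_equal(sgcca_criterion(list(X1, X2), list(a1, a2),
                               matrix(0, 2, 2), "horst"), 0)
  z <- matrix(scale(rnorm(10)), ncol = 1)
  expect_equal(sgcca_criterion(list(z, z), list(1, 1), C, "horst"), 2,
               tolerance = 1e-12)
})

test_that("project_l1_l2 solves the constrained direction problem", {
  # vacuous L1 constraint: plain normalization
  v <- c(3, -1, 2)
  expect_equal(project_l1_l2(v, sqrt(3)), v / sqrt(sum(v^2)),
               tolerance = 1e-12)
  # tightest bound: signed one-hot at the largest magnitude
  expect_equal(project_l1_l2(c(3, -1), 1), c(1, 0))
  expect_equal(project_l1_l2(c(1, -4), 1), c(0, -1))
  # documented toy: both constraints active
  w <- project_l1_l2(c(3, 1), 1.2)
  expect_equal(sum(w^2), 1, tolerance = 1e-10)
  expect_equal(sum(abs(w)), 1.2, tolerance = 1e-6)
  expect_true(all(w >= 0) && w[1] > w[2])
  expect_error(project_l1_l2(c(0, 0), 1.5), "all-zero")
})

test_that("project_l1_l2 agrees with a dense grid search + KKT check", {
  set.seed(29)
  for (rep in 1:100) {
    p <- sample(2:10, 1)
    v <- rnorm(p)
    bound <- runif(1, 1, sqrt(p))
    w <- project_l1_l2(v, bound)
    expect_lte(sum(w^2), 1 + 1e-8)
    expect_lte(sum(abs(w)), bound + 1e-6)
    # oracle: densely scan thresholds, keep the feasible maximizer of v'w
    lams <- seq(0, max(abs(v)) * 0.999, length.out = 4000)
    best <- -Inf
    for (l in lams) {
      s <- sign(v) * pmax(abs(v) - l, 0)
      if (all(s == 0)) next
      s <- s / sqrt(sum(s^2))
      if (sum(abs(s)) <= bound + 1e-9) best <- max(best, sum(v * s))
    }
    expect_gte(sum(v * w), best - 1e-4)
    # KKT: signs follow v on the support
    on <- which(w != 0)
    expect_true(all(sign(w[on]) == sign(v[on])))
  }
})

test_that("two-block tau=1 fit matches the leading singular pair", {
  d <- two_block_design()
  for (s in 1:20) {
    b <- make_random_blocks(seed = 100 + s)
    fit <- sgcca_fit(b, d, scheme = "horst", tau = 1, seed = s,
                     tol = 1e-14, max_iter = 5000)
    sv <- svd(crossprod(b$A, b$B) / (nrow(b$A) - 1))
    expect_lt(max(abs(abs(fit$weights$A) - abs(sv$u[, 1]))), 1e-6)
    expect_lt(max(abs(abs(fit$weights$B) - abs(sv$v[, 1]))), 1e-6)
    expect_equal(utils::tail(fit$crit, 1), 2 * sv$d[1], tolerance = 1e-6)
  }
})

test_that("criterion trace is nondecreasing across seeds/designs/schemes", {
  ds <- make_signal_dataset(seed = 12)
  pp <- preprocess_dataset(ds)$dataset
  blocks <- c(pp$blocks, list(DX = blocklink:::dx_block(ds$phenotype)))
  set.seed(31)
  cases <- expand.grid(scheme = c("horst", "factorial", "centroid"),
                       design = c("sequential", "complete",
                                  "reversed_sequential"),
                       stringsAsFactors = FALSE)
  n_fits <- 0
  for (seed in 1:6) {
    for (i in seq_len(nrow(cases))) {
      fit <- sgcca_fit(blocks, build_design(cases$design[i]),
                       scheme = cases$scheme[i],
                       sparsity = c(RNA = 0.5, IMG = 0.6), seed = seed)
      expect_true(all(diff(fit$crit) >= -1e-10))
      # constraints tight in sparse mode
      for (nm in c("RNA", "IMG", "DX"))
        expect_lte(abs(sum(fit$weights[[nm]]^2) - 1), 1e-6)
      expect_lte(sum(abs(fit$weights$RNA)),
                 0.5 * sqrt(ncol(blocks$RNA)) + 1e-8)
      n_fits <- n_fits + 1
    }
  }
  expect_gte(n_fits, 50)
})

test_that("permuting a block's columns permutes its weights identically", {
  b <- make_random_blocks(n = 30, p1 = 6, p2 = 4, seed = 41)
  d <- two_block_design()
  fit <- sgcca_fit(b, d, scheme = "centroid", sparsity = 0.7, seed = 2)
  perm <- c(3, 1, 6, 2, 5, 4)
  b2 <- list(A = b$A[, perm], B = b$B)
  fit2 <- sgcca_fit(b2, d, scheme = "centroid", sparsity = 0.7, seed = 2,
                    init = list(fit$weights$A[perm], fit$weights$B))
  expect_equal(unname(fit2$weights$A), unname(fit$weights$A[perm]),
               tolerance = 1e-4)
  expect_equal(utils::tail(fit2$crit, 1), utils::tail(fit$crit, 1),
               tolerance = 1e-10)
})

test_that("sparse mode with vacuous bound reproduces the tau = 1 fit", {
  b <- make_random_blocks(n = 25, p1 = 5, p2 = 4, seed = 43)
  d <- two_block_design()
  f_reg <- sgcca_fit(b, d, scheme = "horst", tau = 1, seed = 7,
                     tol = 1e-14, max_iter = 5000)
  f_sp <- sgcca_fit(b, d, scheme = "horst", sparsity = c(A = 1, B = 1),
                    seed = 7, tol = 1e-14, max_iter = 5000)
  expect_equal(f_sp$weights$A, f_reg$weights$A, tolerance = 1e-6)
  expect_equal(f_sp$weights$B, f_reg$weights$B, tolerance = 1e-6)
})

test_that("criterion never exceeds its standardized-data ceiling", {
  ds <- make_signal_dataset(seed = 14)
  pp <- preprocess_dataset(ds)$dataset
  blocks <- c(pp$blocks, list(DX = blocklink:::dx_block(ds$phenotype)))
  d <- build_design("complete")
  fit <- sgcca_fit(blocks, d, scheme = "centroid", seed = 3)
  # on unit-variance blocks |cov(y_j, y_k)| <= max block variance along a
  # unit direction; bound each pair by sqrt of the largest eigenvalues
  tops <- vapply(blocks, function(X) {
    max(eigen(stats::cov(X), symmetric = TRUE,
              only.values = TRUE)$values)
  }, numeric(1))
  ceiling_ <- sum(d$C * sqrt(outer(tops, tops)))
  expect_lte(utils::tail(fit$crit, 1), ceiling_ + 1e-8)
})

test_that("multi-start criteria agree on well-conditioned data", {
  ds <- make_signal_dataset(seed = 15)
  pp <- preprocess_dataset(ds)$dataset
  blocks <- c(pp$blocks, list(DX = blocklink:::dx_block(ds$phenotype)))
  d <- build_design("sequential")
  crits <- vapply(1:10, function(s) {
    utils::tail(sgcca_fit(blocks, d, scheme = "centroid",
                          sparsity = c(RNA = 0.7, IMG = 0.7),
                          seed = s, tol = 1e-12)$crit, 1)
  }, numeric(1))
  expect_lt(diff(range(crits)), 1e-4)
})

test_that("canonical sign convention yields reproducible weights", {
  b <- make_random_blocks(seed = 47)
  d <- two_block_design()
  fit <- sgcca_fit(b, d, scheme = "centroid", seed = 5)
  for (nm in names(fit$weights))
    expect_gt(fit$weights[[nm]][which.max(abs(fit$weights[[nm]]))], 0)
})

test_that("component scores follow y = X a on new data, with shape checks", {
  b <- make_random_blocks(seed = 53)
  d <- two_block_design()
  fit <- sgcca_fit(b, d, scheme = "centroid", seed = 1)
  newb <- make_random_blocks(n = 7, seed = 54)
  sc <- sgcca_components(fit, newb)
  expect_equal(sc[, "A"], as.vector(newb$A %*% fit$weights$A))
  expect_error(sgcca_components(fit, list(A = newb$A)), "missing")
  expect_error(sgcca_components(fit, list(A = newb$A[, 1:3],
                                          B = newb$B)), "columns")
})

test_that("supervised third block sharpens phenotype alignment", {
  # mirrors the supervised-vs-unsupervised contrast: including the
  # diagnosis block steers the imaging component toward the phenotype
  wins <- 0
  for (s in 1:20) {
    ds <- make_signal_dataset(n_case = 40, n_control = 40, seed = 200 + s)
    pp <- preprocess_dataset(ds)$dataset
    dxb <- blocklink:::dx_block(ds$phenotype)
    f_sup <- sgcca_fit(c(pp$blocks, list(DX = dxb)),
                       build_design("sequential"), scheme = "centroid",
                       seed = s)
    f_uns <- sgcca_fit(pp$blocks,
                       build_design("custom", c("RNA", "IMG"),
                                    C = rbind(c(0, 1), c(1, 0))),
                       scheme = "centroid", seed = s)
    r_sup <- abs(cor(f_sup$components[, "IMG"], ds$phenotype))
    r_uns <- abs(cor(f_uns$components[, "IMG"], ds$phenotype))
    wins <- wins + (r_sup >= r_uns)
  }
  expect_gte(wins, 16)
})

test_that("fit agrees with the mixOmics sparse multiblock implementation", {
  # independent cross-check on a small three-block instance
  library(mixOmics)
  ds <- make_signal_dataset(n_case = 25, n_control = 25, seed = 61)
  pp <- preprocess_dataset(ds)$dataset
  dxb <- blocklink:::dx_block(ds$phenotype)
  blocks <- c(pp$blocks, list(DX = dxb))
  d <- build_design("complete")
  fit <- sgcca_fit(blocks, d, scheme = "centroid",
                   sparsity = c(RNA = 0.6, IMG = 0.7, DX = 1),
                   seed = 3, tol = 1e-12)
  ref <- mixOmics::wrapper.sgcca(
    X = blocks, penalty = c(0.6, 0.7, 1), design = d$C, ncomp = 1,
    scheme = "centroid", scale = FALSE, init = "svd.single",
    tol = 1e-12, max.iter = 2000)
  for (nm in c("RNA", "IMG")) {
    a_ref <- as.vector(ref$loadings[[nm]])
    a_ref <- a_ref / sqrt(sum(a_ref^2))
    agree <- abs(sum(a_ref * fit$weights[[nm]]))
    expect_gt(agree, 0.999)
  }
})
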