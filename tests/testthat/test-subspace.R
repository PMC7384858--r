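# Brute-force alignment oracle: explicit covariance, explicit projection
# trace, denominator from a dense eigendecomposition of the covariance
# computed through R's svd (a different code path than the package's
# eigen-based route).
oracle_alignment <- function(x_target, v_ref) {
  xc <- sweep(x_target, 2L, colMeans(x_target))
  cv <- t(xc) %*% xc / (nrow(x_target) - 1)
  num <- 0
  for (j in seq_len(ncol(v_ref)))
    num <- num + drop(t(v_ref[, j]) %*% cv %*% v_ref[, j])
  ev <- svd(cv)$d
  num / sum(ev[seq_len(ncol(v_ref))])
}

test_that("fit_subspace matches dense eigenstructure and handles rank", {
  set.seed(81)
  # variance along a single known axis
  ax <- c(1, 2, -1) / sqrt(6)
  x1 <- outer(rnorm(50), ax)
  m1 <- fit_subspace(x1 + 0, k = 1)
  expect_equal(abs(sum(m1$v * ax)), 1, tolerance = 1e-8)
  expect_equal(m1$var_frac, 1, tolerance = 1e-10)
  # toy matrix vs an independent svd-based eigendecomposition, up to sign
  x <- matrix(rnorm(40 * 6), 40, 6)
  mdl <- fit_subspace(x, k = 3)
  sv <- svd(cov(x))
  for (j in 1:3)
    expect_equal(abs(sum(mdl$v[, j] * sv$u[, j])), 1, tolerance = 1e-8)
  expect_equal(mdl$eigenvalues, sv$d, tolerance = 1e-8)
  expect_equal(crossprod(mdl$v), diag(3), tolerance = 1e-10,
               ignore_attr = TRUE)
  # deterministic sign: largest-|entry| coordinate positive
  for (j in 1:3) expect_gt(mdl$v[which.max(abs(mdl$v[, j])), j], 0)
  # rank deficiency reports the achievable k
  xr <- cbind(x1, x1[, 1] * 2)   # rank 1 in 4 columns
  expect_error(fit_subspace(xr, k = 3), "achievable k = 1")
  expect_error(fit_subspace(matrix(rnorm(6), 2, 3), k = 3), "T > k")
})

test_that("alignment identities hold to 1e-10", {
  set.seed(82)
  x <- matrix(rnorm(60 * 8), 60, 8) %*% diag(c(4, 3, 2.5, 2, 1, 1, 1, 1))
  mdl <- fit_subspace(x, k = 3)
  expect_equal(alignment_index(x, mdl)$a, 1, tolerance = 1e-10)
  # data confined to the orthogonal complement of the basis
  cmp <- qr.Q(qr(cbind(mdl$v, matrix(rnorm(8 * 5), 8, 5))))[, 4:8]
  x_perp <- matrix(rnorm(60 * 5), 60, 5) %*% t(cmp)
  expect_equal(alignment_index(x_perp, mdl)$a, 0, tolerance = 1e-10)
  expect_error(alignment_index(x[, 1:5], mdl), "must match")
})

test_that("alignment equals the brute-force oracle on random instances", {
  set.seed(83)
  for (i in 1:100) {
    n <- sample(5:8, 1)
    k <- sample(1:3, 1)
    x_ref <- matrix(rnorm(30 * n), 30, n)
    x_tgt <- matrix(rnorm(30 * n), 30, n)
    mdl <- fit_subspace(x_ref, k = k)
    a <- alignment_index(x_tgt, mdl)$a
    expect_equal(a, oracle_alignment(x_tgt, mdl$v), tolerance = 1e-10)
    expect_gte(a, 0); expect_lte(a, 1)
  }
})

test_that("alignment is invariant to scale and covariance convention", {
  set.seed(84)
  x_ref <- matrix(rnorm(40 * 6), 40, 6)
  x <- matrix(rnorm(40 * 6), 40, 6)
  mdl <- fit_subspace(x_ref, k = 2)
  a1 <- alignment_index(x, mdl)$a
  expect_equal(alignment_index(37.5 * x, mdl)$a, a1, tolerance = 1e-12)
  # T vs T-1 covariance convention cancels in the ratio
  xc <- sweep(x, 2L, colMeans(x))
  cv_t <- crossprod(xc) / nrow(x)
  num <- sum(diag(t(mdl$v) %*% cv_t %*% mdl$v))
  den <- sum(eigen(cv_t, symmetric = TRUE, only.values = TRUE)$values[1:2])
  expect_equal(num / den, a1, tolerance = 1e-12)
})

test_that("k = 1 planted rotations obey the cos^2 law (noise-free)", {
  set.seed(85)
  n <- 12
  v0 <- qr.Q(qr(matrix(rnorm(n), n, 1)))
  vp <- qr.Q(qr(cbind(v0, rnorm(n))))[, 2]
  z <- sin(seq(0, 6 * pi, length.out = 80))
  mdl <- fit_subspace(outer(z, drop(v0)), k = 1)
  prev <- Inf
  for (th in c(0, 30, 45, 60, 90) * pi / 180) {
    vt <- cos(th) * drop(v0) + sin(th) * vp
    a <- alignment_index(outer(z, vt), mdl)$a
    expect_equal(a, cos(th)^2, tolerance = 1e-6)
    expect_lte(a, prev + 1e-9)
    prev <- a
  }
})

test_that("random orthonormal null draws are Haar-like and the p convention is strict", {
  set.seed(86)
  # every draw orthonormal
  for (i in 1:20) {
    q <- mirrorpop:::random_orthonormal(15, 3)
    expect_equal(crossprod(q), diag(3), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  # rank-k equal-eigenvalue target: null mean ~ k/N (module-scale check)
  n <- 20; k <- 2; tt <- 60
  v <- qr.Q(qr(matrix(rnorm(n * k), n, k)))
  e <- qr.Q(qr(matrix(rnorm(tt * k), tt, k))) * sqrt(tt - 1)
  x <- e %*% t(v)
  nl <- random_orthonormal_null(x, k = k, n = 4000, seed = 1)
  expect_equal(nl$mean, k / n, tolerance = 0.05)
  # isotropic full-rank target: every draw captures everything, a = 1,
  # and the strictly-greater convention makes p = 0 for observed a = 1
  m <- matrix(rnorm(60 * 10), 60, 10)
  mc <- sweep(m, 2L, colMeans(m))
  iso <- mc %*% solve(chol(cov(mc)))    # whitened: cov exactly identity
  nl2 <- random_orthonormal_null(iso, k = 3, n = 200, seed = 2,
                                 observed = 1)
  expect_true(all(abs(nl2$null - 1) < 1e-10))
  expect_equal(nl2$p, 0)
})

test_that("cross-grasp bootstrap is symmetric, degenerate and sensitive as planted", {
  set.seed(87)
  n <- 16; tt <- 60
  shared <- matrix(rnorm(tt * n), tt, n)
  # identical activity for both grasps in both conditions: all alignments
  # ~1 and p ~ 0.5 by symmetry
  x_by <- list(execution = list(PG = shared, WHG = shared),
               observation = list(PG = shared, WHG = shared))
  bs <- bootstrap_cross_grasp(x_by, k = 2, n = 200, seed = 1)
  expect_true(all(abs(c(bs$a_execution, bs$a_observation) - 1) < 1e-8))
  expect_equal(bs$p, mean(bs$a_execution > bs$a_observation))
  # fraction = 1: every draw identical to the full-population value
  bs1 <- bootstrap_cross_grasp(x_by, k = 2, fraction = 1, n = 20, seed = 2)
  expect_equal(length(unique(round(bs1$a_execution, 12))), 1)
  # planted execution grasp separation with shared observation subspace
  v_pg <- qr.Q(qr(matrix(rnorm(n * 2), n, 2)))
  v_whg <- qr.Q(qr(cbind(v_pg, matrix(rnorm(n * 2), n, 2))))[, 3:4]
  z <- matrix(rnorm(tt * 2), tt, 2)
  x_by2 <- list(
    execution = list(PG = z %*% t(v_pg) + 0.05 * matrix(rnorm(tt * n), tt, n),
                     WHG = z %*% t(v_whg) + 0.05 * matrix(rnorm(tt * n), tt, n)),
    observation = list(PG = z %*% t(v_pg) + 0.05 * matrix(rnorm(tt * n), tt, n),
                       WHG = z %*% t(v_pg) + 0.05 * matrix(rnorm(tt * n), tt, n)))
  bs2 <- bootstrap_cross_grasp(x_by2, k = 2, n = 200, seed = 3)
  expect_lt(bs2$p, 0.05)
  expect_lt(mean(bs2$a_execution), mean(bs2$a_observation))
  expect_error(bootstrap_cross_grasp(x_by, k = 5, n = 10, seed = 1),
               "2k neurons")
})

test_that("projection suite reproduces the planted signature patterns", {
  run_sig <- function(rho_eo, rho_on, seed) {
    sim <- small_session(seed = seed, n_neurons = 30,
                         rho_exe_obs = rho_eo, rho_obs_nogo = rho_on,
                         trials_per_grasp = c(execution = 12,
                                              observation = 12, nogo = 8))
    b <- sim$bundle
    canon <- canonical_events(b)
    tl <- list()
    for (cond in c("execution", "observation", "nogo"))
      tl[[cond]] <- list(PG = multi_align(b, cond, "PG", canonical = canon))
    flat <- soft_normalize(baseline_correct(unlist(tl, recursive = FALSE)),
                           "range_soft", 5)
    tl <- list(execution = list(PG = flat[[1]]),
               observation = list(PG = flat[[2]]),
               nogo = list(PG = flat[[3]]))
    condition_projection_suite(tl, k = 3, n_null = 1000, seed = seed)$PG
  }
  m1 <- run_sig(0, 0.9, 881)
  expect_gt(m1$movement$observation$p, 0.05)
  expect_lt(m1$observation$nogo$p, 0.05)
  f5 <- run_sig(0.9, 0, 882)
  expect_lt(f5$movement$observation$p, 0.05)
  expect_gt(f5$observation$nogo$p, 0.05)
  # a is always in [0, 1]
  for (s in list(m1, f5)) {
    expect_gte(s$movement$observation$a, 0)
    expect_lte(s$movement$observation$a, 1)
  }
  # nogo tensor absent: analysis skipped, not errored
  sim <- small_session(seed = 883, n_neurons = 12)
  canon <- canonical_events(sim$bundle)
  tl <- list(execution = list(PG = multi_align(sim$bundle, "execution",
                                               "PG", canonical = canon)),
             observation = list(PG = multi_align(sim$bundle, "observation",
                                                 "PG", canonical = canon)))
  st <- condition_projection_suite(tl, k = 3, n_null = 200, seed = 1)
  expect_true(st$PG$observation$nogo$skipped)
})
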