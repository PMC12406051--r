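test_that("LS-A reduces to projection identities on trivial designs", {
  # identity design: estimates equal the signal
  Y <- matrix(rnorm(12), 4, 3)
  des <- trialwise_design(diag(4), trial_cols = 1:4)
  est <- lsa_estimate(Y, des)
  expect_equal(est$gamma, Y, ignore_attr = TRUE)
  expect_identical(est$method, "LSA")

  # noiseless signal: exact recovery
  des2 <- toy_design(t = 6, seed = 2)
  G <- matrix(rnorm(6 * 3), 6, 3)
  Xt <- des2$matrix[, des2$trial_cols]
  est2 <- lsa_estimate(Xt %*% G, des2)
  expect_equal(est2$gamma, G, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("LS-A equals a dense GLS solve with non-identity scan covariance", {
  set.seed(10)
  n <- 20; t <- 5; v <- 3
  X <- cbind(matrix(rnorm(n * t), n, t), 1)
  V <- random_spd(n, seed = 11)
  des <- trialwise_design(X, trial_cols = 1:t, TR = 1, scan_cov = V)
  Y <- matrix(rnorm(n * v), n, v)
  est <- lsa_estimate(Y, des)
  B <- gls_solve(X, Y, V)
  expect_equal(est$gamma, B[1:t, , drop = FALSE], tolerance = 1e-8,
               ignore_attr = TRUE)

  # residual orthogonality: Xt' V^-1 (Y - X %*% B) = 0 for every voxel
  resid <- Y - X %*% B
  expect_lt(max(abs(t(X) %*% solve(V) %*% resid)), 1e-8)
})

test_that("rank-deficient designs fail loudly naming the collinear columns", {
  X <- cbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = rnorm(4))
  des <- trialwise_design(X, trial_cols = 1:2)
  expect_error(lsa_estimate(matrix(rnorm(8), 4, 2), des), "condition number")
  expect_error(lsa_estimate(matrix(rnorm(8), 4, 2), des), "b")
})

test_that("LS-S matches hand-solved two-trial normal equations and equals LS-A when trials do not overlap", {
  # 4-scan toy, 2 trials: the per-trial models coincide with the full model
  X <- matrix(c(1, 1, 0, 0,
                0, 1, 1, 1), 4, 2)
  des <- trialwise_design(X, trial_cols = 1:2)
  y <- matrix(c(2, 3, 1, 0.5), 4, 1)
  G <- crossprod(X)                       # [[2,1],[1,3]]
  expected <- solve(G, crossprod(X, y))
  est <- lss_estimate(y, des)
  expect_equal(est$gamma, expected, tolerance = 1e-10, ignore_attr = TRUE)

  # non-overlapping trials: LS-S == LS-A elementwise
  ev <- event_table(onset = c(0, 40, 80), duration = 2, condition = "A")
  des2 <- build_trialwise_design(ev, n_scans = 60, TR = 2)
  Y <- matrix(rnorm(60 * 4), 60, 4)
  expect_equal(lss_estimate(Y, des2)$gamma, lsa_estimate(Y, des2)$gamma,
               tolerance = 1e-8)

  expect_error(lss_estimate(matrix(rnorm(8), 4, 2),
                            trialwise_design(matrix(rnorm(4)), trial_cols = 1)),
               "lsa_estimate")
})

test_that("LS-S fits one model per trial and agrees with explicit per-trial GLMs", {
  des <- toy_design(t = 100, seed = 5, isi = c(0, 4))
  set.seed(6)
  Y <- matrix(rnorm(des$n_scans * 2), des$n_scans, 2)
  est <- lss_estimate(Y, des)
  expect_identical(attr(est, "n_fits"), 100L)

  # independent oracle: explicit three-column GLM for a few trials
  X <- des$matrix
  tc <- des$trial_cols
  for (i in c(1, 37, 100)) {
    Xi <- cbind(X[, i], rowSums(X[, setdiff(tc, i), drop = FALSE]),
                X[, des$nuisance_cols])
    bi <- solve(crossprod(Xi), crossprod(Xi, Y))
    expect_equal(est$gamma[i, ], bi[1, ], tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("uncorrelation matrix matches hand inverses and reflects trial overlap", {
  # printed 2x2 toy
  des <- trialwise_design(matrix(c(1, 1, 0, 1), 2, 2), trial_cols = 1:2)
  expect_equal(uncorrelation_matrix(des),
               matrix(c(1, -1, -1, 2), 2, 2), tolerance = 1e-12)

  # orthonormal trial columns -> identity
  Q <- qr.Q(qr(matrix(rnorm(18), 6, 3)))
  expect_equal(uncorrelation_matrix(trialwise_design(Q, trial_cols = 1:3)),
               diag(3), tolerance = 1e-10)

  # the trial block accounts for nuisance covariation: it equals the block of
  # the full inverse, not the inverse of the trial-only cross-product
  des_n <- toy_design(t = 6, seed = 8)
  U <- uncorrelation_matrix(des_n)
  full_inv <- solve(crossprod(des_n$matrix))
  expect_equal(U, full_inv[1:6, 1:6], tolerance = 1e-9, ignore_attr = TRUE)

  # short ISIs induce negative covariance between adjacent trials,
  # decaying with temporal distance
  des_s <- toy_design(t = 20, seed = 9, isi = c(0, 4))
  Us <- uncorrelation_matrix(des_s)
  adj <- Us[cbind(1:19, 2:20)]
  far <- Us[cbind(1:10, 11:20)]
  expect_lt(mean(adj), 0)
  expect_gt(mean(abs(adj)), mean(abs(far)))

  # off-diagonal mass shrinks as ISIs grow
  offdiag_mass <- function(U) mean(abs(U[upper.tri(U)]))
  des_l <- toy_design(t = 20, seed = 9, isi = c(4, 8))
  expect_lt(offdiag_mass(uncorrelation_matrix(des_l)), offdiag_mass(Us))
})

test_that("the covariance of LS-A estimates across noise repetitions is proportional to U", {
  des <- toy_design(t = 8, seed = 12, isi = c(0, 4), constant = FALSE)
  U <- uncorrelation_matrix(des)
  gamma0 <- rnorm(8)
  sigma2 <- 1.5
  N <- 4000
  set.seed(13)
  mu <- des$matrix %*% gamma0
  # each repetition is one "voxel": estimate all repetitions in one call
  Y <- matrix(mu, des$n_scans, N) +
    matrix(rnorm(des$n_scans * N, sd = sqrt(sigma2)), des$n_scans, N)
  gh <- lsa_estimate(Y, des)$gamma
  emp_cov <- stats::cov(t(gh))
  expect_lt(max(abs(emp_cov - sigma2 * U)) / max(abs(sigma2 * U)), 0.15)
})
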