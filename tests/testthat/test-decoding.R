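test_that("decoding weights satisfy inversion identities", {
  # estimates equal to the design variables: weights are the identity
  Tm <- diag(3)[rep(1:3, 4), ]
  W <- item_weights(Tm, Tm, U = NULL)
  expect_equal(W, diag(3), ignore_attr = TRUE, tolerance = 1e-10)

  # noiseless linear encoding with invertible pattern matrix: W = B^-1
  set.seed(31)
  B <- matrix(rnorm(4), 2, 2) + diag(2)
  T0 <- cbind(rep(c(1, 0), 10), rep(c(0, 1), 10))
  G <- T0 %*% B
  W2 <- item_weights(G, T0)
  expect_equal(W2, solve(B), tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(predict_design(W2, G), T0, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("decoding weights equal a dense GLS solve and its whitened-OLS form", {
  set.seed(32)
  t <- 40; v <- 6; p <- 2
  G <- matrix(rnorm(t * v), t, v)
  Tm <- cbind(rnorm(t), rnorm(t))
  U <- random_spd(t, seed = 33)
  W <- item_weights(G, Tm, U)
  # oracle 1: brute-force generalized least squares by explicit inversion
  Ui <- solve(U)
  W_gls <- solve(t(G) %*% Ui %*% G) %*% t(G) %*% Ui %*% Tm
  expect_equal(W, W_gls, tolerance = 1e-8, ignore_attr = TRUE)
  # oracle 2: ordinary least squares after whitening by the Cholesky factor
  Li <- solve(t(chol(U)))
  W_ols <- qr.coef(qr(Li %*% G), Li %*% Tm)
  expect_equal(W, W_ols, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("singular training systems error unless the pseudoinverse fallback is enabled", {
  set.seed(34)
  G <- matrix(rnorm(5 * 8), 5, 8)      # more voxels than trials
  Tm <- cbind(rep(1:0, length.out = 5), rep(0:1, length.out = 5))
  expect_error(item_weights(G, Tm), "singular")
  W <- item_weights(G, Tm, fallback = TRUE)
  expect_true(all(is.finite(W)))
  expect_error(predict_design(W, matrix(rnorm(12), 3, 4)), "voxel mismatch")
})

test_that("cross-validated ITEM fit partitions sessions into folds and predicts each trial once", {
  for (S in c(2, 4)) {
    est <- toy_estimates(t_per_session = 12, v = 4, S = S, seed = 40 + S)
    labels <- factor(rep(rep(c("A", "B"), 6), S))
    fit <- item(est, labels, calibrate = FALSE)
    expect_s3_class(fit, "item")
    expect_length(fit$weights, S)
    expect_true(all(!is.na(fit$predicted)))
    expect_equal(sort(unique(fit$fold)), sort(as.character(1:S)))
    # folds partition trials: each trial appears in exactly one held-out fold
    expect_equal(unname(table(fit$fold)), rep(12, S), ignore_attr = TRUE)
  }
  est1 <- toy_estimates(S = 1)
  expect_error(item(est1, factor(rep(c("A", "B"), 10))), "2 sessions")
})

test_that("model methods expose coefficients, predictions, residuals and summaries", {
  set.seed(50)
  est <- toy_estimates(t_per_session = 16, v = 5, S = 2, seed = 50)
  labels <- factor(rep(rep(c("A", "B"), 8), 2))
  fit <- item(est, labels, calibrate = FALSE)
  expect_output(print(fit), "classification")
  s <- summary(fit)
  expect_s3_class(s, "summary.item")
  expect_true(s$pooled["accuracy"] >= 0 && s$pooled["accuracy"] <= 1)
  expect_equal(dim(coef(fit)), c(5, 2))
  expect_equal(dim(coef(fit, fold = 1)), c(5, 2))
  pred <- predict(fit, est$gamma[1:4, ])
  expect_equal(dim(pred), c(4, 2))
  cls <- predict(fit, est, type = "class")
  expect_s3_class(cls, "factor")
  expect_equal(residuals(fit), fit$actual - fitted(fit), ignore_attr = TRUE)
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))

  # regression targets
  xval <- rnorm(32)
  fitr <- item(est, xval, calibrate = FALSE)
  expect_identical(fitr$task, "regression")
  sr <- summary(fitr)
  expect_true(is.finite(sr$pooled[1, "correlation"]))
})

test_that("classification helpers follow their declared contracts", {
  expect_equal(classify(matrix(c(0.8, 0.2), 1)), 1L)
  expect_equal(classify(matrix(c(0.5, 0.5), 1)), 1L)     # tie -> lowest index
  expect_equal(classify(diag(4)), 1:4)
  expect_equal(decoding_accuracy(c(1, 1, 2, 2), c(1, 2, 2, 2)), 0.75)
  expect_equal(decoding_accuracy(1:5, 1:5), 1)
  expect_error(decoding_accuracy(integer(), integer()), "empty")
  # balanced accuracy weights classes equally
  expect_equal(balanced_accuracy(c(1, 1, 1, 2), c(1, 1, 2, 2)), 0.75)
  # random labels against balanced truth: binomial oracle at n = 10000
  set.seed(60)
  truth <- rep(1:2, 5000)
  labels <- sample(1:2, 10000, replace = TRUE)
  expect_lt(abs(decoding_accuracy(labels, truth) - 0.5), 0.02)
})

test_that("predictive correlation and MAE match hand computations", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 6)
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(predictive_correlation(y, x), num / den)
  expect_equal(predictive_correlation(x, x), 1)
  expect_equal(predictive_correlation(-x, x), -1)
  expect_warning(r <- predictive_correlation(x, rep(1, 5)), "constant")
  expect_true(is.nan(r))
  expect_error(predictive_correlation(1:2, 1:2), "3 trials")
  expect_equal(median_absolute_error(y, x), 1)
})

test_that("decoding accuracy sits at chance when labels carry no information", {
  set.seed(70)
  accs <- replicate(200, {
    est <- trial_estimates(matrix(rnorm(40 * 6), 40, 6), rep(1:2, each = 20),
                           U = list(`1` = diag(20), `2` = diag(20)))
    labels <- factor(sample(rep(c("A", "B"), 20)))
    fit <- item(est, labels, calibrate = FALSE)
    decoding_accuracy(classify(fit$predicted), max.col(fit$actual))
  })
  expect_lt(abs(mean(accs) - 0.5), 0.03)
})

test_that("SVM baseline cross-validates by session and stays at chance for shuffled labels", {
  set.seed(71)
  accs <- replicate(60, {
    est <- trial_estimates(matrix(rnorm(40 * 6), 40, 6), rep(1:2, each = 20))
    labels <- factor(sample(rep(c("A", "B"), 20)))
    cv <- svm_crossvalidate(est, labels)
    mean(cv$predicted == cv$actual)
  })
  expect_lt(abs(mean(accs) - 0.5), 0.05)
  est <- trial_estimates(matrix(rnorm(20 * 3), 20, 3), rep(1, 20))
  expect_error(svm_crossvalidate(est, factor(rep(c("A", "B"), 10))),
               "2 sessions")
})
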