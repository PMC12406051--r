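test_that("canonical HRF has the expected double-gamma shape", {
  h <- canonical_hrf(0.1, length = 32)
  tt <- attr(h, "time")
  expect_equal(max(h), 1)                      # peak-normalized
  peak <- tt[which.max(h)]
  expect_gt(peak, 4)
  expect_lt(peak, 7)
  expect_lt(h[which.min(abs(tt - 20))], 0)     # post-stimulus undershoot
  expect_error(canonical_hrf(0), "positive")
  expect_error(canonical_hrf(-1), "positive")
})

test_that("trial-wise design has one column per trial and matches a direct convolution oracle", {
  t <- 100
  set.seed(42)
  onsets <- c(0, cumsum(2 + runif(t - 1, 0, 4)))
  ev <- event_table(onset = onsets, duration = 2,
                    condition = rep(c("A", "B"), 50))
  n_scans <- ceiling((max(onsets) + 2 + 32) / 2)
  des <- build_trialwise_design(ev, n_scans = n_scans, TR = 2)
  expect_s3_class(des, "trialwise_design")
  expect_length(des$trial_cols, 100)
  expect_identical(colnames(des$matrix)[101], "constant")

  # independent oracle: direct convolution sum on the fine grid, one trial
  TR <- 2; ovs <- 16; dt <- TR / ovs
  ev1 <- event_table(onset = 3.3, duration = 2, condition = "A")
  d1 <- build_trialwise_design(ev1, n_scans = 25, TR = TR)
  h <- canonical_hrf(dt)
  n_fine <- 25 * ovs
  box <- numeric(n_fine)
  box[round(3.3 / dt) + seq_len(round(2 / dt))] <- 1
  conv <- numeric(n_fine)
  for (n in seq_len(n_fine)) {
    k <- seq_len(min(n, length(h)))
    conv[n] <- sum(h[k] * box[n - k + 1]) * dt
  }
  ref <- (seq_len(25) - 1) * ovs + ovs / 2 + 1
  expect_equal(unname(d1$matrix[, 1]), conv[ref], tolerance = 1e-10)

  # column peaks 6-8 s after onset
  tpeak <- (which.max(d1$matrix[, 1]) - 1) * TR + TR / 2
  expect_gt(tpeak - 3.3, 4)
  expect_lt(tpeak - 3.3, 9)
})

test_that("well-separated trials give orthogonal regressors", {
  ev <- event_table(onset = c(0, 40), duration = 2, condition = c("A", "B"))
  des <- build_trialwise_design(ev, n_scans = 40, TR = 2, constant = FALSE)
  expect_equal(sum(des$matrix[, 1] * des$matrix[, 2]), 0)
})

test_that("design construction is deterministic and validates inputs", {
  ev <- event_table(onset = c(0, 5, 12), duration = 2, condition = c("A", "B", "A"))
  d1 <- build_trialwise_design(ev, n_scans = 30, TR = 2)
  d2 <- build_trialwise_design(ev, n_scans = 30, TR = 2)
  expect_identical(d1$matrix, d2$matrix)
  expect_error(build_trialwise_design(ev, n_scans = 30, TR = -1), "TR")
  expect_error(event_table(onset = numeric(), duration = numeric(),
                           condition = character()), "at least one event")
  expect_error(event_table(onset = c(5, 1), duration = 2,
                           condition = c("A", "B")), "increasing")
  expect_error(event_table(onset = c(0, 5), duration = -1,
                           condition = c("A", "B")), "positive")
  # event beyond the scanned interval: truncated with a warning
  ev_long <- event_table(onset = c(0, 19), duration = 2, condition = c("A", "B"))
  expect_warning(build_trialwise_design(ev_long, n_scans = 10, TR = 2),
                 "truncated")
})

test_that("transformation matrix is the condition indicator (plus modulators)", {
  ev <- event_table(onset = c(0, 6, 12, 18), duration = 2,
                    condition = c("A", "B", "A", "B"))
  Tm <- build_transformation_matrix(ev)
  expect_equal(Tm, matrix(c(1, 0, 1, 0, 0, 1, 0, 1), 4, 2), ignore_attr = TRUE)
  expect_true(all(rowSums(Tm) == 1))

  ev1 <- event_table(onset = c(0, 6, 12), duration = 2, condition = "stim")
  expect_equal(build_transformation_matrix(ev1), matrix(1, 3, 1),
               ignore_attr = TRUE)

  # 48 parametric modulators on a single stimulation condition
  set.seed(7)
  mods <- as.data.frame(matrix(runif(10 * 48), 10, 48))
  names(mods) <- sprintf("sector_%02d", 1:48)
  evm <- event_table(onset = seq(0, 27, by = 3), duration = 3,
                     condition = "stim", modulators = mods)
  Tm <- build_transformation_matrix(evm, modulators = names(mods))
  expect_equal(ncol(Tm), 49)
  expect_equal(sum(attr(Tm, "column_kind") == "parametric"), 48)
  expect_equal(unname(Tm[, "sector_05"]), mods$sector_05)

  evna <- event_table(onset = c(0, 6), duration = 2, condition = "stim",
                      modulators = data.frame(m = c(1, NA)))
  expect_error(build_transformation_matrix(evna, modulators = "m"), "missing")
})

test_that("multiplying the trial-wise design by T reconstructs the condition-based design", {
  set.seed(3)
  onsets <- c(0, cumsum(2 + runif(19, 0, 4)))
  cond <- sample(rep(c("A", "B"), 10))
  ev_tw <- event_table(onset = onsets, duration = 2, condition = cond)
  ev_std <- event_table(onset = onsets, duration = 2, condition = cond,
                        is_trialwise = FALSE)
  n_scans <- ceiling((max(onsets) + 34) / 2)
  des_tw <- build_trialwise_design(ev_tw, n_scans = n_scans, TR = 2, constant = FALSE)
  des_std <- build_trialwise_design(ev_std, n_scans = n_scans, TR = 2, constant = FALSE)
  Tm <- build_transformation_matrix(ev_tw)
  X_rec <- des_tw$matrix[, des_tw$trial_cols] %*% Tm
  expect_equal(unname(X_rec[, "A"]), unname(des_std$matrix[, "A"]), tolerance = 1e-10)
  expect_equal(unname(X_rec[, "B"]), unname(des_std$matrix[, "B"]), tolerance = 1e-10)
})

test_that("BIDS events.tsv round-trips through read_events", {
  tsv <- file.path(tempdir(), "events.tsv")
  df <- data.frame(onset = c(0, 4.5, 9), duration = 2,
                   trial_type = c("face", "house", "face"),
                   intensity = c(0.1, 0.5, 1))
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  ev <- read_events(tsv, session = 3L, modulator_columns = "intensity")
  expect_s3_class(ev, "event_table")
  expect_equal(ev$onset, df$onset)
  expect_equal(ev$condition, df$trial_type)
  expect_equal(ev$intensity, df$intensity)
  expect_true(all(ev$session == 3L))
  expect_error(read_events(tsv, modulator_columns = "nope"), "not found")
  expect_error(read_events(file.path(tempdir(), "absent.tsv")), "not found")
})
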