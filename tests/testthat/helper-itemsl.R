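# Shared fixture builders (all fixtures are generated in code).

# a small random trial-wise design with overlapping HRFs
toy_design <- function(t = 5, TR = 2, isi = c(1, 3), duration = 2, seed = 1,
                       constant = TRUE) {
  set.seed(seed)
  isi_draw <- runif(t, isi[1], isi[2])
  onsets <- c(0, cumsum(duration + isi_draw[-t]))
  n_scans <- ceiling((onsets[t] + duration + 32) / TR)
  ev <- event_table(onset = onsets, duration = duration,
                    condition = rep(c("A", "B"), length.out = t))
  build_trialwise_design(ev, n_scans = n_scans, TR = TR, constant = constant)
}

# random trial estimates with identity uncorrelation, grouped by session
toy_estimates <- function(t_per_session = 20, v = 6, S = 2, seed = 1,
                          U_blocks = NULL, method = "LSA") {
  set.seed(seed)
  gamma <- matrix(rnorm(S * t_per_session * v), S * t_per_session, v)
  sessions <- rep(seq_len(S), each = t_per_session)
  if (is.null(U_blocks)) {
    U_blocks <- setNames(lapply(seq_len(S), function(s) diag(t_per_session)),
                         seq_len(S))
  }
  trial_estimates(gamma, sessions, U = U_blocks, method = method)
}

# dense generalized least squares by explicit inversion (independent oracle)
gls_solve <- function(X, Y, V = NULL) {
  if (is.null(V)) V <- diag(nrow(X))
  Vi <- solve(V)
  solve(t(X) %*% Vi %*% X) %*% t(X) %*% Vi %*% Y
}

# random symmetric positive-definite matrix
random_spd <- function(n, seed = 1) {
  set.seed(seed)
  A <- matrix(rnorm(n * n), n)
  crossprod(A) / n + diag(n)
}
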