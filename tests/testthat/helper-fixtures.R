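# Shared fixtures and independent oracles used across the suite.

# Reduced paradigm: 6 blocks of 9 trials keep the per-pair position balance
# (9 trials per ordered pair per run are divisible by the 3 positions) while
# shortening runs for test-time simulation.
small_params <- function(n_runs = 1) {
  paradigm_params(n_runs = n_runs, trials_per_block = 9, nulls_per_run = 8)
}

# Cache of small schedules so repeated tests do not rebuild them.
.schedule_cache <- new.env(parent = emptyenv())
cached_schedule <- function(seed, n_runs = 1) {
  key <- paste0("s", seed, "r", n_runs)
  if (is.null(.schedule_cache[[key]])) {
    .schedule_cache[[key]] <- build_experiment(seed, small_params(n_runs))
  }
  .schedule_cache[[key]]
}

# Brute-force hazard oracle: enumerate the three equally likely outcomes
# (deviant at 4, 5 or 6) and count, among outcomes where no deviant occurred
# before position k, those with the deviant exactly at k.
enumerate_hazard <- function(k, positions = 4:6) {
  at_k <- sum(positions == k)
  at_or_after <- sum(positions >= k)
  at_k / at_or_after
}

# Brute-force normal-equations GLM oracle.
normal_equations_fit <- function(y, X) {
  solve(crossprod(X), crossprod(X, y))
}

# Iterative-thresholding ROI oracle: raise the threshold over the observed
# values until at most `target` voxels survive; pad deterministically (lowest
# linear index first) if the tie at the threshold overshoots.
iterative_threshold_roi <- function(prior, stat, target) {
  vals <- stat[prior]
  for (th in sort(unique(vals))) {
    if (sum(vals >= th) <= target) break
  }
  surviving <- prior[vals >= th]
  if (length(surviving) < target) {
    at_tie <- setdiff(prior[vals == max(vals[vals < th])], surviving)
    surviving <- c(surviving, sort(at_tie)[seq_len(target -
                                                     length(surviving))])
  }
  sort(surviving)
}

# Numerical-quadrature oracle for the conjugate linear-model evidence:
# integrate the likelihood times the Normal-Inverse-Gamma prior over a dense
# (beta1, beta2, log sigma^2) grid by trapezoid summation in log space.
# Only valid for 2-column designs.
quad_log_evidence <- function(y, X, lambda = 1, a0 = 1e-3, b0 = 1e-3,
                              beta_lim = 8, n_beta = 141,
                              ls_range = log(c(1e-3, 1e3)), n_s = 241) {
  stopifnot(ncol(X) == 2)
  n <- length(y)
  A <- crossprod(X)
  bb <- crossprod(X, y)
  c0 <- sum(y^2)
  beta <- seq(-beta_lim, beta_lim, length.out = n_beta)
  hb <- beta[2] - beta[1]
  # residual sum of squares + prior quadratic over the (beta1, beta2) grid
  Q <- outer(beta, beta, function(b1, b2) {
    c0 - 2 * (bb[1] * b1 + bb[2] * b2) +
      A[1, 1] * b1^2 + 2 * A[1, 2] * b1 * b2 + A[2, 2] * b2^2 +
      lambda * (b1^2 + b2^2)
  })
  wbeta <- matrix(2 * log(hb), n_beta, n_beta)  # hb^2 cell area
  wbeta[c(1, n_beta), ] <- wbeta[c(1, n_beta), ] + log(0.5)
  wbeta[, c(1, n_beta)] <- wbeta[, c(1, n_beta)] + log(0.5)

  s <- seq(ls_range[1], ls_range[2], length.out = n_s)
  hs <- s[2] - s[1]
  ws <- rep(log(hs), n_s)
  ws[c(1, n_s)] <- ws[c(1, n_s)] + log(0.5)

  const <- a0 * log(b0) - lgamma(a0) + log(lambda)  # p/2 log lambda, p = 2
  chunks <- vapply(seq_len(n_s), function(i) {
    sig2 <- exp(s[i])
    L <- -(n + 2) / 2 * log(2 * pi * sig2) - Q / (2 * sig2) -
      (a0 + 1) * s[i] - b0 / sig2 + s[i] + const + wbeta
    m <- max(L)
    m + log(sum(exp(L - m))) + ws[i]
  }, numeric(1))
  m <- max(chunks)
  m + log(sum(exp(chunks - m)))
}

# Random small-evidence toy: 12 timepoints, 2 standardised columns.
make_evidence_toy <- function(seed, n = 12, beta_sd = 1, noise_sd = 1) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n), n, 2)
  beta <- rnorm(2, 0, beta_sd)
  y <- as.numeric(X %*% beta + rnorm(n, 0, noise_sd))
  list(y = y, X = X)
}
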