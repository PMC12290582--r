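test_that("identical designs give identical evidence and log K = 0", {
  toy <- make_evidence_toy(1)
  l1 <- log_evidence(toy$y, toy$X)
  l2 <- log_evidence(toy$y, toy$X)
  expect_equal(l1, l2)
  bf <- subject_bayes_factor(l1, l2)
  expect_equal(bf$K, 1)
})

test_that("closed-form evidence matches numerical quadrature", {
  for (seed in 1:5) {
    toy <- make_evidence_toy(seed)
    expect_equal(log_evidence(toy$y, toy$X),
                 quad_log_evidence(toy$y, toy$X), tolerance = 1e-3)
  }
  # with different hyperparameters too
  toy <- make_evidence_toy(42)
  expect_equal(log_evidence(toy$y, toy$X, prior_precision = 4, a0 = 0.5,
                            b0 = 0.5),
               quad_log_evidence(toy$y, toy$X, lambda = 4, a0 = 0.5,
                                 b0 = 0.5), tolerance = 1e-3)
})

test_that("evidence is vectorised over voxels and validates input", {
  toy <- make_evidence_toy(2)
  Y <- cbind(toy$y, 2 * toy$y - 1)
  both <- log_evidence(Y, toy$X)
  expect_equal(both[1], log_evidence(toy$y, toy$X))
  expect_equal(both[2], log_evidence(Y[, 2], toy$X))
  expect_error(log_evidence(toy$y, cbind(toy$X, toy$X[, 1])),
               "rank deficient")
  expect_error(log_evidence(toy$y[1:5], toy$X), "match")
})

test_that("irrelevant extra regressors pay an Occam penalty on null data", {
  set.seed(7)
  diffs <- replicate(200, {
    n <- 40
    X_small <- cbind(1, rnorm(n))
    X_big <- cbind(X_small, rnorm(n))
    y <- rnorm(n)
    log_evidence(y, X_small) - log_evidence(y, X_big)
  })
  expect_gt(mean(diffs), 0)
})

test_that("subject Bayes factors classify evidence bands correctly", {
  bf <- subject_bayes_factor(0, log(10))
  expect_equal(bf$K, 10)
  expect_equal(as.character(bf$band), "substantial-h2")
  expect_equal(as.character(subject_bayes_factor(0, log(10) - 1e-9)$band),
               "indeterminate")
  expect_equal(as.character(subject_bayes_factor(0, -log(11))$band),
               "substantial-h1")
  # antisymmetry
  expect_equal(subject_bayes_factor(1.3, 4.2)$K,
               1 / subject_bayes_factor(4.2, 1.3)$K)
})

test_that("group random-effects BMC has the known closed-form limits", {
  # equal evidences: symmetric posterior
  lme <- matrix(0, 8, 2)
  r <- group_rfx_bmc(lme)
  expect_equal(unname(r$expected_prob[1, ]), c(0.5, 0.5))
  expect_equal(unname(r$k_map[1]), 1)

  # saturated responsibilities: alpha approaches (1, 11) for 10 subjects
  # all favouring one model by 10 nats
  lme <- cbind(h1 = rep(0, 10), h2 = rep(10, 10))
  r <- group_rfx_bmc(lme)
  expect_equal(unname(r$alpha[1, ]), c(1, 11), tolerance = 1e-3)
  expect_equal(unname(r$expected_prob[1, "h2"]), 11 / 12, tolerance = 1e-3)

  # shift invariance: adding a constant to one subject's row changes nothing
  set.seed(8)
  lme <- matrix(rnorm(12), 6, 2)
  shifted <- lme
  shifted[3, ] <- shifted[3, ] + 57
  expect_equal(group_rfx_bmc(lme)$alpha, group_rfx_bmc(shifted)$alpha,
               tolerance = 1e-9)
  expect_error(group_rfx_bmc(matrix(0, 1, 2)), "2 subjects")
})

test_that("large prior concentration drives responsibilities to the
           fixed-effects weights monotonically", {
  set.seed(9)
  lme <- matrix(rnorm(10, sd = 2), 5, 2)
  ffx <- t(apply(lme, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
  target <- colSums(ffx)
  dev <- vapply(c(1, 10, 100, 1000), function(a0) {
    r <- group_rfx_bmc(lme, alpha0 = a0)
    sum(abs((r$alpha[1, ] - a0) - target))
  }, numeric(1))
  expect_true(all(diff(dev) < 1e-8))
  expect_lt(dev[4], 1e-3)
})

test_that("posterior summaries report K fractions and stable densities", {
  set.seed(10)
  k_map <- exp(c(rnorm(300, 2, 1), rnorm(100, -2, 1)))
  rfx <- list(k_map = k_map)
  sm <- posterior_probability_summary(rfx, list(a = 1:300, b = 301:400))
  expect_equal(sm$a$n, 300)
  expect_equal(sm$a$fractions[["k_gt_1"]], mean(log(k_map[1:300]) > 0))
  expect_gt(sm$a$fractions[["k_gt_10"]], 0)
  expect_gt(sm$b$fractions[["k_lt_tenth"]], 0)
  # split halves of identical composition are statistically indistinguishable
  half1 <- posterior_probability_summary(rfx, list(h = seq(1, 300, 2)))
  half2 <- posterior_probability_summary(rfx, list(h = seq(2, 300, 2)))
  ks <- suppressWarnings(ks.test(half1$h$log_k, half2$h$log_k))
  expect_gt(ks$p.value, 0.01)
  expect_warning(posterior_probability_summary(rfx, list(e = integer(0))),
                 "empty")
})

test_that("evidence-based model attribution is correct without noise", {
  sched <- cached_schedule(31)$runs[[1]]
  acq <- acquisition_params(noise_sd = 0.01, drift_sd = 0, ar_coefficient = 0)
  run <- simulate_run(sched, data.frame(model = c("h1", "h2"),
                                        scale = c(1, 1)), acq, seed = 12)
  lme <- subject_log_evidence(list(run), acq, prewhiten = FALSE)
  expect_gt(lme[1, "h1"], lme[1, "h2"])
  expect_gt(lme[2, "h2"], lme[2, "h1"])
})
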