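test_that("GLM matches the brute-force normal-equations solution", {
  set.seed(10)
  for (rep in 1:20) {
    X <- cbind(1, matrix(rnorm(50 * 5), 50, 5))
    colnames(X) <- paste0("c", 1:6)
    y <- rnorm(50)
    fit <- fit_glm(matrix(y, 1), X)
    oracle <- normal_equations_fit(y, X)
    expect_equal(as.numeric(fit$betas), as.numeric(oracle),
                 tolerance = 1e-8)
    # residuals orthogonal to every design column
    res <- y - as.numeric(X %*% oracle)
    expect_lt(max(abs(crossprod(X, res))), 1e-8)
  }
})

test_that("design matrices carry the expected condition structure", {
  sched <- cached_schedule(21)$runs[[1]]
  acq <- acquisition_params()
  des <- build_design_matrix(sched, acq)
  expect_equal(des$condition_cols,
               c("std0", "std1", "std1xpos", "std2", "std2xpos",
                 "dev4", "dev5", "dev6"))
  expect_equal(des$n_vol, ceiling(sched$duration / 1000 / acq$tr))
  # number of stimulus events = 8 per trial
  ev <- sched$events[sched$events$condition != "null", ]
  expect_equal(nrow(ev), 8 * nrow(sched$trials))
  # convolved condition regressors correlate moderately but are not collinear
  cc <- cor(des$X[, c("std0", "std1", "std2", "dev4", "dev5", "dev6")])
  off <- abs(cc[upper.tri(cc)])
  expect_true(all(off < 0.95))
  expect_gt(mean(off), 0.1)
})

test_that("split-by-class designs expose one condition set per sweep pairing", {
  sched <- cached_schedule(21)$runs[[1]]
  des <- build_design_matrix(sched, split_by_class = TRUE)
  expect_equal(length(des$condition_cols), 18)
  expect_true(all(c("dev4@100", "std0@300", "std2@400") %in%
                    des$condition_cols))
})

test_that("rank deficiency and misalignment are reported", {
  sched <- cached_schedule(21)$runs[[1]]
  des <- build_design_matrix(sched)
  dup <- cbind(des$X, copy = des$X[, "std0"])
  expect_error(fit_glm(matrix(rnorm(nrow(dup)), 1), dup), "rank deficient")
  expect_error(fit_glm(matrix(rnorm(10), 1), des), "time axes")
  expect_error(build_design_matrix(sched,
                                   nuisance = matrix(0, 3, 1)), "row per")
})

test_that("AR(1) prewhitening recovers the pooled noise coefficient", {
  sched <- cached_schedule(21)$runs[[1]]
  acq <- acquisition_params(noise_sd = 1, ar_coefficient = 0.45,
                            drift_sd = 0)
  run <- simulate_run(sched, data.frame(model = rep("null", 40),
                                        scale = 0), acq, seed = 8)
  des <- build_design_matrix(sched, acq)
  fit <- fit_glm(run, des, prewhiten = TRUE)
  expect_lt(abs(fit$rho - 0.45), 0.1)
})

test_that("z-scoring normalises the pooled betas and rejects degenerate pools", {
  set.seed(3)
  B <- matrix(rnorm(60, mean = 4, sd = 2), 10, 6,
              dimnames = list(NULL, paste0("c", 1:6)))
  z <- zscore_betas(B)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(as.vector(z)), 1, tolerance = 1e-12)
  expect_equal(zscore_betas(z), z, tolerance = 1e-12)  # idempotent
  expect_error(zscore_betas(matrix(2, 4, 3)), "zero variance")
})

test_that("the SSA index follows its defining formula", {
  expect_equal(ssa_index(1, 1, 1), 0)
  expect_equal(ssa_index(1, 0.5, 0.5), 1 / 3)
  expect_equal(ssa_index(3, 1, 1), 0.5)
  # SI > 0 exactly when the deviant exceeds the mean repeated standard
  set.seed(4)
  dev <- runif(50); s1 <- runif(50); s2 <- runif(50)
  si <- ssa_index(dev, s1, s2)
  expect_equal(si > 0, dev > (s1 + s2) / 2)
  expect_warning(out <- ssa_index(1, -1, -1), "undefined")
  expect_true(is.na(out))
})

test_that("the group rank test is exact, symmetric and null-calibrated", {
  vals <- matrix(0, 18, 3)
  expect_equal(group_voxelwise_test(vals), rep(1, 3))
  # 18 strongly positive subjects reach the smallest achievable two-tailed p
  strong <- matrix(5 + runif(18), 18, 1)
  expect_equal(group_voxelwise_test(strong)[1], 2 / 2^18, tolerance = 1e-10)
  set.seed(5)
  v <- matrix(rnorm(18 * 4), 18, 4)
  expect_equal(group_voxelwise_test(v), group_voxelwise_test(-v))
  expect_error(group_voxelwise_test(matrix(1, 1, 2)), "2 subjects")
})

test_that("FDR thresholding implements the step-up rule over its scope", {
  expect_true(all(fdr_threshold(rep(0.001, 30))))
  expect_true(fdr_threshold(0.04))            # single test: raw threshold
  expect_false(fdr_threshold(0.06))
  p <- c(0.001, 0.2, 0.5, 0.9)
  expect_equal(fdr_threshold(p, scope = 1:4),
               stats::p.adjust(p, "BH") <= 0.05)
  # out-of-scope voxels never survive
  m <- fdr_threshold(rep(0.001, 10), scope = 3:5)
  expect_equal(which(m), 3:5)
  expect_warning(empty <- fdr_threshold(p, scope = integer(0)), "empty")
  expect_false(any(empty))
})

test_that("SSA maps take the voxelwise maximum p and respect scopes", {
  adapt <- c(0.001, 0.2, 0.01)
  devd <- c(0.2, 0.001, 0.01)
  cm <- ssa_mask(adapt, devd, alpha = 0.05)
  expect_equal(cm$ssa_p, c(0.2, 0.2, 0.01))
  expect_true(cm$masks$ssa[3])
  expect_false(any(cm$masks$ssa[1:2]))
  expect_true(cm$contract_ok)
  expect_error(ssa_mask(adapt, devd[1:2]), "misaligned")
})

test_that("volume-matched ROI selection equals both oracles", {
  set.seed(6)
  stat <- c(runif(200))
  prior <- sort(sample(200, 100))
  roi <- define_roi(prior, stat, 10)
  expect_equal(roi, sort(prior[order(-stat[prior])[1:10]]))
  expect_equal(roi, iterative_threshold_roi(prior, stat, 10))
  # invariance to monotone transforms and the full-prior edge case
  expect_equal(define_roi(prior, exp(3 * stat), 10), roi)
  expect_equal(define_roi(prior, stat, 100), prior)
  expect_error(define_roi(prior, stat, 101), "exceeds")
  # deterministic tie-breaking by ascending voxel index
  tied <- rep(1, 200)
  expect_equal(define_roi(prior, tied, 5), prior[1:5])
})
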