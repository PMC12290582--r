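test_that("the canonical HRF peaks near 5 s, starts at 0 and dies out", {
  h <- canonical_hrf(dt = 0.1)
  t <- (seq_along(h) - 1) * 0.1
  expect_equal(t[which.max(h)], 5, tolerance = 0.11)
  expect_equal(h[1], 0)
  expect_equal(max(h), 1)
  expect_lt(max(abs(h[t > 31])), 0.01)
  # sampled at the repetition time the peak lands within one sample of 5 s
  h_tr <- canonical_hrf(dt = 1.9)
  expect_lte(abs((which.max(h_tr) - 1) * 1.9 - 5), 1.9)
})

test_that("noise-free simulation is a pure scaled model response", {
  sched <- cached_schedule(11)$runs[[1]]
  acq <- acquisition_params(noise_sd = 0, drift_sd = 0)
  null_run <- simulate_voxel(sched, model = "null", scale = 0, acq = acq)
  expect_true(all(null_run$data == acq$baseline))

  one <- simulate_voxel(sched, model = "h2", scale = 1, acq = acq)
  two <- simulate_voxel(sched, model = "h2", scale = 2, acq = acq)
  expect_equal(2 * (one$data - acq$baseline), two$data - acq$baseline,
               tolerance = 1e-12)
})

test_that("noiseless GLM recovers generating amplitudes exactly", {
  # generate data inside the design span: amplitudes per condition plus a
  # linear position modulation, i.e. exactly what the design models
  sched <- cached_schedule(11)$runs[[1]]
  acq <- acquisition_params(noise_sd = 0, drift_sd = 0)
  des <- build_design_matrix(sched, acq)
  beta_true <- c(1.2, 0.8, -0.1, 0.5, 0.05, 1.5, 1.0, 0.3)
  names(beta_true) <- des$condition_cols
  y <- as.numeric(des$X[, des$condition_cols] %*% beta_true) + 50
  fit <- fit_glm(matrix(y, 1), des)
  expect_equal(fit$betas[1, des$condition_cols], beta_true,
               tolerance = 1e-8)
  expect_equal(unname(fit$betas[1, "intercept"]), 50, tolerance = 1e-8)
})

test_that("cohort simulation is deterministic and carries ground truth", {
  ph <- make_phantom(grid = c(3, 2, 1), region_sizes = c("IC-L" = 4),
                     generating_model = "h2")
  a <- simulate_cohort(2, 1, ph, acquisition_params(noise_sd = 1), seed = 4,
                       params = small_params())
  b <- simulate_cohort(2, 1, ph, acquisition_params(noise_sd = 1), seed = 4,
                       params = small_params())
  expect_identical(a$subjects[[2]]$runs[[1]]$data,
                   b$subjects[[2]]$runs[[1]]$data)
  expect_equal(a$phantom$model, c(rep("h2", 4), rep("null", 2)))
  # schedules differ between subjects
  expect_false(identical(a$subjects[[1]]$schedule$runs[[1]]$events$onset,
                         a$subjects[[2]]$schedule$runs[[1]]$events$onset))
  expect_error(simulate_cohort(1, 1, ph, params = small_params()),
               "at least 2")
})

test_that("phantom construction partitions the grid as requested", {
  ph <- make_phantom(grid = c(12, 12, 6))
  expect_equal(sum(ph$region == "IC-L"), 146)
  expect_equal(sum(ph$region == "MGB-R"), 152)
  expect_equal(sum(ph$region == "background"), 12 * 12 * 6 - 2 * 146 - 2 * 152)
  expect_true(all(ph$model[ph$region == "background"] == "null"))
  expect_equal(sum(ph$subdivision == "ventral", na.rm = TRUE), 152)
  expect_error(make_phantom(grid = c(2, 2, 2)), "cannot hold")

  rois <- phantom_rois(ph)
  expect_equal(lengths(rois)[c("IC-L", "MGB-L")], c("IC-L" = 146L,
                                                    "MGB-L" = 152L))
})

test_that("phantom maps round-trip through NIfTI volumes", {
  ph <- make_phantom(grid = c(4, 3, 2), region_sizes = c("IC-L" = 5))
  path <- withr::local_tempfile(fileext = ".nii")
  vals <- seq_len(nrow(ph)) / 7
  write_phantom_map(vals, ph, path)
  expect_equal(read_phantom_map(path), vals, tolerance = 1e-6)
})

test_that("the localizer produces the blocked sound/silence structure", {
  ph <- make_phantom(grid = c(4, 2, 1), region_sizes = c("IC-L" = 4),
                     generating_model = "h2")
  acq <- acquisition_params(noise_sd = 0, drift_sd = 0)
  loc <- simulate_localizer(ph, acq, seed = 1)
  expect_equal(nrow(loc$events), 20)
  expect_equal(sum(loc$events$condition == "silence"), 10)
  expect_equal(max(loc$events$onset + loc$events$duration), 320)

  con <- localizer_contrast(loc)
  expect_true(all(con$beta[ph$region == "IC-L"] > 0))
  expect_equal(con$beta[ph$region == "background"], rep(0, 4),
               tolerance = 1e-10)
})

test_that("volume-matched ROIs recover auditory voxels from the localizer", {
  ph <- make_phantom(grid = c(6, 4, 2), region_sizes = c("IC-L" = 10),
                     generating_model = "h2")
  loc <- simulate_localizer(ph, acquisition_params(noise_sd = 0.5),
                            seed = 2, scale = 2)
  con <- localizer_contrast(loc)
  prior <- dilate_mask(which(ph$region == "IC-L"), ph, radius = 1)
  roi <- define_roi(prior, con$tstat, 10)
  expect_equal(roi, which(ph$region == "IC-L"))
})
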