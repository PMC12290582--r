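test_that("deviant hazards match brute-force enumeration and the rules", {
  for (k in 4:6) {
    expect_equal(deviant_hazard(k), enumerate_hazard(k))
  }
  expect_equal(deviant_hazard(4), 1 / 3)
  expect_equal(deviant_hazard(5), 1 / 2)
  expect_equal(deviant_hazard(6), 1)
  # non-uniform prior still renormalises over the remaining positions
  m <- expectation_model(4:6, c(0.5, 0.25, 0.25))
  expect_equal(deviant_hazard(5, m), 0.5)
  expect_equal(deviant_hazard(6, m), 1)
  expect_error(deviant_hazard(3), "candidate")
})

test_that("sequence duration and onsets follow the fixed sequence grammar", {
  expect_equal(sequence_duration(), 5300)
  expect_equal(sequence_duration(8, 0, 0), 0)
  on <- stimulus_onsets()
  expect_equal(on[1], 0)
  expect_equal(on, (0:7) * 750)
  expect_equal(diff(on), rep(750, 7))
})

test_that("default sweeps carry the three frequency spans", {
  sw <- default_sweeps()
  expect_equal(sw$fast_up$delta_f, 200)
  expect_equal(sw$slow_up$delta_f, 100)
  expect_equal(sw$fast_down$delta_f, -200)
  expect_equal(sw$fast_down$f_start - sw$fast_down$f_end, 200)
  for (s in sw) {
    expect_equal(s$total_duration,
                 2 * s$plateau_duration + s$sweep_duration)
  }
  expect_error(sweep_spec("bad", 1000, 1200, ramp_duration = 10), "ramp")
  expect_error(sweep_spec("bad", 1000, 1200, total_duration = 60), "total")
})

test_that("inter-trial timing respects the truncation and the ITI floor", {
  p <- paradigm_params()
  set.seed(1)
  draws <- fmadapt:::rtruncnorm(1e5, p$idi_mean, p$idi_sd, p$idi_lower,
                                p$idi_upper)
  expect_true(all(draws >= 3000 & draws <= 11000))
  # analytic mean of the truncated normal (a, b are standardised bounds)
  a <- (3000 - 5000) / 1000; b <- (11000 - 5000) / 1000
  mu_trunc <- 5000 + 1000 * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  expect_equal(mean(draws), mu_trunc, tolerance = 0.005)

  set.seed(2)
  tm <- sample_intertrial_timing(4, 6, p, n = 500)
  expect_true(all(tm$iti >= 1500))
  expect_equal(tm$idi, tm$iti + (5300 - 3 * 750) + 5 * 750)

  # force the draw to the lower truncation bound: positions (6, 4) leave
  # 1550 + 2250 = 3800 ms of within-sequence time, so a 3000 ms target IDI
  # is infeasible and the ITI clamps to its floor exactly
  forced <- paradigm_params(idi_mean = 3000, idi_sd = 1e-9,
                            idi_upper = 3000.001)
  tm <- sample_intertrial_timing(6, 4, forced)
  expect_equal(tm$iti, 1500)
  expect_equal(tm$idi, 1500 + (5300 - 5 * 750) + 3 * 750)

  expect_error(sample_intertrial_timing(4, 5, paradigm_params(
    idi_lower = 5000, idi_upper = 3000)), "bounds")
  expect_error(sample_intertrial_timing(3, 5), "positions")
})

test_that("a full experiment satisfies all count invariants", {
  for (seed in c(1, 99)) {
    ex <- build_experiment(seed)
    tr <- do.call(rbind, lapply(ex$runs, `[[`, "trials"))
    expect_equal(nrow(tr), 540)
    expect_equal(unname(table(tr$deviant_position)), rep(180L, 3),
                 ignore_attr = TRUE)
    cell <- table(tr$deviant_position, tr$delta_class)
    expect_true(all(cell == 60))
    # each run: 6 blocks of 10 trials, one ordered pair per block, all 6
    # ordered pairs present
    for (run in ex$runs) {
      expect_equal(nrow(run$trials), 60)
      per_block <- unique(run$trials[, c("block", "standard", "deviant")])
      expect_equal(nrow(per_block), 6)
      pairs <- fmadapt:::ordered_pairs(default_sweeps())
      expect_equal(sort(paste(per_block$standard, per_block$deviant)),
                   sort(paste(pairs$standard, pairs$deviant)))
      expect_equal(length(run$null_onsets), 23)
      expect_true(all(run$events$duration[run$events$condition == "null"]
                      == 5.3))
    }
  }
})

test_that("schedules are deterministic in the seed and vary across seeds", {
  a <- build_experiment(5)
  b <- build_experiment(5)
  c <- build_experiment(6)
  expect_identical(a$runs[[2]]$events, b$runs[[2]]$events)
  expect_false(identical(a$runs[[2]]$events$onset, c$runs[[2]]$events$onset))
  # different seeds still satisfy identical count invariants
  trc <- do.call(rbind, lapply(c$runs, `[[`, "trials"))
  expect_equal(unname(table(trc$deviant_position)), rep(180L, 3),
               ignore_attr = TRUE)
})

test_that("events on a run timeline never overlap", {
  ex <- cached_schedule(3)
  ev <- ex$runs[[1]]$events
  ev <- ev[order(ev$onset), ]
  gaps <- ev$onset[-1] - (ev$onset[-nrow(ev)] + ev$duration[-nrow(ev)])
  expect_true(all(gaps >= -1e-9))
})

test_that("unbalanceable designs raise a configuration error", {
  expect_error(build_experiment(1, paradigm_params(n_runs = 1)),
               "divisible")
  expect_error(build_experiment(1, paradigm_params(blocks_per_run = 5)),
               "ordered sweep pairs")
})

test_that("event tables round-trip through tab-separated files", {
  ex <- cached_schedule(3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_events(ex$runs[[1]]$events, path)
  back <- read_events(path)
  expect_equal(back$onset, ex$runs[[1]]$events$onset)
  expect_equal(back$condition, ex$runs[[1]]$events$condition)
})
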