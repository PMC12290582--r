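# Synthetic BOLD generation: single voxels, whole runs, cohorts and the
# blocked sound/silence localizer, all with recorded ground truth.

#' Acquisition and noise parameters for simulated BOLD runs
#'
#' @param tr Repetition time (s).
#' @param dt Microtime resolution used for convolution (s).
#' @param noise_sd Marginal standard deviation of the AR(1) noise, in the
#'   same response units as the event amplitudes. The default together with
#'   unit event amplitude gives the reference per-event SNR of 0.5.
#' @param ar_coefficient AR(1) coefficient of the noise, in `[0, 1)`.
#' @param drift_order Polynomial drift order included in the simulation (and
#'   matched in the design matrix).
#' @param drift_sd Standard deviation of the random drift coefficients.
#' @param baseline Constant signal baseline.
#' @return Named list of acquisition parameters.
#' @export
acquisition_params <- function(tr = 1.9, dt = 0.1, noise_sd = 2,
                               ar_coefficient = 0.3, drift_order = 1,
                               drift_sd = 0.5, baseline = 100) {
  stopifnot(tr > 0, dt > 0, abs(ar_coefficient) < 1, noise_sd >= 0,
            drift_order >= 0)
  list(tr = tr, dt = dt, noise_sd = noise_sd,
       ar_coefficient = ar_coefficient, drift_order = drift_order,
       drift_sd = drift_sd, baseline = baseline)
}

n_volumes <- function(schedule, acq) {
  as.integer(ceiling(schedule$duration / 1000 / acq$tr))
}

# Stimulus events of a run with per-event amplitudes under a response model.
# Returns onsets (s) and amplitudes; the unit-parameter profile of the
# generating model supplies the amplitude of each slot given the trial's
# deviant position.
model_event_train <- function(schedule, model) {
  ev <- schedule$events[schedule$events$condition != "null", ]
  prof <- lapply(stats::setNames(4:6, 4:6), function(p) {
    if (model == "h1") as.numeric(h1_profile(p)) else
      as.numeric(h2_profile(p))
  })
  pos <- schedule$trials$deviant_position[ev$trial]
  amp <- vapply(seq_len(nrow(ev)), function(i) {
    prof[[as.character(pos[i])]][ev$slot[i]]
  }, numeric(1))
  list(onsets = ev$onset, amplitudes = amp)
}

# Noise-free unit-scale signal of a generating model for one run, sampled at
# volume times. "null" gives zeros.
model_signal <- function(schedule, model, acq) {
  nv <- n_volumes(schedule, acq)
  if (model == "null") return(numeric(nv))
  tr_ev <- model_event_train(schedule, model)
  event_regressor(tr_ev$onsets, tr_ev$amplitudes, nv, acq$tr, acq$dt)
}

# Orthonormal polynomial drift basis (without intercept).
drift_basis <- function(n_vol, order) {
  if (order < 1) return(matrix(0, n_vol, 0))
  stats::poly(seq_len(n_vol), degree = order, raw = FALSE) * sqrt(n_vol)
}

ar1_noise <- function(n, sd, phi) {
  if (sd == 0) return(numeric(n))
  innov <- stats::rnorm(n, 0, sd * sqrt(1 - phi^2))
  as.numeric(stats::filter(innov, phi, method = "recursive"))
}

#' Simulate one run of voxel timecourses
#'
#' Each voxel's signal is `baseline + scale * s_m(t) + drift + AR(1) noise`,
#' where `s_m` is the voxel's generating-model response train (unit-parameter
#' amplitude profile at each stimulus, convolved with the canonical HRF and
#' sampled at volume times).
#'
#' @param schedule A `run_schedule`.
#' @param voxels Data frame with columns `model` (`"h1"`, `"h2"`, `"null"`)
#'   and `scale`; typically a [make_phantom()] phantom (or a subset of its
#'   rows).
#' @param acq [acquisition_params()].
#' @param seed Integer seed for the noise and drift draws.
#' @param run_id,subject_id Identifiers carried into the result.
#' @return A `bold_run`: list with `data` (voxel x time matrix), `events`,
#'   `schedule`, `acq`, `truth` (the `voxels` input) and ids.
#' @export
simulate_run <- function(schedule, voxels, acq = acquisition_params(),
                         seed = 1, run_id = schedule$run_id,
                         subject_id = "sub-01") {
  stopifnot(inherits(schedule, "run_schedule"),
            all(c("model", "scale") %in% names(voxels)))
  nv <- n_volumes(schedule, acq)
  n_vox <- nrow(voxels)
  signals <- lapply(stats::setNames(nm = unique(voxels$model)),
                    function(m) model_signal(schedule, m, acq))
  drift <- drift_basis(nv, acq$drift_order)
  Y <- with_seed(seed, {
    out <- matrix(0, n_vox, nv)
    for (v in seq_len(n_vox)) {
      dc <- if (ncol(drift) > 0)
        drift %*% stats::rnorm(ncol(drift), 0, acq$drift_sd) else 0
      out[v, ] <- acq$baseline +
        voxels$scale[v] * signals[[voxels$model[v]]] +
        as.numeric(dc) + ar1_noise(nv, acq$noise_sd, acq$ar_coefficient)
    }
    out
  })
  structure(list(data = Y, events = schedule$events, schedule = schedule,
                 acq = acq, truth = voxels, run_id = run_id,
                 subject_id = subject_id),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  cat(sprintf("<bold_run %s/%s> %d voxels x %d volumes (TR %.2g s)\n",
              x$subject_id, x$run_id, nrow(x$data), ncol(x$data), x$acq$tr))
  invisible(x)
}

#' Simulate a single voxel
#'
#' Convenience wrapper around [simulate_run()] for one voxel.
#'
#' @inheritParams simulate_run
#' @param model Generating model tag (`"h1"`, `"h2"`, `"null"`).
#' @param scale Response scale (0 gives pure baseline + noise + drift).
#' @return A `bold_run` with a single row of data.
#' @export
simulate_voxel <- function(schedule, model = "h2", scale = 1,
                           acq = acquisition_params(), seed = 1) {
  simulate_run(schedule, data.frame(model = model, scale = scale), acq,
               seed = seed)
}

#' Simulate a multi-subject cohort with ground truth
#'
#' Every subject receives an independent experiment schedule (its own block
#' order, deviant pseudorandomisation and timing jitter) and independent
#' noise. Defaults reproduce the study conditions: 18 subjects with 9 runs
#' each.
#'
#' @param n_subjects Number of subjects (at least 2).
#' @param runs_per_subject Runs per subject.
#' @param phantom [make_phantom()] phantom giving each voxel's generating
#'   model and scale.
#' @param acq [acquisition_params()].
#' @param seed Master seed.
#' @param params [paradigm_params()]; `n_runs` is overridden by
#'   `runs_per_subject`.
#' @return A `bold_cohort`: list with `subjects` (each holding `schedule`
#'   and a list of `bold_run`s), the `phantom` (ground-truth record), `acq`
#'   and `seed`.
#' @export
simulate_cohort <- function(n_subjects = 18, runs_per_subject = 9,
                            phantom = make_phantom(),
                            acq = acquisition_params(), seed = 1,
                            params = paradigm_params()) {
  if (n_subjects < 2) stop("a cohort needs at least 2 subjects")
  params$n_runs <- runs_per_subject
  subjects <- lapply(seq_len(n_subjects), function(s) {
    sid <- sprintf("sub-%02d", s)
    sched <- build_experiment(substream_seed(seed, paste0("schedule:", sid)),
                              params)
    runs <- lapply(seq_len(runs_per_subject), function(r) {
      simulate_run(sched$runs[[r]], phantom, acq,
                   seed = substream_seed(seed, paste0("noise:", sid,
                                                      ":run", r)),
                   subject_id = sid)
    })
    list(subject_id = sid, schedule = sched, runs = runs)
  })
  structure(list(subjects = subjects, phantom = phantom, acq = acq,
                 seed = seed),
            class = "bold_cohort")
}

#' @export
print.bold_cohort <- function(x, ...) {
  cat(sprintf("<bold_cohort> %d subjects x %d runs, %d voxels (seed %d)\n",
              length(x$subjects), length(x$subjects[[1]]$runs),
              nrow(x$phantom), x$seed))
  invisible(x)
}

#' Simulate a blocked sound/silence localizer run
#'
#' Alternating 16 s blocks, half of them silent (20 blocks by default).
#' Auditory-labelled voxels (any non-background region) respond to the sound
#' blocks; background voxels carry only baseline, drift and noise.
#'
#' @param phantom [make_phantom()] phantom.
#' @param acq [acquisition_params()].
#' @param seed Integer seed.
#' @param n_blocks Total number of blocks (even; half silent).
#' @param block_duration Block duration (s).
#' @param scale Response amplitude of auditory voxels to the sound boxcar.
#' @return A `bold_run` whose `events` table holds the sound/silence blocks.
#' @export
simulate_localizer <- function(phantom, acq = acquisition_params(),
                               seed = 1, n_blocks = 20, block_duration = 16,
                               scale = 1) {
  stopifnot(n_blocks %% 2 == 0)
  onset <- (seq_len(n_blocks) - 1) * block_duration
  condition <- rep(c("sound", "silence"), n_blocks / 2)
  events <- data.frame(onset = onset, duration = block_duration,
                       condition = condition)
  dur_s <- n_blocks * block_duration + 16
  nv <- as.integer(ceiling(dur_s / acq$tr))
  # boxcar at microtime resolution, convolved and sampled at volume times
  n_fine <- ceiling(nv * acq$tr / acq$dt) + 1L
  box <- numeric(n_fine)
  for (i in which(condition == "sound")) {
    i0 <- floor(onset[i] / acq$dt) + 1L
    i1 <- min(floor((onset[i] + block_duration) / acq$dt), n_fine)
    box[i0:i1] <- 1
  }
  conv <- convolve_kernel(box, canonical_hrf(dt = acq$dt))
  vol_idx <- pmin(round((seq_len(nv) - 1) * acq$tr / acq$dt) + 1L, n_fine)
  sound_reg <- conv[vol_idx]

  drift <- drift_basis(nv, acq$drift_order)
  auditory <- phantom$region != "background"
  Y <- with_seed(seed, {
    out <- matrix(0, nrow(phantom), nv)
    for (v in seq_len(nrow(phantom))) {
      dc <- if (ncol(drift) > 0)
        drift %*% stats::rnorm(ncol(drift), 0, acq$drift_sd) else 0
      out[v, ] <- acq$baseline +
        (if (auditory[v]) scale * sound_reg else 0) +
        as.numeric(dc) + ar1_noise(nv, acq$noise_sd, acq$ar_coefficient)
    }
    out
  })
  structure(list(data = Y, events = events, schedule = NULL, acq = acq,
                 truth = phantom, run_id = "localizer",
                 subject_id = "sub-01", sound_regressor = sound_reg,
                 drift = drift),
            class = "bold_run")
}

#' Sound-versus-silence contrast of a localizer run
#'
#' Fits `y ~ sound regressor + drift + intercept` per voxel and returns the
#' sound-effect t statistic, used to carve volume-matched functional ROIs
#' out of the prior masks.
#'
#' @param localizer A [simulate_localizer()] result.
#' @return Data frame with per-voxel `beta` and `tstat`.
#' @export
localizer_contrast <- function(localizer) {
  X <- cbind(intercept = 1, sound = localizer$sound_regressor,
             localizer$drift)
  qrX <- qr(X)
  coefs <- qr.coef(qrX, t(localizer$data))
  res <- qr.resid(qrX, t(localizer$data))
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / df
  XtX_inv <- solve(crossprod(X))
  se <- sqrt(sigma2 * XtX_inv[2, 2])
  data.frame(beta = coefs["sound", ], tstat = coefs["sound", ] / se)
}
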