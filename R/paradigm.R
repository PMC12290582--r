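# Experimental paradigm: FM-sweep combinations, oddball trial sequences,
# deviant-position expectation model, jittered inter-trial timing.

#' Specify an FM-sweep stimulus
#'
#' A sweep is a short sinusoid whose instantaneous frequency moves linearly
#' from `f_start` to `f_end` during the sweep segment, flanked by
#' constant-frequency plateaus that overlap the on/off amplitude ramps.
#'
#' @param label Short name for the sweep.
#' @param f_start,f_end Start and end frequency of the sweep segment (Hz).
#' @param total_duration Total stimulus duration (ms).
#' @param sweep_duration Duration of the frequency-modulated segment (ms).
#' @param plateau_duration Duration of each constant-frequency flank (ms).
#' @param ramp_duration Raised-cosine on/off ramp duration (ms); ramps overlap
#'   the plateaus and must not exceed them.
#' @return A `sweep_spec` object with derived field `delta_f = f_end - f_start`.
#' @examples
#' sweep_spec("fast_up", 1000, 1200)
#' @export
sweep_spec <- function(label, f_start, f_end,
                       total_duration = 50, sweep_duration = 40,
                       plateau_duration = 5, ramp_duration = 5) {
  stopifnot(is.character(label), length(label) == 1L,
            f_start > 0, f_end > 0)
  if (any(c(total_duration, sweep_duration, plateau_duration,
            ramp_duration) <= 0)) {
    stop("all durations must be positive")
  }
  if (abs(total_duration - (2 * plateau_duration + sweep_duration)) > 1e-9) {
    stop("total_duration must equal sweep_duration + 2 * plateau_duration")
  }
  if (ramp_duration > plateau_duration + 1e-9) {
    stop("ramp_duration must not exceed plateau_duration")
  }
  structure(
    list(label = label, f_start = f_start, f_end = f_end,
         delta_f = f_end - f_start,
         total_duration = total_duration, sweep_duration = sweep_duration,
         plateau_duration = plateau_duration, ramp_duration = ramp_duration),
    class = "sweep_spec")
}

#' @export
print.sweep_spec <- function(x, ...) {
  cat(sprintf("<sweep_spec '%s'> %g -> %g Hz (delta_f = %+g Hz), %g ms\n",
              x$label, x$f_start, x$f_end, x$delta_f, x$total_duration))
  invisible(x)
}

#' The three FM-sweeps of the paradigm
#'
#' Fast up (1000 to 1200 Hz), slow up (1070 to 1170 Hz) and fast down
#' (1280 to 1080 Hz); all 50 ms long with a 40 ms sweep segment and 5 ms
#' constant-frequency flanks. Average frequencies differ so that the three
#' sweeps are pitch-matched; they are distinguishable only by FM direction
#' and/or FM rate.
#'
#' @return Named list of three [sweep_spec()] objects
#'   (`fast_up`, `slow_up`, `fast_down`).
#' @export
default_sweeps <- function() {
  list(fast_up   = sweep_spec("fast_up",   1000, 1200),
       slow_up   = sweep_spec("slow_up",   1070, 1170),
       fast_down = sweep_spec("fast_down", 1280, 1080))
}

#' Abstract-rule expectation model for the deviant position
#'
#' Listeners are told that every sequence holds exactly one deviant and that
#' it sits in one of `candidate_positions`, each a priori equally likely.
#'
#' @param candidate_positions Integer vector of allowed deviant positions.
#' @param prior Prior probability of each position; must sum to 1.
#' @return An `expectation_model` object.
#' @export
expectation_model <- function(candidate_positions = 4:6,
                              prior = rep(1 / length(candidate_positions),
                                          length(candidate_positions))) {
  stopifnot(length(candidate_positions) == length(prior),
            all(prior >= 0), abs(sum(prior) - 1) < 1e-12)
  structure(list(candidate_positions = as.integer(candidate_positions),
                 prior = prior),
            class = "expectation_model")
}

#' Conditional probability of a deviant at a position (hazard)
#'
#' Probability that the deviant occupies `position` given that all earlier
#' candidate positions held standards: `prior(position)` renormalised over
#' the positions not yet ruled out. With the default uniform prior over
#' positions 4--6 the hazards are 1/3, 1/2 and 1.
#'
#' @param position Candidate deviant position.
#' @param model An [expectation_model()].
#' @return Probability in (0, 1].
#' @examples
#' deviant_hazard(5)  # 1/2
#' @export
deviant_hazard <- function(position, model = expectation_model()) {
  idx <- match(position, model$candidate_positions)
  if (any(is.na(idx))) {
    stop("position ", paste(position[is.na(idx)], collapse = ", "),
         " is not a candidate deviant position")
  }
  vapply(idx, function(i) {
    model$prior[i] / sum(model$prior[seq(i, length(model$prior))])
  }, numeric(1))
}

#' Duration of one trial's tone sequence
#'
#' Eight stimuli separated by a fixed inter-stimulus interval:
#' `n * stimulus_duration + (n - 1) * isi`. This is also the duration used
#' for silent null events.
#'
#' @param n_stimuli Stimuli per sequence.
#' @param stimulus_duration Stimulus duration (ms).
#' @param isi Inter-stimulus interval (ms).
#' @return Duration in ms (5300 under defaults).
#' @export
sequence_duration <- function(n_stimuli = 8, stimulus_duration = 50,
                              isi = 700) {
  stopifnot(n_stimuli >= 1)
  n_stimuli * stimulus_duration + (n_stimuli - 1) * isi
}

#' Stimulus onsets within a trial sequence
#'
#' @inheritParams sequence_duration
#' @return Onsets in ms relative to sequence start; first onset at 0, constant
#'   spacing `stimulus_duration + isi`.
#' @export
stimulus_onsets <- function(n_stimuli = 8, stimulus_duration = 50,
                            isi = 700) {
  (seq_len(n_stimuli) - 1) * (stimulus_duration + isi)
}

#' Paradigm parameters
#'
#' Defaults describe the full design: 9 runs of 6 blocks by 10 trials
#' (each block a single ordered standard/deviant pair, all 6 pairs once per
#' run), 23 null events per run with the duration of one tone sequence, and
#' inter-deviant intervals drawn from a normal distribution with mean 5 s and
#' SD 1 s truncated to [3, 11] s, with inter-trial intervals floored at 1.5 s.
#'
#' @param n_runs,blocks_per_run,trials_per_block,nulls_per_run Design counts.
#' @param n_stimuli Stimuli per sequence.
#' @param isi Inter-stimulus interval (ms).
#' @param idi_mean,idi_sd,idi_lower,idi_upper Truncated-normal parameters of
#'   the target inter-deviant interval (ms).
#' @param iti_min Minimum inter-trial interval (ms).
#' @param run_tail Silent tail appended after the last event (ms) so that the
#'   final haemodynamic response is sampled.
#' @param sweeps List of three [sweep_spec()] objects.
#' @return Named list of parameters.
#' @export
paradigm_params <- function(n_runs = 9, blocks_per_run = 6,
                            trials_per_block = 10, nulls_per_run = 23,
                            n_stimuli = 8, isi = 700,
                            idi_mean = 5000, idi_sd = 1000,
                            idi_lower = 3000, idi_upper = 11000,
                            iti_min = 1500, run_tail = 16000,
                            sweeps = default_sweeps()) {
  list(n_runs = n_runs, blocks_per_run = blocks_per_run,
       trials_per_block = trials_per_block, nulls_per_run = nulls_per_run,
       n_stimuli = n_stimuli, isi = isi,
       idi_mean = idi_mean, idi_sd = idi_sd,
       idi_lower = idi_lower, idi_upper = idi_upper,
       iti_min = iti_min, run_tail = run_tail, sweeps = sweeps)
}

# Onset of the deviant within its sequence (ms from sequence start),
# onset-to-onset convention.
deviant_onset_within_sequence <- function(position, params) {
  stim_dur <- params$sweeps[[1]]$total_duration
  (position - 1) * (stim_dur + params$isi)
}

#' Sample the jittered gap between two consecutive trials
#'
#' A target inter-deviant interval (IDI, deviant onset to deviant onset) is
#' drawn from the truncated normal distribution; the inter-trial interval
#' (ITI) that realises it is derived from the deviant positions of the two
#' trials and floored at `iti_min`, after which the realised IDI is
#' recomputed from the clamped ITI.
#'
#' @param pos_current,pos_next Deviant positions of the current and next
#'   trial.
#' @param params [paradigm_params()].
#' @param n Number of draws.
#' @return List with `iti` (clamped, ms), `idi` (realised, ms) and
#'   `idi_target` (the raw truncated-normal draw, ms).
#' @export
sample_intertrial_timing <- function(pos_current, pos_next,
                                     params = paradigm_params(), n = 1) {
  model <- expectation_model()
  if (!all(c(pos_current, pos_next) %in% model$candidate_positions)) {
    stop("deviant positions must lie in {4, 5, 6}")
  }
  idi_target <- rtruncnorm(n, params$idi_mean, params$idi_sd,
                           params$idi_lower, params$idi_upper)
  seq_dur <- sequence_duration(params$n_stimuli,
                               params$sweeps[[1]]$total_duration, params$isi)
  after_dev <- seq_dur - deviant_onset_within_sequence(pos_current, params)
  next_onset <- deviant_onset_within_sequence(pos_next, params)
  iti <- pmax(idi_target - after_dev - next_onset, params$iti_min)
  list(iti = iti, idi = iti + after_dev + next_onset,
       idi_target = idi_target)
}

# Label the 8 slots of a sequence given the deviant position:
# slot 1 = std0, slots before the deviant = std1, the deviant slot = dev<p>,
# slots after the deviant = std2. The parametric value is the raw
# within-sequence position for std1/std2 (mean-centred later, at design time).
slot_conditions <- function(position, n_stimuli = 8) {
  stopifnot(position %in% 4:6)
  cond <- character(n_stimuli)
  cond[1] <- "std0"
  cond[seq(2, position - 1)] <- "std1"
  cond[position] <- paste0("dev", position)
  if (position < n_stimuli) cond[seq(position + 1, n_stimuli)] <- "std2"
  value <- ifelse(cond %in% c("std1", "std2"), seq_len(n_stimuli), NA_real_)
  data.frame(slot = seq_len(n_stimuli), condition = cond, value = value)
}

# All 6 ordered standard/deviant pairs with their |delta_f| class.
ordered_pairs <- function(sweeps) {
  labs <- names(sweeps)
  grid <- expand.grid(standard = labs, deviant = labs,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$standard != grid$deviant, ]
  grid$delta_class <- vapply(seq_len(nrow(grid)), function(i) {
    abs(sweeps[[grid$deviant[i]]]$delta_f - sweeps[[grid$standard[i]]]$delta_f)
  }, numeric(1))
  grid[order(grid$standard, grid$deviant), ]
}

# Assemble one run: trials (already ordered, with deviant positions) are laid
# on a timeline with jittered ITIs; null events are inserted at random
# inter-trial boundaries (never splitting a trial).
build_run_schedule <- function(trials, params, run_id, timing_seed,
                               null_seed) {
  n_trials <- nrow(trials)
  stim_dur <- params$sweeps[[1]]$total_duration
  seq_dur <- sequence_duration(params$n_stimuli, stim_dur, params$isi)

  itis <- numeric(n_trials)
  with_seed(timing_seed, {
    for (i in seq_len(n_trials - 1)) {
      itis[i] <- sample_intertrial_timing(trials$deviant_position[i],
                                          trials$deviant_position[i + 1],
                                          params)$iti
    }
  })
  itis[n_trials] <- params$iti_min

  # nulls at uniformly random boundaries: 0 = before the first trial,
  # k = after trial k; several nulls may share a boundary
  null_boundary <- with_seed(null_seed,
    sort(sample(0:n_trials, params$nulls_per_run, replace = TRUE)))

  onset <- numeric(n_trials)
  null_onsets <- numeric(params$nulls_per_run)
  t <- 0
  ni <- 1L
  while (ni <= length(null_boundary) && null_boundary[ni] == 0L) {
    null_onsets[ni] <- t; t <- t + seq_dur; ni <- ni + 1L
  }
  for (i in seq_len(n_trials)) {
    onset[i] <- t
    t <- t + seq_dur + itis[i]
    while (ni <= length(null_boundary) && null_boundary[ni] == i) {
      null_onsets[ni] <- t; t <- t + seq_dur; ni <- ni + 1L
    }
  }
  trials$onset <- onset
  trials$iti_after <- itis

  slot_rel <- stimulus_onsets(params$n_stimuli, stim_dur, params$isi)
  ev <- do.call(rbind, lapply(seq_len(n_trials), function(i) {
    sc <- slot_conditions(trials$deviant_position[i], params$n_stimuli)
    data.frame(onset = (trials$onset[i] + slot_rel) / 1000,
               duration = stim_dur / 1000,
               condition = sc$condition, value = sc$value,
               trial = i, block = trials$block[i], slot = sc$slot,
               standard = trials$standard[i], deviant = trials$deviant[i],
               delta_class = trials$delta_class[i])
  }))
  if (params$nulls_per_run > 0) {
    ev <- rbind(ev, data.frame(
      onset = null_onsets / 1000, duration = seq_dur / 1000,
      condition = "null", value = NA_real_, trial = NA_integer_,
      block = NA_integer_, slot = NA_integer_, standard = NA_character_,
      deviant = NA_character_, delta_class = NA_real_))
  }
  ev <- ev[order(ev$onset), ]
  rownames(ev) <- NULL

  structure(list(run_id = run_id, trials = trials, events = ev,
                 null_onsets = null_onsets,
                 duration = max(ev$onset + ev$duration) * 1000 +
                   params$run_tail,
                 params = params),
            class = "run_schedule")
}

#' @export
print.run_schedule <- function(x, ...) {
  cat(sprintf("<run_schedule %s> %d trials, %d nulls, %.1f s\n",
              x$run_id, nrow(x$trials), length(x$null_onsets),
              x$duration / 1000))
  invisible(x)
}

#' Build a full per-participant experiment schedule
#'
#' Generates 9 runs of 6 blocks by 10 trials. Each block uses a single
#' ordered standard/deviant pair and every pair appears once per run in
#' randomised order. Deviant positions are pseudorandomised so that each
#' position occurs 30 times within every ordered pair across the experiment
#' (hence 180 times per participant and 60 times per position-by-|delta f|
#' cell), while per-run counts are left free. Null events and inter-trial
#' jitter are randomised within each run. Fully deterministic given `seed`.
#'
#' @param seed Integer seed; all randomness flows from it through named
#'   substreams.
#' @param params [paradigm_params()].
#' @return An `experiment_schedule`: list of [build_run_schedule()] results
#'   plus the seed and parameters.
#' @export
build_experiment <- function(seed, params = paradigm_params()) {
  pairs <- ordered_pairs(params$sweeps)
  if (nrow(pairs) != params$blocks_per_run) {
    stop("blocks_per_run (", params$blocks_per_run, ") must equal the ",
         "number of ordered sweep pairs (", nrow(pairs), ")")
  }
  per_pair <- params$n_runs * params$trials_per_block
  if (per_pair %% 3L != 0L) {
    stop("trials per ordered pair (", per_pair,
         ") must be divisible by the 3 deviant positions")
  }

  # per ordered pair: balanced multiset of positions, shuffled once, then
  # dealt sequentially into that pair's one block per run
  pair_positions <- lapply(seq_len(nrow(pairs)), function(j) {
    pool <- rep(4:6, each = per_pair / 3L)
    shuffled <- with_seed(
      substream_seed(seed, paste0("positions:", pairs$standard[j], ">",
                                  pairs$deviant[j])),
      sample(pool))
    split(shuffled, rep(seq_len(params$n_runs),
                        each = params$trials_per_block))
  })

  runs <- lapply(seq_len(params$n_runs), function(r) {
    block_order <- with_seed(substream_seed(seed, paste0("blocks:run", r)),
                             sample(nrow(pairs)))
    trials <- do.call(rbind, lapply(seq_along(block_order), function(b) {
      j <- block_order[b]
      data.frame(block = b,
                 standard = pairs$standard[j], deviant = pairs$deviant[j],
                 delta_class = pairs$delta_class[j],
                 deviant_position = pair_positions[[j]][[r]])
    }))
    build_run_schedule(trials, params, run_id = paste0("run-", r),
                       timing_seed = substream_seed(seed,
                                                    paste0("timing:run", r)),
                       null_seed = substream_seed(seed,
                                                  paste0("nulls:run", r)))
  })

  structure(list(runs = runs, seed = seed, params = params),
            class = "experiment_schedule")
}

#' @export
print.experiment_schedule <- function(x, ...) {
  n_trials <- sum(vapply(x$runs, function(r) nrow(r$trials), integer(1)))
  cat(sprintf("<experiment_schedule> %d runs, %d trials (seed %d)\n",
              length(x$runs), n_trials, x$seed))
  invisible(x)
}

#' Tabulate deviant positions of an experiment schedule
#'
#' @param schedule An `experiment_schedule`.
#' @return Data frame of counts per deviant position and |delta f| class.
#' @export
position_counts <- function(schedule) {
  tr <- do.call(rbind, lapply(schedule$runs, `[[`, "trials"))
  as.data.frame(table(position = tr$deviant_position,
                      delta_class = tr$delta_class),
                stringsAsFactors = FALSE)
}

#' Write / read an event table as tab-separated text
#'
#' Columns follow the BIDS-events dialect: `onset` (s), `duration` (s),
#' `condition`, `value` (parametric modulation), plus bookkeeping columns.
#'
#' @param events Event data frame (e.g. `run$events`).
#' @param path File path.
#' @return `write_events` returns `path` invisibly; `read_events` the data
#'   frame.
#' @export
write_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
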