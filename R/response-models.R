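# The two competing linear response models mapping the 8 stimuli of a trial
# to expected response amplitudes:
#   h1 (habituation): asymptotic decay over repeated standards, full recovery
#     at any change, independent of the listener's expectations;
#   h2 (prediction error): amplitudes scale with the probability that the
#     heard stimulus violates the listener's current expectation, derived
#     from the deviant-position hazard (1/3, 1/2, 1).
# Each model is linear in its free parameters, so a model is represented by
# a basis matrix (8 slots x parameters); a profile is basis %*% params.

#' Basis matrix of the habituation model (h1)
#'
#' Four free amplitude parameters: `a0` (first standard), `a1` (decay chain
#' of pre-deviant standards, amplitude `a1/n` after n repetitions), `a2`
#' (deviant recovery) and `a3` (decay chain of post-deviant standards).
#'
#' @param position Deviant position (4, 5 or 6).
#' @return 8 x 4 numeric matrix, columns `a0`, `a1`, `a2`, `a3`.
#' @export
h1_basis <- function(position) {
  if (!position %in% 4:6) stop("deviant position must be 4, 5 or 6")
  B <- matrix(0, 8, 4, dimnames = list(NULL, c("a0", "a1", "a2", "a3")))
  B[1, "a0"] <- 1
  pre <- seq(2, position - 1)                 # standards before the deviant
  B[pre, "a1"] <- 1 / seq_along(pre)
  B[position, "a2"] <- 1                      # the deviant itself
  post <- seq(position + 1, 8)                # standards after the deviant
  B[post, "a3"] <- 1 / seq_along(post)
  B
}

#' Basis matrix of the prediction-error model (h2)
#'
#' Two free parameters: `a0` (response to the first standard, additionally
#' affected by onset-time uncertainty) and `a1`, which scales the
#' expectation-violation probabilities: a standard heard at candidate
#' position k elicits `a1 * hazard(k)` (the expectation of a deviant was
#' violated), and the deviant at position p elicits `a1 * (1 - hazard(p))`.
#' Standards at non-candidate positions and all stimuli after the deviant
#' carry no prediction error.
#'
#' @param position Deviant position (4, 5 or 6).
#' @param model [expectation_model()] supplying the hazards.
#' @return 8 x 2 numeric matrix, columns `a0`, `a1`.
#' @export
h2_basis <- function(position, model = expectation_model()) {
  if (!position %in% 4:6) stop("deviant position must be 4, 5 or 6")
  B <- matrix(0, 8, 2, dimnames = list(NULL, c("a0", "a1")))
  B[1, "a0"] <- 1
  cand <- model$candidate_positions[model$candidate_positions < position]
  B[cand, "a1"] <- deviant_hazard(cand, model)       # violated expectations
  B[position, "a1"] <- 1 - deviant_hazard(position, model)
  B
}

#' Expected amplitude profile under the habituation model
#'
#' @param position Deviant position (4, 5 or 6).
#' @param params Named list or vector with `a0`, `a1`, `a2`, `a3`
#'   (nonnegative; defaults all 1).
#' @return An `amplitude_profile`: numeric vector of 8 amplitudes with
#'   attributes `deviant_position` and `model`.
#' @examples
#' h1_profile(4)  # a0, a1, a1/2, a2, a3, a3/2, a3/3, a3/4 at unit parameters
#' @export
h1_profile <- function(position, params = c(a0 = 1, a1 = 1, a2 = 1, a3 = 1)) {
  p <- unlist(params)[c("a0", "a1", "a2", "a3")]
  check_amplitudes(p)
  structure(drop(h1_basis(position) %*% p),
            deviant_position = position, model = "h1",
            class = "amplitude_profile")
}

#' Expected amplitude profile under the prediction-error model
#'
#' @param position Deviant position (4, 5 or 6).
#' @param params Named list or vector with `a0`, `a1` (nonnegative; defaults
#'   all 1).
#' @param model [expectation_model()] supplying the hazards.
#' @return An `amplitude_profile` of 8 amplitudes.
#' @examples
#' h2_profile(5)  # a0, 0, 0, 1/3, 1/2, 0, 0, 0 at unit parameters
#' @export
h2_profile <- function(position, params = c(a0 = 1, a1 = 1),
                       model = expectation_model()) {
  p <- unlist(params)[c("a0", "a1")]
  check_amplitudes(p)
  structure(drop(h2_basis(position, model) %*% p),
            deviant_position = position, model = "h2",
            class = "amplitude_profile")
}

check_amplitudes <- function(p) {
  if (anyNA(p) || any(!is.finite(p)) || any(p < 0)) {
    stop("model amplitudes must be finite and nonnegative")
  }
  invisible(p)
}

#' @export
print.amplitude_profile <- function(x, ...) {
  cat(sprintf("<amplitude_profile %s, deviant in %d>\n",
              attr(x, "model"), attr(x, "deviant_position")))
  print(round(unclass(x), 4))
  invisible(x)
}

# Basis for a given model tag; used by the simulator and the BMC designs.
model_basis <- function(model = c("h1", "h2"), position) {
  switch(match.arg(model), h1 = h1_basis(position), h2 = h2_basis(position))
}

#' Label a trial's stimulus slots with GLM conditions and amplitudes
#'
#' Tags slot 1 as `std0`, pre-deviant slots as `std1` (parametric value =
#' within-sequence position), the deviant slot as `dev4`/`dev5`/`dev6`, and
#' post-deviant slots as `std2` (position values), and attaches the
#' profile's amplitudes.
#'
#' @param position Deviant position of the trial, or a trial row with a
#'   `deviant_position` field.
#' @param profile Optional `amplitude_profile`; its deviant position must
#'   match the trial's.
#' @return Data frame with `slot`, `condition`, `value` and (if a profile is
#'   given) `amplitude`.
#' @export
profile_to_conditions <- function(position, profile = NULL) {
  if (is.list(position)) position <- position$deviant_position
  out <- slot_conditions(position)
  if (!is.null(profile)) {
    if (!identical(as.integer(attr(profile, "deviant_position")),
                   as.integer(position))) {
      stop("profile deviant position (", attr(profile, "deviant_position"),
           ") does not match the trial's (", position, ")")
    }
    out$amplitude <- as.numeric(profile)
  }
  out
}
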