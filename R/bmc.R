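# Per-voxel Bayesian evidence for the habituation (h1) and prediction-error
# (h2) linear models, subject Bayes factors, and random-effects group
# Bayesian model comparison via a variational Dirichlet scheme.

#' Closed-form log-evidence of a linear model
#'
#' Marginal likelihood of `y = X b + e` under the conjugate
#' Normal-Inverse-Gamma prior `b | s2 ~ N(0, s2 * diag(1/prior_precision))`,
#' `s2 ~ Inv-Gamma(a0, b0)`, with coefficients and noise variance integrated
#' out analytically. The prior precision may be a scalar or one value per
#' column, which allows shared nuisance columns to enter both competing
#' models with a vague prior.
#'
#' @param y Timecourse vector (or time x voxel matrix for many voxels).
#' @param X Design matrix (time x columns, full rank).
#' @param prior_precision Prior coefficient precision(s), scalar or
#'   per-column.
#' @param a0,b0 Inverse-gamma shape and scale of the noise-variance prior.
#' @return Log-evidence in nats (vector with one value per data column).
#' @export
log_evidence <- function(y, X, prior_precision = 1, a0 = 1e-3, b0 = 1e-3) {
  X <- as.matrix(X)
  Y <- as.matrix(y)
  n <- nrow(X)
  if (nrow(Y) != n) stop("length of y must match the design rows")
  p <- ncol(X)
  if (qr(X)$rank < p) stop("design matrix is rank deficient")
  lambda0 <- rep_len(prior_precision, p)
  Ln <- crossprod(X) + diag(lambda0, p)
  ch <- chol(Ln)
  logdet_Ln <- 2 * sum(log(diag(ch)))
  logdet_L0 <- sum(log(lambda0))
  XtY <- crossprod(X, Y)
  mu <- backsolve(ch, forwardsolve(t(ch), XtY))
  quad <- colSums(XtY * mu)             # mu' Ln mu
  an <- a0 + n / 2
  bn <- b0 + 0.5 * (colSums(Y^2) - quad)
  if (any(bn <= 0)) stop("non-positive posterior scale; ill-posed input")
  as.numeric(0.5 * (logdet_L0 - logdet_Ln) + a0 * log(b0) - an * log(bn) +
               lgamma(an) - lgamma(a0) - n / 2 * log(2 * pi))
}

#' BMC design matrices for the two response models on one run
#'
#' Each model contributes one HRF-convolved regressor per free amplitude
#' parameter (four for h1: `a0`, `a1`, `a2`, `a3`; two for h2: `a0`, `a1`),
#' built from the model's basis evaluated at each trial's deviant position
#' and scaled to unit variance so that, against standardised timecourses,
#' the coefficients are effect sizes in data-SD units and the unit prior
#' precision is weakly informative at any SNR. Intercept and polynomial
#' drift are appended to both designs as shared nuisance columns.
#'
#' @param schedule A `run_schedule`.
#' @param acq [acquisition_params()].
#' @param models Model tags to build.
#' @return Named list of `list(X, n_cond)` per model, where the first
#'   `n_cond` columns are the model's own regressors.
#' @export
bmc_designs <- function(schedule, acq = acquisition_params(),
                        models = c("h1", "h2")) {
  nv <- n_volumes(schedule, acq)
  ev <- schedule$events[schedule$events$condition != "null", ]
  pos <- schedule$trials$deviant_position[ev$trial]
  drift <- drift_basis(nv, acq$drift_order)
  lapply(stats::setNames(nm = models), function(m) {
    bases <- lapply(stats::setNames(4:6, 4:6),
                    function(p) model_basis(m, p))
    pn <- colnames(bases[[1]])
    cols <- vapply(pn, function(par) {
      amp <- vapply(seq_len(nrow(ev)), function(i) {
        bases[[as.character(pos[i])]][ev$slot[i], par]
      }, numeric(1))
      keep <- amp != 0
      x <- event_regressor(ev$onset[keep], amp[keep], nv, acq$tr, acq$dt)
      # unit-variance scaling: coefficients live in data-SD units, so the
      # unit prior precision is weakly informative at any SNR
      x / stats::sd(x)
    }, numeric(nv))
    X <- cbind(cols, intercept = 1, drift)
    list(X = X, n_cond = length(pn))
  })
}

#' Per-voxel log-evidence of both models for one subject
#'
#' For every run the voxel timecourses are standardised (zero mean, unit
#' variance within the run, so that a unit prior precision on the condition
#' coefficients is on the data scale), optionally AR(1)-prewhitened with a
#' single pooled coefficient estimated from the standard GLM residuals (the
#' same whitening is applied to both model designs, so the models compete
#' on identical data), and the conjugate evidence is accumulated across
#' runs.
#'
#' @param runs List of `bold_run`s for one subject.
#' @param acq [acquisition_params()].
#' @param prewhiten Apply AR(1) prewhitening before evidence computation.
#' @param prior_precision Prior precision of the model's own coefficients;
#'   nuisance columns get `1e-6`.
#' @param a0,b0 Noise-variance prior hyperparameters.
#' @return Voxel x model matrix of log-evidences (nats), columns `h1`, `h2`.
#' @export
subject_log_evidence <- function(runs, acq = acquisition_params(),
                                 prewhiten = TRUE, prior_precision = 1,
                                 a0 = 1e-3, b0 = 1e-3) {
  n_vox <- nrow(runs[[1]]$data)
  lme <- matrix(0, n_vox, 2, dimnames = list(NULL, c("h1", "h2")))
  for (run in runs) {
    Yt <- t(run$data)
    Yt <- scale(Yt)                      # per-voxel standardisation
    if (any(!is.finite(Yt))) stop("constant voxel timecourse in run ",
                                  run$run_id)
    rho <- 0
    if (prewhiten) {
      des <- build_design_matrix(run$schedule, acq)
      rho <- pooled_ar1(qr.resid(qr(des$X), Yt))
      Yt <- ar1_transform(Yt, rho)
    }
    designs <- bmc_designs(run$schedule, acq)
    for (m in names(designs)) {
      X <- designs[[m]]$X
      if (rho != 0) X <- ar1_transform(X, rho)
      prec <- c(rep(prior_precision, designs[[m]]$n_cond),
                rep(1e-6, ncol(X) - designs[[m]]$n_cond))
      lme[, m] <- lme[, m] + log_evidence(Yt, X, prec, a0, b0)
    }
  }
  lme
}

#' Subject-level Bayes factor between the two models
#'
#' `K = exp(lme_h2 - lme_h1)`; `K > 10` is read as substantial evidence for
#' the prediction-error model, `K < 1/10` as substantial evidence for
#' habituation, anything in between as indeterminate.
#'
#' @param lme_h1,lme_h2 Log-evidences (nats) from the same voxel and data.
#' @return List with `K` and `band` (factor with levels `substantial-h1`,
#'   `indeterminate`, `substantial-h2`).
#' @export
subject_bayes_factor <- function(lme_h1, lme_h2) {
  K <- exp(lme_h2 - lme_h1)
  band <- cut(K, c(-Inf, 1 / 10, 10, Inf),
              labels = c("substantial-h1", "indeterminate",
                         "substantial-h2"),
              right = FALSE)
  list(K = K, band = band)
}

# Variational random-effects update for one voxel's subject x model
# log-evidence matrix (Dirichlet posterior over model frequencies).
rfx_bmc_one <- function(lme, alpha0, tol, max_iter) {
  alpha <- rep(alpha0, ncol(lme))
  for (it in seq_len(max_iter)) {
    lu <- sweep(lme, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    lu <- lu - apply(lu, 1, max)
    u <- exp(lu)
    u <- u / rowSums(u)
    alpha_new <- alpha0 + colSums(u)
    if (max(abs(alpha_new - alpha)) < tol) return(alpha_new)
    alpha <- alpha_new
  }
  stop("random-effects BMC did not converge after ", max_iter,
       " iterations (last delta ", signif(max(abs(alpha_new - alpha)), 3),
       ")")
}

#' Random-effects group Bayesian model comparison
#'
#' Variational Dirichlet scheme over per-subject log-evidences: subject
#' responsibilities `u(n, m)` proportional to
#' `exp(lme(n, m) + digamma(alpha_m) - digamma(sum(alpha)))` and
#' concentration updates `alpha = alpha0 + colSums(u)`, iterated to
#' convergence per voxel. Expected posterior model probabilities are
#' `alpha / sum(alpha)` and the group Bayes-factor map is their h2/h1
#' ratio.
#'
#' @param lme Voxel x subject x model array, or a subject x model matrix for
#'   a single voxel; model order `(h1, h2)`.
#' @param alpha0 Prior Dirichlet concentration per model.
#' @param tol Convergence tolerance on the concentration parameters.
#' @param max_iter Iteration cap (non-convergence is an error).
#' @return An `rfx_result`: `alpha` (voxel x model), `expected_prob`,
#'   `k_map` (h2 vs h1), `n_subjects`.
#' @export
group_rfx_bmc <- function(lme, alpha0 = 1, tol = 1e-6, max_iter = 1000) {
  if (is.matrix(lme)) lme <- array(lme, c(1, dim(lme)))
  stopifnot(length(dim(lme)) == 3)
  n_vox <- dim(lme)[1]; n_sub <- dim(lme)[2]; n_mod <- dim(lme)[3]
  if (n_sub < 2 || n_mod < 2) stop("need at least 2 subjects and 2 models")
  model_names <- dimnames(lme)[[3]] %||% c("h1", "h2")
  alpha <- t(vapply(seq_len(n_vox), function(v) {
    rfx_bmc_one(matrix(lme[v, , ], n_sub, n_mod), alpha0, tol, max_iter)
  }, numeric(n_mod)))
  colnames(alpha) <- model_names
  prob <- alpha / rowSums(alpha)
  structure(list(alpha = alpha, expected_prob = prob,
                 k_map = prob[, 2] / prob[, 1], n_subjects = n_sub,
                 alpha0 = alpha0),
            class = "rfx_result")
}

#' @export
print.rfx_result <- function(x, ...) {
  cat(sprintf("<rfx_result> %d voxels, %d subjects; median K = %.3g\n",
              nrow(x$alpha), x$n_subjects, stats::median(x$k_map)))
  invisible(x)
}

#' Summaries of group posterior probabilities per ROI
#'
#' Kernel-density estimates (Scott's bandwidth) of `log K` across the
#' voxels of each mask, plus the fractions of voxels with `K > 1`,
#' `K > 10`, `K < 1/10`.
#'
#' @param rfx An `rfx_result` (or any list with a `k_map`).
#' @param masks Named list of voxel-index vectors.
#' @return Named list per ROI with `n`, `log_k`, `density` and `fractions`;
#'   empty masks yield `NULL` with a warning.
#' @export
posterior_probability_summary <- function(rfx, masks) {
  lapply(masks, function(idx) {
    if (length(idx) == 0) {
      warning("empty mask in posterior summary")
      return(NULL)
    }
    lk <- log(rfx$k_map[idx])
    dens <- if (length(lk) >= 2 && stats::sd(lk) > 0)
      stats::density(lk, bw = "nrd") else NULL
    list(n = length(lk), log_k = lk, density = dens,
         fractions = c(k_gt_1 = mean(lk > 0),
                       k_gt_10 = mean(lk > log(10)),
                       k_lt_tenth = mean(lk < -log(10))))
  })
}
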