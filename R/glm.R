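# First-level GLM: design assembly with parametric modulation, OLS fitting
# with optional AR(1) prewhitening, beta z-scoring, SSA index, group
# nonparametric tests and FDR thresholding.

#' Build the first-level design matrix for one run
#'
#' Pooled designs carry 8 condition columns: `std0`, `std1`, `std1xpos`,
#' `std2`, `std2xpos`, `dev4`, `dev5`, `dev6`. The parametric modulators
#' carry the within-sequence stimulus position, mean-centred per run within
#' their parent condition. With `split_by_class = TRUE` the design instead
#' carries 6 columns (`std0`, `std1`, `std2`, `dev4`, `dev5`, `dev6`,
#' without modulators) for each |delta f| class, enabling the
#' direction-only / rate-only partition analyses. All condition columns are
#' HRF-convolved impulse trains; an intercept, polynomial drift and optional
#' nuisance columns are appended.
#'
#' Condition columns without any event (e.g. `dev5` in a schedule with only
#' position-4 deviants) are flagged with a warning and dropped.
#'
#' @param schedule A `run_schedule`.
#' @param acq [acquisition_params()].
#' @param nuisance Optional matrix of extra nuisance columns (one row per
#'   volume).
#' @param split_by_class Build per-|delta f|-class condition columns.
#' @param drift_order Polynomial drift order; defaults to the acquisition's.
#' @return A `design_matrix`: list with `X` (volumes x columns),
#'   `condition_cols`, `nuisance_cols`, `n_vol`, `tr`.
#' @export
build_design_matrix <- function(schedule, acq = acquisition_params(),
                                nuisance = NULL, split_by_class = FALSE,
                                drift_order = acq$drift_order) {
  stopifnot(inherits(schedule, "run_schedule"))
  nv <- n_volumes(schedule, acq)
  ev <- schedule$events[schedule$events$condition != "null", ]

  reg <- function(sel, amplitudes = 1) {
    event_regressor(ev$onset[sel], amplitudes, nv, acq$tr, acq$dt)
  }
  cols <- list()
  if (!split_by_class) {
    for (cond in c("std0", "std1", "std2")) {
      sel <- ev$condition == cond
      cols[[cond]] <- reg(sel)
      if (cond %in% c("std1", "std2") && any(sel)) {
        centred <- ev$value[sel] - mean(ev$value[sel])
        cols[[paste0(cond, "xpos")]] <- reg(sel, centred)
      }
    }
    for (d in c("dev4", "dev5", "dev6")) cols[[d]] <- reg(ev$condition == d)
  } else {
    for (cl in sort(unique(ev$delta_class))) {
      in_cl <- ev$delta_class == cl
      for (cond in c("std0", "std1", "std2", "dev4", "dev5", "dev6")) {
        cols[[sprintf("%s@%g", cond, cl)]] <-
          reg(in_cl & ev$condition == cond)
      }
    }
  }
  empty <- vapply(cols, function(x) all(x == 0), logical(1))
  if (any(empty)) {
    warning("dropping condition columns without events: ",
            paste(names(cols)[empty], collapse = ", "))
    cols <- cols[!empty]
  }
  condition_cols <- names(cols)

  drift <- drift_basis(nv, drift_order)
  if (ncol(drift) > 0) colnames(drift) <- paste0("drift", seq_len(ncol(drift)))
  X <- cbind(do.call(cbind, cols), intercept = 1, drift)
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != nv) stop("nuisance must have one row per volume")
    if (is.null(colnames(nuisance)))
      colnames(nuisance) <- paste0("nuisance", seq_len(ncol(nuisance)))
    X <- cbind(X, nuisance)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X))]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  structure(list(X = X, condition_cols = condition_cols,
                 nuisance_cols = setdiff(colnames(X), condition_cols),
                 n_vol = nv, tr = acq$tr),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> %d volumes x %d columns (%d condition)\n",
              x$n_vol, ncol(x$X), length(x$condition_cols)))
  invisible(x)
}

# AR(1) transform of a time x k matrix: first row scaled by sqrt(1 - rho^2),
# later rows replaced by innovations.
ar1_transform <- function(M, rho) {
  M <- as.matrix(M)
  out <- M
  out[1, ] <- sqrt(1 - rho^2) * M[1, ]
  out[-1, ] <- M[-1, , drop = FALSE] -
    rho * M[-nrow(M), , drop = FALSE]
  out
}

# Pooled lag-1 autocorrelation of residual columns.
pooled_ar1 <- function(res) {
  num <- sum(res[-1, , drop = FALSE] * res[-nrow(res), , drop = FALSE])
  den <- sum(res^2)
  if (den == 0) 0 else num / den
}

#' Fit the first-level GLM for one run
#'
#' Ordinary least squares for every voxel, optionally followed by one AR(1)
#' prewhitening refit: a single pooled AR coefficient is estimated from the
#' OLS residuals, data and design are whitened, and the model is refit once.
#'
#' @param data A `bold_run` or a voxel x time matrix.
#' @param design A [build_design_matrix()] result (or bare design matrix).
#' @param prewhiten Apply the AR(1) refit.
#' @return A `glm_result`: `betas` (voxel x column), `sigma2` (residual
#'   variance at `df` degrees of freedom), `df`, `rho` (0 without
#'   prewhitening), `design`.
#' @export
fit_glm <- function(data, design, prewhiten = FALSE) {
  Y <- if (inherits(data, "bold_run")) data$data else as.matrix(data)
  X <- if (inherits(design, "design_matrix")) design$X else as.matrix(design)
  if (ncol(Y) != nrow(X)) {
    stop("time axes disagree: data has ", ncol(Y), " volumes, design ",
         nrow(X))
  }
  Yt <- t(Y)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("design matrix is rank deficient")
  beta <- qr.coef(qrX, Yt)
  res <- qr.resid(qrX, Yt)
  rho <- 0
  if (prewhiten) {
    rho <- pooled_ar1(res)
    Yw <- ar1_transform(Yt, rho)
    Xw <- ar1_transform(X, rho)
    qrX <- qr(Xw)
    beta <- qr.coef(qrX, Yw)
    res <- qr.resid(qrX, Yw)
  }
  df <- nrow(X) - ncol(X)
  structure(list(betas = t(beta), sigma2 = colSums(res^2) / df, df = df,
                 rho = rho, design = design),
            class = "glm_result")
}

#' @export
print.glm_result <- function(x, ...) {
  cat(sprintf("<glm_result> %d voxels x %d coefficients (df = %d)\n",
              nrow(x$betas), ncol(x$betas), x$df))
  invisible(x)
}

#' Z-score condition betas within a normalisation pool
#'
#' All condition coefficients of a run (across voxels and conditions) form
#' one pool that is shifted and scaled to mean 0 and SD 1; this is applied
#' per run and participant before any group statistic.
#'
#' @param betas A `glm_result` or a voxel x condition matrix.
#' @param condition_cols Columns forming the pool; defaults to the design's
#'   condition columns when `betas` is a `glm_result`.
#' @return Matrix of z-scored condition betas (voxel x condition).
#' @export
zscore_betas <- function(betas, condition_cols = NULL) {
  if (inherits(betas, "glm_result")) {
    condition_cols <- condition_cols %||%
      betas$design$condition_cols
    B <- betas$betas[, condition_cols, drop = FALSE]
  } else {
    B <- as.matrix(betas)
    if (!is.null(condition_cols)) B <- B[, condition_cols, drop = FALSE]
  }
  if (length(B) == 0) stop("empty normalisation pool")
  s <- stats::sd(as.vector(B))
  if (!is.finite(s) || s == 0) {
    stop("degenerate normalisation pool: betas have zero variance")
  }
  (B - mean(B)) / s
}

#' Stimulus-specific adaptation index
#'
#' `SI = (dev4 - (std1 + std2) / 2) / (dev4 + (std1 + std2) / 2)`.
#' `SI > 0` is equivalent to the deviant-detection contrast; `SI = 0` when
#' the deviant response equals the mean repeated-standard response.
#'
#' @param dev4,std1,std2 Response amplitudes (vectors recycle).
#' @return Dimensionless index; `NA` (with a warning) where the denominator
#'   vanishes.
#' @examples
#' ssa_index(1, 0.5, 0.5)  # 1/3
#' @export
ssa_index <- function(dev4, std1, std2) {
  denom <- dev4 + (std1 + std2) / 2
  bad <- abs(denom) < .Machine$double.eps^0.5
  if (any(bad)) warning(sum(bad), " voxel(s) with zero denominator: ",
                        "SSA index undefined, returning NA")
  out <- (dev4 - (std1 + std2) / 2) / denom
  out[bad] <- NA_real_
  out
}

#' Per-subject condition betas for a set of runs
#'
#' Fits the GLM to each run, z-scores the condition betas per run, and
#' averages across runs, giving one voxel x condition matrix per subject.
#'
#' @param runs List of `bold_run`s for one subject.
#' @param acq [acquisition_params()].
#' @param prewhiten Passed to [fit_glm()].
#' @param split_by_class Passed to [build_design_matrix()].
#' @return Voxel x condition matrix of run-averaged z-scored betas.
#' @export
subject_condition_betas <- function(runs, acq = acquisition_params(),
                                    prewhiten = FALSE,
                                    split_by_class = FALSE) {
  mats <- lapply(runs, function(run) {
    des <- build_design_matrix(run$schedule, acq,
                               split_by_class = split_by_class)
    zscore_betas(fit_glm(run, des, prewhiten = prewhiten))
  })
  cols <- Reduce(intersect, lapply(mats, colnames))
  Reduce(`+`, lapply(mats, function(m) m[, cols, drop = FALSE])) /
    length(mats)
}

#' Contrast values from a condition-beta matrix
#'
#' `adaptation` is `std0 - (std1 + std2) / 2`; `deviant_detection` is
#' `dev4 - (std1 + std2) / 2` (position 4 carries the lowest expectation).
#'
#' @param betas Voxel x condition matrix with `std0`, `std1`, `std2`,
#'   `dev4` columns.
#' @param contrast Contrast name.
#' @return Numeric vector, one value per voxel.
#' @export
condition_contrast <- function(betas,
                               contrast = c("adaptation",
                                            "deviant_detection")) {
  contrast <- match.arg(contrast)
  ref <- (betas[, "std1"] + betas[, "std2"]) / 2
  switch(contrast,
         adaptation = betas[, "std0"] - ref,
         deviant_detection = betas[, "dev4"] - ref)
}

#' Voxelwise nonparametric group test against zero
#'
#' Two-tailed Wilcoxon signed-rank test of the per-subject contrast values
#' against zero, one sample per participant, independently per voxel.
#'
#' @param values Subject x voxel matrix of contrast values.
#' @return Vector of uncorrected two-tailed p-values, one per voxel.
#' @export
group_voxelwise_test <- function(values) {
  values <- as.matrix(values)
  if (nrow(values) < 2) stop("group test needs at least 2 subjects")
  apply(values, 2, function(v) {
    if (all(v == 0)) return(1)
    suppressWarnings(stats::wilcox.test(v, mu = 0,
                                        alternative = "two.sided")$p.value)
  })
}

#' Benjamini-Hochberg FDR thresholding
#'
#' Step-up FDR correction over the voxels in `scope`; voxels outside the
#' scope never survive.
#'
#' @param p Vector of p-values.
#' @param alpha FDR level.
#' @param scope Integer indices defining the correction scope; defaults to
#'   all voxels.
#' @return Logical mask of surviving voxels (same length as `p`).
#' @export
fdr_threshold <- function(p, alpha = 0.05, scope = NULL) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  scope <- scope %||% seq_along(p)
  mask <- logical(length(p))
  if (length(scope) == 0) {
    warning("empty scope: returning empty mask")
    return(mask)
  }
  mask[scope] <- stats::p.adjust(p[scope], method = "BH") <= alpha
  mask & !is.na(mask)
}

#' SSA contrast maps and FDR masks
#'
#' The SSA p-value is the voxelwise maximum of the adaptation and
#' deviant-detection p-values (an upper bound for the conjunction); each of
#' the three maps is FDR-thresholded within every anatomical ROI scope.
#' The contract that the SSA mask is contained in the intersection of the
#' two parent masks is checked and reported.
#'
#' @param adaptation_p,deviant_detection_p Aligned p-value vectors.
#' @param alpha FDR level.
#' @param scopes Named list of voxel-index vectors (one per anatomical ROI).
#' @return A `contrast_maps` list: the three p maps, the three masks, and
#'   `contract_ok`.
#' @export
ssa_mask <- function(adaptation_p, deviant_detection_p, alpha = 0.05,
                     scopes = list(all = seq_along(adaptation_p))) {
  if (length(adaptation_p) != length(deviant_detection_p)) {
    stop("p maps are misaligned")
  }
  ssa_p <- pmax(adaptation_p, deviant_detection_p)
  combine <- function(p) {
    m <- logical(length(p))
    for (sc in scopes) m <- m | fdr_threshold(p, alpha, sc)
    m
  }
  masks <- list(adaptation = combine(adaptation_p),
                deviant_detection = combine(deviant_detection_p),
                ssa = combine(ssa_p))
  contract_ok <- !any(masks$ssa &
                        !(masks$adaptation & masks$deviant_detection))
  if (!contract_ok) {
    warning("SSA mask is not contained in the intersection of the ",
            "adaptation and deviant-detection masks")
  }
  structure(list(adaptation_p = adaptation_p,
                 deviant_detection_p = deviant_detection_p, ssa_p = ssa_p,
                 masks = masks, alpha = alpha, contract_ok = contract_ok),
            class = "contrast_maps")
}

#' Volume-matched functional ROI definition
#'
#' Iteratively thresholding a contrast map to increasingly conservative
#' values until exactly `target_count` voxels survive is equivalent to
#' selecting the `target_count` voxels with the largest statistic inside
#' the prior mask; ties are broken by ascending voxel index so the result
#' is deterministic.
#'
#' @param prior_mask Integer voxel indices of the (inflated) prior region.
#' @param contrast_map Per-voxel statistic (full-length vector).
#' @param target_count Number of voxels to retain.
#' @return Sorted integer indices of the selected voxels.
#' @export
define_roi <- function(prior_mask, contrast_map, target_count) {
  if (target_count > length(prior_mask)) {
    stop("target_count (", target_count, ") exceeds the prior mask size (",
         length(prior_mask), ")")
  }
  vals <- contrast_map[prior_mask]
  ord <- order(-vals, prior_mask)
  sort(prior_mask[ord[seq_len(target_count)]])
}

#' Inflate a prior mask by binary dilation on the phantom grid
#'
#' Stand-in for Gaussian-kernel inflation of anatomical priors at phantom
#' resolution: each voxel within `radius` grid steps (Chebyshev metric) of
#' the mask is added.
#'
#' @param mask_idx Integer voxel indices.
#' @param phantom The phantom defining the grid.
#' @param radius Dilation radius in voxels.
#' @return Sorted integer indices of the dilated mask.
#' @export
dilate_mask <- function(mask_idx, phantom, radius = 1) {
  grid <- attr(phantom, "dim3")
  vol <- array(FALSE, grid)
  vol[mask_idx] <- TRUE
  out <- vol
  offs <- expand.grid(dx = -radius:radius, dy = -radius:radius,
                      dz = -radius:radius)
  co <- arrayInd(which(vol), .dim = grid)
  for (i in seq_len(nrow(offs))) {
    sh <- sweep(co, 2, as.numeric(offs[i, ]), `+`)
    ok <- sh[, 1] >= 1 & sh[, 1] <= grid[1] &
      sh[, 2] >= 1 & sh[, 2] <= grid[2] &
      sh[, 3] >= 1 & sh[, 3] <= grid[3]
    out[sh[ok, , drop = FALSE]] <- TRUE
  }
  sort(which(out))
}
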