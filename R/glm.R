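#' Canonical double-gamma haemodynamic response function
#'
#' The conventional canonical HRF: a gamma response peaking near 5 s (shape 6,
#' scale 1 s) minus a 1/6-amplitude undershoot (shape 16, scale 1 s), sampled
#' on \[0, 32\] s and normalized to unit peak.
#'
#' @param dt Sampling interval in seconds (> 0).
#' @param duration Kernel support in seconds.
#' @return Numeric vector of kernel samples at `0, dt, 2 dt, ...`.
#' @export
canonical_hrf <- function(dt, duration = 32) {
  if (dt <= 0) stop("canonical_hrf: dt must be > 0")
  t <- seq(0, duration, by = dt)
  h <- stats::dgamma(t, shape = 6, scale = 1) -
    stats::dgamma(t, shape = 16, scale = 1) / 6
  h / max(h)
}

# HRF-convolved block regressors sampled at the volume grid.
# events: data.frame(condition, onset, duration) in seconds, onsets relative
# to the first retained volume. Returns n_volumes x length(conditions).
condition_regressors <- function(events, n_volumes, tr,
                                 conditions = sort(unique(events$condition)),
                                 microtime = 16L) {
  dt <- tr / microtime
  nf <- n_volumes * microtime
  h <- canonical_hrf(dt)
  vol_idx <- (seq_len(n_volumes) - 1L) * microtime + 1L
  X <- sapply(conditions, function(cn) {
    ev <- events[events$condition == cn, , drop = FALSE]
    box <- numeric(nf)
    for (j in seq_len(nrow(ev))) {
      i0 <- floor(ev$onset[j] / dt) + 1
      i1 <- min(nf, ceiling((ev$onset[j] + ev$duration[j]) / dt))
      if (i0 <= nf) box[i0:min(i1, nf)] <- 1
    }
    conv <- stats::convolve(box, rev(h), type = "open")[seq_len(nf)] * dt
    conv[vol_idx]
  })
  matrix(X, nrow = n_volumes, dimnames = list(NULL, conditions))
}

# Discrete-cosine high-pass basis: the K = floor(2 T / cutoff) lowest
# nonconstant DCT-II functions, i.e. those with period above the cutoff.
dct_highpass_basis <- function(n_volumes, tr, cutoff = 128) {
  K <- floor(2 * n_volumes * tr / cutoff)
  if (K < 1) return(matrix(numeric(0), n_volumes, 0))
  t <- seq_len(n_volumes) - 1L
  B <- sapply(seq_len(K), function(k)
    sqrt(2 / n_volumes) * cos(pi * (2 * t + 1) * k / (2 * n_volumes)))
  colnames(B) <- paste0("hpf_", seq_len(K))
  B
}

#' Discard leading dummy volumes
#'
#' Removes the first `n_dummy` volumes from a voxel x volume run and shifts the
#' schedule onsets accordingly, so the retained data and events stay aligned.
#'
#' @param bold voxel x volume matrix.
#' @param schedule The run's `stimulus_schedule`.
#' @param motion Optional motion trace (rows trimmed in step).
#' @param n_dummy Number of leading volumes to drop.
#' @return List with trimmed `bold`, shifted `events`, `n_volumes`, `tr`,
#'   and trimmed `motion`.
#' @export
discard_dummies <- function(bold, schedule, motion = NULL, n_dummy = 5L) {
  stopifnot(inherits(schedule, "stimulus_schedule"))
  keep <- seq.int(n_dummy + 1L, schedule$n_volumes)
  events <- schedule$events
  events$onset <- events$onset - n_dummy * schedule$tr
  list(bold = bold[, keep, drop = FALSE],
       events = events,
       n_volumes = length(keep),
       tr = schedule$tr,
       conditions = schedule$conditions,
       motion = if (!is.null(motion)) motion[keep, , drop = FALSE])
}

#' Build a first-level design matrix
#'
#' One HRF-convolved boxcar regressor per condition, mean-centered motion
#' regressors, a discrete-cosine high-pass basis for periods above
#' `hpf_cutoff`, and an intercept. All-zero motion columns (e.g. a motionless
#' synthetic trace) are dropped.
#'
#' @param events Block events data frame (condition, onset, duration) with
#'   onsets relative to the first analyzed volume.
#' @param n_volumes Number of analyzed volumes.
#' @param tr Repetition time (s).
#' @param motion Optional n_volumes x 6 motion trace.
#' @param hpf_cutoff High-pass period cutoff in seconds (default 128).
#' @param conditions Condition labels fixing the column order.
#' @return Object of class `design_matrix`: `matrix`, `condition_cols`,
#'   `names`, `tr`.
#' @export
build_design_matrix <- function(events, n_volumes, tr, motion = NULL,
                                hpf_cutoff = 128,
                                conditions = sort(unique(events$condition))) {
  Xc <- condition_regressors(events, n_volumes, tr, conditions)
  parts <- list(Xc)
  if (!is.null(motion)) {
    if (nrow(motion) != n_volumes)
      stop("build_design_matrix: motion rows must equal n_volumes")
    M <- scale(motion, center = TRUE, scale = FALSE)
    M <- M[, apply(abs(M), 2, max) > 0, drop = FALSE]
    if (ncol(M)) parts <- c(parts, list(M))
  }
  H <- dct_highpass_basis(n_volumes, tr, hpf_cutoff)
  if (ncol(H)) parts <- c(parts, list(H))
  parts <- c(parts, list(intercept = matrix(1, n_volumes, 1,
                                            dimnames = list(NULL, "intercept"))))
  X <- do.call(cbind, parts)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("build_design_matrix: rank-deficient design; offending columns: ",
         paste(bad, collapse = ", "))
  }
  structure(list(matrix = X,
                 condition_cols = seq_along(conditions),
                 names = colnames(X),
                 conditions = conditions,
                 tr = tr),
            class = "design_matrix")
}

#' Global signal scaling
#'
#' Proportionally rescales a run so its grand mean over voxels and volumes
#' equals 100 (the conventional scaling constant).
#'
#' @param Y voxel x volume (or volume x voxel) matrix with positive grand mean.
#' @return Rescaled matrix.
#' @export
global_scale <- function(Y) {
  g <- mean(Y)
  if (!is.finite(g) || g <= 0)
    stop("global_scale: grand mean must be positive")
  Y * (100 / g)
}

#' Fit the general linear model to one run
#'
#' Ordinary least squares, optionally after AR(1) whitening with a single
#' pooled coefficient: a first OLS pass yields residuals whose lag-1
#' autocorrelation, pooled over all voxels, gives the AR coefficient used to
#' pre-whiten data and design before the final fit.
#'
#' @param Y volumes x voxels data matrix (a vector is treated as one voxel).
#' @param X A `design_matrix`.
#' @param whitening `"none"` or `"ar1_global"`.
#' @return Object of class `beta_estimates`: `betas` (condition x voxel),
#'   `nuisance` (other regressors x voxel), `sigma2` per voxel, `dof`,
#'   `ar1_coeff`, and `cov_unscaled` of the (whitened) regressors.
#' @export
fit_glm <- function(Y, X, whitening = c("none", "ar1_global")) {
  whitening <- match.arg(whitening)
  stopifnot(inherits(X, "design_matrix"))
  Y <- as.matrix(Y)
  if (!all(is.finite(Y))) stop("fit_glm: Y contains non-finite values")
  Xm <- X$matrix
  if (nrow(Y) != nrow(Xm))
    stop("fit_glm: Y volumes must match design rows")
  rho <- 0
  if (whitening == "ar1_global") {
    R <- stats::lm.fit(Xm, Y)$residuals
    R <- as.matrix(R)
    n <- nrow(R)
    rho <- sum(R[-1, , drop = FALSE] * R[-n, , drop = FALSE]) /
      sum(R[-n, , drop = FALSE]^2)
    W <- function(A) {
      A2 <- A - rho * rbind(0, A[-nrow(A), , drop = FALSE])
      A2[1, ] <- sqrt(1 - rho^2) * A[1, ]
      A2
    }
    Yw <- W(Y); Xw <- W(Xm)
  } else {
    Yw <- Y; Xw <- Xm
  }
  fit <- stats::lm.fit(Xw, Yw)
  beta <- as.matrix(fit$coefficients)
  res <- as.matrix(fit$residuals)
  dof <- nrow(Yw) - fit$rank
  sigma2 <- colSums(res^2) / dof
  ic <- X$condition_cols
  structure(list(
    betas = beta[ic, , drop = FALSE],
    nuisance = beta[-ic, , drop = FALSE],
    sigma2 = sigma2,
    dof = dof,
    ar1_coeff = rho,
    whitening = whitening,
    cov_unscaled = chol2inv(chol(crossprod(Xw))),
    conditions = X$conditions,
    n_regressors = ncol(Xm)
  ), class = "beta_estimates")
}

#' Linear contrast of condition effects
#'
#' Per-voxel effect `c' beta` and t statistic for a contrast over the
#' condition regressors. Given a list of per-run fits, effects are averaged
#' over runs and the variance and degrees of freedom pooled.
#'
#' @param fits A `beta_estimates` or list of them (one per run).
#' @param contrast Numeric contrast vector over the condition regressors.
#' @return Object of class `contrast_map`: `effect`, `t`, `se`, `dof`.
#'   Voxels with zero residual variance get `NA` t and are flagged in
#'   `undefined`.
#' @export
compute_contrast <- function(fits, contrast) {
  if (inherits(fits, "beta_estimates")) fits <- list(fits)
  k <- length(fits[[1]]$conditions)
  if (length(contrast) != k)
    stop("compute_contrast: contrast length must equal condition count (",
         k, ")")
  per_run <- lapply(fits, function(f) {
    cfull <- numeric(f$n_regressors)
    cfull[seq_len(k)] <- contrast
    eff <- drop(crossprod(contrast, f$betas))
    var <- f$sigma2 * drop(t(cfull) %*% f$cov_unscaled %*% cfull)
    list(effect = eff, var = var, dof = f$dof)
  })
  R <- length(per_run)
  effect <- Reduce(`+`, lapply(per_run, `[[`, "effect")) / R
  var <- Reduce(`+`, lapply(per_run, `[[`, "var")) / R^2
  dof <- sum(vapply(per_run, `[[`, 0, "dof"))
  se <- sqrt(var)
  t <- ifelse(se > 0, effect / se, NA_real_)
  structure(list(effect = effect, se = se, t = t, dof = dof,
                 undefined = !(se > 0)),
            class = "contrast_map")
}

#' Sphere ROI on a regular voxel grid
#'
#' All voxels whose centers lie within `radius_mm` (inclusive) of the center,
#' on an axis-aligned grid with the given spacing. With the default 8-mm
#' radius on a 2-mm grid and a grid-aligned center, this yields 257 voxels
#' (2056 mm^3).
#'
#' @param center_mm Length-3 center coordinate (mm).
#' @param radius_mm Sphere radius (mm, > 0).
#' @param grid_spacing_mm Voxel spacing (mm).
#' @return Object of class `roi_definition`: `coords` (n x 3 voxel-center
#'   coordinates in mm), `n_voxels`, `voxel_volume` (mm^3), plus the sphere
#'   parameters.
#' @export
make_sphere_roi <- function(center_mm = c(0, 0, 0), radius_mm = 8,
                            grid_spacing_mm = 2) {
  if (radius_mm <= 0) stop("make_sphere_roi: radius must be > 0")
  s <- grid_spacing_mm
  rng <- function(c0) {
    lo <- floor((c0 - radius_mm) / s)
    hi <- ceiling((c0 + radius_mm) / s)
    s * (lo:hi)
  }
  g <- as.matrix(expand.grid(x = rng(center_mm[1]), y = rng(center_mm[2]),
                             z = rng(center_mm[3])))
  d2 <- rowSums(sweep(g, 2, center_mm)^2)
  keep <- d2 <= radius_mm^2 + 1e-9
  if (!any(keep)) stop("make_sphere_roi: empty ROI")
  structure(list(coords = g[keep, , drop = FALSE],
                 n_voxels = sum(keep),
                 voxel_volume = s^3,
                 center = center_mm, radius = radius_mm, spacing = s),
            class = "roi_definition")
}

#' @export
print.roi_definition <- function(x, ...) {
  cat(sprintf("Sphere ROI: %d voxels (%g mm^3), radius %g mm, spacing %g mm\n",
              x$n_voxels, x$n_voxels * x$voxel_volume, x$radius, x$spacing))
  invisible(x)
}

#' Individual activation detection within an ROI
#'
#' Thresholds the t map at the upper-tail quantile for `p_uncorrected` with
#' the map's degrees of freedom; a participant is "activated" if any ROI voxel
#' survives. Activation size is the suprathreshold voxel count times the voxel
#' volume.
#'
#' @param tmap A `contrast_map`.
#' @param roi Integer voxel indices into the map (default: all voxels).
#' @param p_uncorrected One-sided uncorrected threshold (default 0.01).
#' @param voxel_volume Volume per voxel in mm^3 (default 8, a 2-mm grid).
#' @return Object of class `activation_result`: `activated`,
#'   `n_suprathreshold_voxels`, `volume`, `threshold`, `peak_t`, `peak_voxel`.
#' @export
detect_activation <- function(tmap, roi = NULL, p_uncorrected = 0.01,
                              voxel_volume = 8) {
  stopifnot(inherits(tmap, "contrast_map"))
  roi <- roi %||% seq_along(tmap$t)
  thr <- stats::qt(1 - p_uncorrected, df = tmap$dof)
  tv <- tmap$t[roi]
  supra <- which(!is.na(tv) & tv > thr)
  n <- length(supra)
  peak <- if (length(tv) && any(!is.na(tv))) which.max(tv) else NA_integer_
  structure(list(activated = n >= 1L,
                 n_suprathreshold_voxels = n,
                 volume = n * voxel_volume,
                 threshold = thr,
                 peak_t = if (!is.na(peak)) tv[peak] else NA_real_,
                 peak_voxel = if (!is.na(peak)) roi[peak] else NA_integer_),
            class = "activation_result")
}

#' Extract ROI betas per run
#'
#' Subsets each run's condition x voxel beta matrix to the ROI voxels,
#' preserving condition order.
#'
#' @param fits List of per-run `beta_estimates` (or plain condition x voxel
#'   matrices).
#' @param voxels Integer voxel indices.
#' @param conditions Optional condition labels to keep (row subset).
#' @return List of condition x voxel matrices, one per run.
#' @export
extract_roi_betas <- function(fits, voxels = NULL, conditions = NULL) {
  lapply(fits, function(f) {
    B <- if (inherits(f, "beta_estimates")) {
      b <- f$betas
      rownames(b) <- f$conditions
      b
    } else as.matrix(f)
    if (!is.null(conditions)) B <- B[conditions, , drop = FALSE]
    if (!is.null(voxels)) B <- B[, voxels, drop = FALSE]
    B
  })
}

#' Read a 4-D NIfTI volume as a voxel x volume matrix
#'
#' Optional real-data entry point: flattens a 4-D image so each row is one
#' voxel's time series. Requires the RNifti package.
#'
#' @param path NIfTI file path.
#' @return voxel x volume matrix with an attribute `dim3` holding the spatial
#'   dimensions.
#' @export
read_bold_nifti <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("read_bold_nifti requires the RNifti package")
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4) stop("read_bold_nifti: expected a 4-D image")
  Y <- matrix(as.numeric(img), prod(d[1:3]), d[4])
  attr(Y, "dim3") <- d[1:3]
  Y
}

#' Read a 3-D NIfTI ROI mask as voxel indices
#'
#' Nonzero voxels are included; indices refer to the flattened voxel order
#' used by [read_bold_nifti()].
#'
#' @param path NIfTI mask path.
#' @return Integer vector of voxel indices.
#' @export
read_roi_mask_nifti <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("read_roi_mask_nifti requires the RNifti package")
  img <- RNifti::readNifti(path)
  which(as.numeric(img) != 0)
}
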