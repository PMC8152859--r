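test_that("canonical HRF has the double-gamma shape", {
  h <- canonical_hrf(0.1)
  t <- seq(0, 32, by = 0.1)
  expect_equal(h[1], 0)
  expect_equal(max(h), 1)
  peak <- t[which.max(h)]
  expect_gte(peak, 4); expect_lte(peak, 6)
  expect_gt(sum(h) * 0.1, 0)
  # late undershoot is negative but small
  expect_lt(min(h), 0)
  expect_gt(min(h), -0.3)
  expect_error(canonical_hrf(0), "dt")
})

test_that("design matrix has the expected structure", {
  # single 12-s block: exactly one condition column supported from its onset
  ev <- data.frame(condition = "hand", onset = 30, duration = 12)
  X <- build_design_matrix(ev, n_volumes = 40, tr = 3, conditions = "hand")
  col <- X$matrix[, "hand"]
  # nothing before onset (volume 11), up to FFT convolution round-off
  expect_lt(max(abs(col[1:10])), 1e-8)
  expect_gt(max(col[11:40]), 0.5)

  # DCT basis count: floor(2 T / cutoff) -> 1 for a 120-s run,
  # 4 for the 303-s analyzed run
  expect_equal(sum(grepl("^hpf_", X$names)), 1)
  X2 <- build_design_matrix(ev, n_volumes = 101, tr = 3, conditions = "hand")
  expect_equal(sum(grepl("^hpf_", X2$names)), 4)

  # zero motion trace: motion columns dropped
  X3 <- build_design_matrix(ev, n_volumes = 40, tr = 3,
                            motion = matrix(0, 40, 6), conditions = "hand")
  expect_identical(X3$names, X$names)

  # duplicated condition column -> named rank-deficiency error
  ev2 <- rbind(ev, data.frame(condition = "hand2", onset = 30, duration = 12))
  expect_error(build_design_matrix(ev2, 40, 3,
                                   conditions = c("hand", "hand2")),
               "rank-deficient")
})

test_that("fit_glm is linear and recovers exact data", {
  ev <- data.frame(condition = rep(c("a", "b"), 3),
                   onset = c(10, 40, 70, 100, 130, 160), duration = 12)
  X <- build_design_matrix(ev, n_volumes = 70, tr = 3,
                           conditions = c("a", "b"))
  B <- rbind(a = c(1, -2), b = c(3, 0.5))
  Y <- X$matrix[, 1:2] %*% B
  fit <- fit_glm(Y, X)
  expect_equal(unname(fit$betas), unname(B), tolerance = 1e-10)

  set.seed(1)
  Y1 <- matrix(rnorm(70 * 2), 70)
  Y2 <- matrix(rnorm(70 * 2), 70)
  f12 <- fit_glm(2 * Y1 + 3 * Y2, X)
  expect_equal(f12$betas, 2 * fit_glm(Y1, X)$betas + 3 * fit_glm(Y2, X)$betas)
  expect_error(fit_glm(Y1 * NA, X), "non-finite")
})

test_that("pooled AR(1) estimate recovers the noise autocorrelation", {
  # lean design (no high-pass) so the projection leaves the noise untouched
  ev <- data.frame(condition = "a", onset = 100, duration = 12)
  X <- build_design_matrix(ev, n_volumes = 400, tr = 3, conditions = "a",
                           hpf_cutoff = 1e9)
  est <- function(phi) {
    mean(sapply(1:10, function(s) {
      set.seed(s)
      Y <- if (phi == 0) matrix(rnorm(400 * 20), 400)
           else sapply(1:20, function(v)
             as.numeric(arima.sim(list(ar = phi), 400)))
      fit_glm(Y, X, whitening = "ar1_global")$ar1_coeff
    }))
  }
  expect_equal(est(0.4), 0.4, tolerance = 0.03)
  expect_lt(abs(est(0)), 0.03)
})

test_that("global scaling normalizes the grand mean to 100", {
  Y <- matrix(50, 10, 10)
  expect_true(all(global_scale(Y) == 100))
  set.seed(2)
  Yr <- matrix(runif(200, 10, 20), 20)
  expect_equal(mean(global_scale(Yr)), 100)
  Y100 <- Yr * (100 / mean(Yr))
  expect_equal(global_scale(Y100), Y100)
  expect_error(global_scale(Yr - 100), "positive")
})

test_that("contrasts behave linearly with planted effects", {
  ev <- data.frame(condition = rep(c("whole_body", "chair"), 2),
                   onset = c(15, 45, 75, 105), duration = 12)
  X <- build_design_matrix(ev, n_volumes = 50, tr = 3,
                           conditions = c("whole_body", "chair"))
  B <- rbind(whole_body = c(2, 2), chair = c(1, 1))
  set.seed(3)
  Y <- X$matrix[, 1:2] %*% B + matrix(rnorm(100, sd = 0.1), 50)
  fit <- fit_glm(Y, X)
  c0 <- compute_contrast(fit, c(0, 0))
  expect_true(all(c0$effect == 0))
  c1 <- compute_contrast(fit, c(1, -1))
  expect_equal(c1$effect, rep(1, 2), tolerance = 0.2)
  c2 <- compute_contrast(fit, c(-1, 1))
  expect_equal(c2$t, -c1$t)
  # noiseless: effect exactly 1
  cx <- compute_contrast(fit_glm(X$matrix[, 1:2] %*% B, X), c(1, -1))
  expect_equal(cx$effect, rep(1, 2), tolerance = 1e-10)
  expect_error(compute_contrast(fit, c(1, -1, 0)), "length")
})

test_that("sphere ROIs enumerate the lattice correctly", {
  roi <- make_sphere_roi(c(0, 0, 0), radius_mm = 8, grid_spacing_mm = 2)
  # independent brute-force count of lattice points with x^2+y^2+z^2 <= 16
  g <- expand.grid(x = -4:4, y = -4:4, z = -4:4)
  expect_equal(roi$n_voxels, sum(g$x^2 + g$y^2 + g$z^2 <= 16))
  expect_equal(roi$n_voxels, 257L)
  expect_equal(roi$n_voxels * roi$voxel_volume, 2056)

  expect_equal(make_sphere_roi(c(0, 0, 0), radius_mm = 0.9,
                               grid_spacing_mm = 2)$n_voxels, 1L)
  # translation by one grid step translates the voxel set identically
  r0 <- make_sphere_roi(c(0, 0, 0))
  r1 <- make_sphere_roi(c(2, 0, 0))
  expect_equal(unname(sweep(r1$coords, 2, c(2, 0, 0))),
               unname(r0$coords))
})

test_that("activation detection thresholds at the t quantile", {
  tm <- structure(list(effect = rep(0, 5), se = rep(1, 5), t = rep(0, 5),
                       dof = 100, undefined = rep(FALSE, 5)),
                  class = "contrast_map")
  a0 <- detect_activation(tm)
  expect_false(a0$activated)
  expect_equal(a0$volume, 0)
  expect_equal(a0$threshold, qt(0.99, 100), tolerance = 1e-12)
  expect_equal(round(a0$threshold, 3), 2.364)

  tm$t[3] <- 10
  a1 <- detect_activation(tm)
  expect_true(a1$activated)
  expect_equal(a1$n_suprathreshold_voxels, 1L)
  expect_equal(a1$volume, 8)
  expect_equal(a1$peak_voxel, 3L)
})

test_that("ROI beta extraction preserves structure", {
  b <- matrix(1:40, 8, 5,
              dimnames = list(BODY_PART_CONDITIONS, NULL))
  runs <- list(b, b * 2)
  all_v <- extract_roi_betas(runs)
  expect_identical(all_v[[1]], b)
  one <- extract_roi_betas(runs, voxels = 3)
  expect_equal(ncol(one[[1]]), 1)
  # disjoint ROIs reconstruct the full matrix
  left <- extract_roi_betas(runs, voxels = 1:2)
  right <- extract_roi_betas(runs, voxels = 3:5)
  expect_equal(cbind(left[[2]], right[[2]]), b * 2)
  # row subsetting preserves condition order
  sub <- extract_roi_betas(runs, conditions = c("waist", "hand"))
  expect_identical(rownames(sub[[1]]), c("waist", "hand"))
})
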