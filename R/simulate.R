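#' Category membership of the stimulus conditions
#'
#' Maps each condition to its hypothesized category: the four action-effector
#' body parts (hand, foot, arm, leg), the two noneffector body parts (chest,
#' waist), the two face parts, and the whole-body and chair control conditions.
#'
#' @param conditions Condition labels; defaults to all ten.
#' @return Named character vector of category labels.
#' @export
condition_categories <- function(conditions = CONDITIONS) {
  map <- c(whole_body = "whole_body", chair = "chair",
           hand = "effector", foot = "effector",
           arm = "effector", leg = "effector",
           chest = "noneffector", waist = "noneffector",
           upper_face = "face", lower_face = "face")
  unknown <- setdiff(conditions, names(map))
  if (length(unknown))
    stop("condition_categories: unknown conditions: ",
         paste(unknown, collapse = ", "))
  map[conditions]
}

#' Generate ground-truth voxel patterns with a planted category geometry
#'
#' Each body-part condition's pattern is a mixture
#' `sqrt(kappa) * prototype(category) + sqrt(1 - kappa) * unique(condition)`
#' of a shared category prototype and a condition-specific component, all
#' i.i.d. standard normal across voxels. The expected correlation between two
#' same-category patterns is therefore `kappa`; distinct-category patterns are
#' uncorrelated in expectation. The whole-body and chair patterns are
#' independent, with the whole-body mean amplitude exceeding the chair mean by
#' `contrast_gain` (the planted univariate localizer contrast).
#'
#' @param n_voxels Number of voxels (>= 2).
#' @param cohesion Within-category pattern cohesion `kappa` in \[0, 1\].
#' @param contrast_gain Mean whole-body minus chair amplitude.
#' @param seed Integer seed.
#' @param conditions Condition labels (default all ten).
#' @return An object of class `ground_truth_patterns` with an `amplitudes`
#'   condition x voxel matrix, the `category_map`, `cohesion` and
#'   `contrast_gain`.
#' @export
generate_patterns <- function(n_voxels, cohesion, contrast_gain = 1,
                              seed = 1L, conditions = CONDITIONS) {
  if (!is.finite(cohesion) || cohesion < 0 || cohesion > 1)
    stop("generate_patterns: cohesion must lie in [0, 1]")
  if (n_voxels < 2) stop("generate_patterns: n_voxels must be >= 2")
  categories <- condition_categories(conditions)
  body_cats <- c("effector", "noneffector", "face")
  amp <- with_seed(derive_seed(seed, 211L), {
    protos <- sapply(body_cats, function(g) rnorm(n_voxels))
    t(sapply(conditions, function(cn) {
      u <- rnorm(n_voxels)
      g <- categories[[cn]]
      if (g %in% body_cats) {
        sqrt(cohesion) * protos[, g] + sqrt(1 - cohesion) * u
      } else if (g == "whole_body") {
        u + contrast_gain
      } else u
    }))
  })
  dimnames(amp) <- list(conditions, NULL)
  structure(list(amplitudes = amp, category_map = categories,
                 cohesion = cohesion, contrast_gain = contrast_gain),
            class = "ground_truth_patterns")
}

#' Simulate a BOLD run from a schedule and planted patterns
#'
#' Forward model inverted by the GLM stage: the condition boxcars of the
#' schedule are convolved with the canonical HRF, scaled by the planted
#' amplitudes, and corrupted by a slow cosine drift (one cycle per run,
#' voxel-specific random phase) and AR(1) Gaussian noise. A constant baseline
#' keeps the signal positive so global scaling is well defined.
#'
#' @param schedule A `stimulus_schedule`.
#' @param patterns A `ground_truth_patterns`; its conditions must cover the
#'   schedule's.
#' @param noise_sd Innovation SD of the AR(1) noise (>= 0).
#' @param ar1_coeff AR(1) coefficient, |coefficient| < 1.
#' @param drift_amplitude Amplitude of the cosine drift (signal units).
#' @param seed Integer seed.
#' @param baseline Constant offset added to every sample.
#' @return voxel x volume matrix.
#' @export
simulate_bold <- function(schedule, patterns, noise_sd = 1, ar1_coeff = 0.2,
                          drift_amplitude = 0, seed = 1L, baseline = 100) {
  stopifnot(inherits(schedule, "stimulus_schedule"),
            inherits(patterns, "ground_truth_patterns"))
  if (noise_sd < 0) stop("simulate_bold: noise_sd must be >= 0")
  if (abs(ar1_coeff) >= 1) stop("simulate_bold: |ar1_coeff| must be < 1")
  missing <- setdiff(unique(schedule$events$condition),
                     rownames(patterns$amplitudes))
  if (length(missing))
    stop("simulate_bold: schedule conditions missing from patterns: ",
         paste(missing, collapse = ", "))
  B <- patterns$amplitudes
  V <- ncol(B)
  n <- schedule$n_volumes
  X <- condition_regressors(schedule$events, n_volumes = n, tr = schedule$tr,
                            conditions = rownames(B))
  signal <- t(X %*% B)                       # voxel x volume
  with_seed(derive_seed(seed, 223L), {
    tsec <- (seq_len(n) - 1) * schedule$tr
    drift <- if (drift_amplitude > 0) {
      phase <- runif(V, 0, 2 * pi)
      drift_amplitude *
        cos(outer(phase, 2 * pi * tsec / schedule$total_duration, `+`))
    } else 0
    noise <- if (noise_sd > 0) {
      e <- matrix(rnorm(V * n, sd = noise_sd), V, n)
      if (ar1_coeff != 0) {
        e[, 1] <- e[, 1] / sqrt(1 - ar1_coeff^2)  # stationary start
        for (t in 2:n) e[, t] <- ar1_coeff * e[, t - 1] + e[, t]
      }
      e
    } else 0
    signal + drift + noise + baseline
  })
}

#' Simulate a rigid-body motion trace
#'
#' Independent Gaussian random walks for the six realignment parameters
#' (3 translations in mm, 3 rotations in radians).
#'
#' @param n_volumes Number of volumes.
#' @param step_sd_mm Per-volume step SD of the translations (mm).
#' @param step_sd_rad Per-volume step SD of the rotations (radians).
#' @param seed Integer seed.
#' @return n_volumes x 6 matrix with columns trans_x..trans_z, rot_x..rot_z.
#' @export
simulate_motion <- function(n_volumes, step_sd_mm = 0.02,
                            step_sd_rad = 2e-4, seed = 1L) {
  if (step_sd_mm < 0 || step_sd_rad < 0)
    stop("simulate_motion: step SDs must be >= 0")
  m <- with_seed(derive_seed(seed, 227L), {
    steps <- cbind(matrix(rnorm(n_volumes * 3, sd = step_sd_mm), n_volumes, 3),
                   matrix(rnorm(n_volumes * 3, sd = step_sd_rad), n_volumes, 3))
    steps[1, ] <- 0
    apply(steps, 2, cumsum)
  })
  m <- matrix(m, nrow = n_volumes)
  colnames(m) <- c("trans_x", "trans_y", "trans_z",
                   "rot_x", "rot_y", "rot_z")
  m
}

#' Default cohort generation configuration
#'
#' Two groups matching the study cohort: 26 adults and 22 children/adolescents.
#' Cohesion (`kappa`), noise and motion levels differ by group: the
#' child/adolescent group gets lower mean cohesion, more thermal noise and
#' larger motion steps (calibrated so mean framewise displacement lands near
#' 0.19 mm vs 0.10 mm for adults). Trait scores are linear in each
#' participant's cohesion plus Gaussian noise, with configurable slope.
#'
#' @param n_adult,n_child Group sizes.
#' @param n_voxels Voxels per simulated ROI.
#' @param kappa_mean,kappa_sd Named per-group mean/SD of the cohesion draw
#'   (truncated to \[0, 1\]).
#' @param noise_sd Named per-group AR(1) innovation SD.
#' @param ar1_coeff AR(1) coefficient of the noise.
#' @param drift_amplitude Cosine drift amplitude.
#' @param motion_step_mm,motion_step_rad Named per-group motion random-walk
#'   step SDs.
#' @param motion_scatter_sdlog Log-SD of the unit-mean lognormal participant
#'   motion scale factor.
#' @param contrast_gain Planted whole-body minus chair amplitude.
#' @param trait_slope Slope of trait score on cohesion.
#' @param trait_noise_sd SD of the trait noise.
#' @param spec The `design_spec` shared by all participants.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_adult = 26L, n_child = 22L,
                          n_voxels = 120L,
                          kappa_mean = c(adult = 0.7, child_adolescent = 0.6),
                          kappa_sd = c(adult = 0.10, child_adolescent = 0.15),
                          noise_sd = c(adult = 1.0, child_adolescent = 1.5),
                          ar1_coeff = 0.2,
                          drift_amplitude = 1,
                          motion_step_mm = c(adult = 0.025,
                                             child_adolescent = 0.047),
                          motion_step_rad = c(adult = 3.5e-4,
                                              child_adolescent = 6.6e-4),
                          motion_scatter_sdlog = 0.6,
                          contrast_gain = 1,
                          trait_slope = 5,
                          trait_noise_sd = 1,
                          spec = design_spec()) {
  if (n_adult < 1L || n_child < 1L)
    stop("cohort_config: group sizes must be positive")
  structure(as.list(environment()), class = "cohort_config")
}

#' Trait score names carried by simulated participants
#' @export
TRAIT_NAMES <- c("SRS", "AQ", "SP_low_registration", "SP_sensory_seeking",
                 "SP_sensory_sensitivity", "SP_sensation_avoiding",
                 "DCDQ", "MABC2", "age", "FSIQ")

#' Generate a simulated cohort
#'
#' Draws one participant at a time: a cohesion value from the group's
#' (truncated) normal, ground-truth patterns, per-run schedules, BOLD arrays
#' and motion traces, plus ten trait scores generated as
#' `trait_slope * kappa + noise` so rank-correlation recovery is testable.
#' All derived seeds are recorded.
#'
#' @param config A `cohort_config`.
#' @param seed Master integer seed.
#' @return An object of class `simulated_cohort`: list of participants (each
#'   with `id`, `group`, `kappa`, `bold` list of voxel x volume matrices,
#'   `motion` list, `patterns`, `schedules`, `traits`) plus the config and
#'   seed.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  groups <- c(rep("adult", config$n_adult),
              rep("child_adolescent", config$n_child))
  participants <- lapply(seq_along(groups), function(i) {
    g <- groups[i]
    pseed <- derive_seed(seed, 401L, i)
    kappa <- with_seed(derive_seed(pseed, 1L),
      min(1, max(0, rnorm(1, config$kappa_mean[[g]], config$kappa_sd[[g]]))))
    patterns <- generate_patterns(config$n_voxels, kappa,
                                  contrast_gain = config$contrast_gain,
                                  seed = derive_seed(pseed, 2L),
                                  conditions = config$spec$conditions)
    schedules <- build_design(config$spec, seed = derive_seed(pseed, 3L))
    bold <- lapply(schedules, function(s)
      simulate_bold(s, patterns,
                    noise_sd = config$noise_sd[[g]],
                    ar1_coeff = config$ar1_coeff,
                    drift_amplitude = config$drift_amplitude,
                    seed = derive_seed(pseed, 4L, s$run_index)))
    # per-participant motion amplitude: lognormal scatter (unit mean) around
    # the group level, so framewise displacement varies across participants
    # with SD comparable to its mean, as in real cohorts
    msig <- config$motion_scatter_sdlog
    mscale <- with_seed(derive_seed(pseed, 7L),
                        exp(stats::rnorm(1, -msig^2 / 2, msig)))
    motion <- lapply(schedules, function(s)
      simulate_motion(s$n_volumes,
                      step_sd_mm = mscale * config$motion_step_mm[[g]],
                      step_sd_rad = mscale * config$motion_step_rad[[g]],
                      seed = derive_seed(pseed, 5L, s$run_index)))
    traits <- with_seed(derive_seed(pseed, 6L), {
      v <- config$trait_slope * kappa +
        rnorm(length(TRAIT_NAMES), sd = config$trait_noise_sd)
      names(v) <- TRAIT_NAMES
      v
    })
    list(id = sprintf("sub-%02d", i), group = g, kappa = kappa, seed = pseed,
         patterns = patterns, schedules = schedules,
         bold = bold, motion = motion, traits = traits)
  })
  structure(list(participants = participants, config = config, seed = seed),
            class = "simulated_cohort")
}

#' @export
print.simulated_cohort <- function(x, ...) {
  tab <- table(vapply(x$participants, `[[`, "", "group"))
  cat("Simulated cohort:",
      paste(sprintf("%s n=%d", names(tab), tab), collapse = ", "),
      sprintf("| %d voxels, seed %d\n", x$config$n_voxels, x$seed))
  invisible(x)
}

#' Write a cohort to a directory
#'
#' One portable array file per run per participant (CSV, voxel x volume), a
#' tab-separated participants table with group and trait columns, and a YAML
#' config recording all generation parameters and the master seed.
#'
#' @param cohort A `simulated_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in cohort$participants) {
    for (r in seq_along(p$bold)) {
      utils::write.csv(p$bold[[r]],
                       file.path(dir, sprintf("%s_run-%d_bold.csv", p$id, r)),
                       row.names = FALSE)
      utils::write.csv(p$motion[[r]],
                       file.path(dir, sprintf("%s_run-%d_motion.csv", p$id, r)),
                       row.names = FALSE)
    }
  }
  traits <- do.call(rbind, lapply(cohort$participants, function(p)
    data.frame(id = p$id, group = p$group, kappa = p$kappa,
               t(p$traits), check.names = FALSE)))
  utils::write.table(traits, file.path(dir, "participants.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  cfg <- cohort$config
  cfg$spec <- unclass(cfg$spec)
  writeLines(jsonlite::toJSON(list(seed = cohort$seed,
                                   config = unclass(cfg)),
                              auto_unbox = TRUE, pretty = TRUE, digits = NA),
             file.path(dir, "cohort_config.json"))
  invisible(dir)
}
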