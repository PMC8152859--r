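#' Full-pipeline configuration
#'
#' Bundles the cohort generation parameters with the analysis options of every
#' downstream stage. All stage seeds are derived deterministically from the
#' master seed passed to [run_pipeline()].
#'
#' @param cohort A [cohort_config()].
#' @param hpf_cutoff High-pass period cutoff in seconds.
#' @param whitening `"ar1_global"` (default, as in the first-level model) or
#'   `"none"`.
#' @param global_scaling Proportionally scale each run to grand mean 100.
#' @param use_motion_regressors Enter the six motion parameters as nuisance
#'   regressors.
#' @param n_dummy Leading volumes discarded per run.
#' @param activation_p Uncorrected threshold for individual activation
#'   detection.
#' @param mantel_permutations Permutations for the Mantel test.
#' @param mantel_exact Enumerate all 8! relabelings instead.
#' @param svm_cost,n_bootstraps Decoder options.
#' @param decode_labels Run the decoder (TRUE) — the label-permutation variant
#'   is available separately via [partition_permutation_test()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            hpf_cutoff = 128,
                            whitening = "ar1_global",
                            global_scaling = TRUE,
                            use_motion_regressors = TRUE,
                            n_dummy = 5L,
                            activation_p = 0.01,
                            mantel_permutations = 9999,
                            mantel_exact = FALSE,
                            svm_cost = 1,
                            n_bootstraps = 100,
                            decode_labels = TRUE) {
  structure(as.list(environment()), class = "pipeline_config")
}

# first-level fits for one participant: list of per-run beta_estimates
fit_participant_glm <- function(p, config) {
  lapply(seq_along(p$bold), function(r) {
    run <- discard_dummies(p$bold[[r]], p$schedules[[r]],
                           motion = p$motion[[r]], n_dummy = config$n_dummy)
    Y <- t(run$bold)                       # volumes x voxels
    if (config$global_scaling) Y <- global_scale(Y)
    X <- build_design_matrix(run$events, run$n_volumes, run$tr,
                             motion = if (config$use_motion_regressors)
                               run$motion,
                             hpf_cutoff = config$hpf_cutoff,
                             conditions = run$conditions)
    fit_glm(Y, X, whitening = config$whitening)
  })
}

#' Run the complete analysis pipeline on a simulated cohort
#'
#' simulate -> first-level GLM -> localizer contrast and activation detection
#' -> split-half RDMs -> group mean RDMs, MDS, ANOSIM (complete 420-partition
#' permutation), Mantel between group-mean RDMs -> within/between-group
#' representational correlations with mixed ANOVA (plus FD-adjusted ANCOVA)
#' -> three-class decoding -> framewise displacement and group/trait
#' statistics. Deterministic given (config, seed).
#'
#' @param config A `pipeline_config`.
#' @param seed Master integer seed.
#' @param out_dir Optional directory; when given, tables are written as CSV
#'   and the summary as JSON.
#' @return Object of class `run_report`.
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1L,
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- generate_cohort(config$cohort, seed = derive_seed(seed, 11L))
  parts <- cohort$participants
  groups <- vapply(parts, `[[`, "", "group")
  ids <- vapply(parts, `[[`, "", "id")
  conds10 <- config$cohort$spec$conditions

  fits <- lapply(parts, fit_participant_glm, config = config)

  # localizer: whole body vs chair, activation within the (whole) synthetic ROI
  cvec <- as.numeric(conds10 == "whole_body") -
    as.numeric(conds10 == "chair")
  activation <- lapply(fits, function(f)
    detect_activation(compute_contrast(f, cvec),
                      p_uncorrected = config$activation_p))
  activated <- vapply(activation, `[[`, TRUE, "activated")
  act_table <- table(group = groups, activated = factor(activated,
                                                        c(TRUE, FALSE)))
  act_chisq <- tryCatch(chi_square_2x2(act_table),
                        error = function(e) e$message)
  act_size <- vapply(activation, `[[`, 0, "volume")
  size_t <- tryCatch(
    two_sample_t(act_size[groups == "adult"],
                 act_size[groups == "child_adolescent"], mode = "student"),
    error = function(e) e$message)

  # RSA
  body_betas <- lapply(fits, extract_roi_betas,
                       conditions = BODY_PART_CONDITIONS)
  rdms <- lapply(body_betas, split_half_rdm)
  names(rdms) <- ids
  group_levels <- unique(groups)
  group_rdms <- lapply(group_levels, function(g) mean_rdm(rdms[groups == g]))
  names(group_rdms) <- group_levels
  group_mds <- lapply(group_rdms, mds_embed, seed = derive_seed(seed, 13L))
  group_anosim <- lapply(group_rdms, anosim_permutation_test)
  participant_anosim <- lapply(rdms, anosim_permutation_test)
  mantel <- mantel_test(group_rdms[[1]], group_rdms[[2]],
                        n_permutations = config$mantel_permutations,
                        seed = derive_seed(seed, 17L),
                        exact = config$mantel_exact)

  # head motion
  fd <- vapply(parts, function(p)
    mean(vapply(p$motion, function(m) framewise_displacement(m)$mean_fd, 0)),
    0)
  fd_t <- two_sample_t(fd[groups == "child_adolescent"],
                       fd[groups == "adult"], mode = "welch")

  # within/between representational correlations, ANOVA and FD-adjusted ANCOVA
  wb <- within_between_correlations(rdms, groups)
  wb_long <- data.frame(
    id = rep(wb$id, 2), group = rep(wb$group, 2),
    type = rep(c("within", "between"), each = nrow(wb)),
    r = c(wb$within, wb$between),
    fd = rep(fd, 2))
  wb_anova <- mixed_anova(wb_long, "r", within = "type", between = "group",
                          subject = "id")
  wb_ancova <- mixed_anova(wb_long, "r", within = "type", between = "group",
                           subject = "id", covariate = "fd")

  # decoding
  decoding <- NULL
  decode_stats <- NULL
  if (config$decode_labels) {
    decoding <- lapply(seq_along(parts), function(i)
      decode(body_betas[[i]], svm_cost = config$svm_cost,
             n_bootstraps = config$n_bootstraps,
             seed = derive_seed(seed, 19L, i)))
    amc <- vapply(decoding, `[[`, 0, "accuracy_minus_chance")
    one_sample <- lapply(group_levels, function(g) {
      v <- amc[groups == g]
      if (stats::sd(v) > 0) {
        tt <- stats::t.test(v)
        list(group = g, mean = mean(v), t = unname(tt$statistic),
             df = unname(tt$parameter), p = tt$p.value)
      } else {
        # degenerate: every participant at the same accuracy
        list(group = g, mean = mean(v),
             t = if (mean(v) == 0) 0 else Inf,
             df = length(v) - 1, p = if (mean(v) == 0) 1 else 0)
      }
    })
    decode_stats <- list(
      accuracy_minus_chance = amc,
      by_group = one_sample,
      group_t = tryCatch(
        two_sample_t(amc[groups == "adult"],
                     amc[groups == "child_adolescent"], mode = "student"),
        error = function(e) e$message))
  }

  # trait correlations in the child/adolescent group
  child <- groups == "child_adolescent"
  child_R <- vapply(participant_anosim[child], `[[`, 0, "R")
  traits <- as.data.frame(do.call(rbind,
                                  lapply(parts[child], `[[`, "traits")))
  trait_report <- tryCatch(spearman_with_bonferroni(child_R, traits),
                           error = function(e) e$message)
  if (inherits(trait_report, "correlation_report")) {
    top_trait <- trait_report$table$score[which.min(trait_report$table$p)]
    trait_partial <- tryCatch(
      partial_correlation(child_R, traits[[top_trait]], fd[child]),
      error = function(e) e$message)
  } else {
    top_trait <- NA_character_
    trait_partial <- NULL
  }

  report <- structure(list(
    seed = seed, config = config,
    participants = data.frame(
      id = ids, group = groups,
      kappa = vapply(parts, `[[`, 0, "kappa"),
      activated = activated, activation_volume = act_size,
      anosim_R = vapply(participant_anosim, `[[`, 0, "R"),
      anosim_P = vapply(participant_anosim, `[[`, 0, "P"),
      mean_fd = fd,
      accuracy_minus_chance = if (!is.null(decode_stats))
        decode_stats$accuracy_minus_chance else NA_real_),
    activation = list(table = act_table, chisq = act_chisq,
                      size_t = size_t),
    group_rdms = group_rdms,
    group_mds = group_mds,
    group_anosim = group_anosim,
    mantel = mantel,
    within_between = wb,
    wb_anova = wb_anova,
    wb_ancova = wb_ancova,
    fd_t = fd_t,
    decoding = decode_stats,
    traits = list(report = trait_report, top_trait = top_trait,
                  partial_fd = trait_partial)
  ), class = "run_report")

  if (!is.null(out_dir)) write_run_report(report, out_dir)
  report
}

summary_list <- function(x) {
  ga <- lapply(names(x$group_anosim), function(g) {
    a <- x$group_anosim[[g]]
    list(group = g, R = a$R, P = a$P, rank = a$rank)
  })
  list(
    seed = x$seed,
    anosim = ga,
    mantel = list(R = x$mantel$R, P = x$mantel$P),
    activation_chisq = if (inherits(x$activation$chisq, "chi_square_result"))
      unclass(x$activation$chisq) else list(note = x$activation$chisq),
    fd_t = unclass(x$fd_t),
    wb_anova = x$wb_anova$effects,
    wb_ancova = x$wb_ancova$effects,
    decoding = if (!is.null(x$decoding)) list(
      by_group = x$decoding$by_group,
      group_t = unclass(x$decoding$group_t)),
    traits = if (inherits(x$traits$report, "correlation_report")) list(
      table = x$traits$report$table,
      corrected_threshold = x$traits$report$corrected_threshold,
      top_trait = x$traits$top_trait,
      partial_fd = x$traits$partial_fd)
    else list(note = x$traits$report)
  )
}

write_run_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$participants,
                   file.path(out_dir, "participants.csv"), row.names = FALSE)
  for (g in names(report$group_rdms))
    utils::write.csv(report$group_rdms[[g]]$matrix,
                     file.path(out_dir, sprintf("rdm_%s.csv", g)),
                     row.names = TRUE)
  for (g in names(report$group_mds)) {
    m <- report$group_mds[[g]]
    utils::write.csv(data.frame(condition = rownames(m$points), m$points,
                                stress = m$stress),
                     file.path(out_dir, sprintf("mds_%s.csv", g)),
                     row.names = FALSE)
  }
  for (g in names(report$group_anosim)) {
    a <- report$group_anosim[[g]]
    parts <- enumerate_partitions()
    utils::write.csv(data.frame(parts, R = a$null_R,
                                hypothesized = seq_len(nrow(parts)) ==
                                  a$hypothesized_index),
                     file.path(out_dir, sprintf("anosim_partitions_%s.csv", g)),
                     row.names = FALSE)
  }
  utils::write.csv(report$within_between,
                   file.path(out_dir, "within_between.csv"), row.names = FALSE)
  writeLines(jsonlite::toJSON(summary_list(report), auto_unbox = TRUE,
                              pretty = TRUE, digits = NA, force = TRUE),
             file.path(out_dir, "summary.json"))
  invisible(out_dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run (seed ", x$seed, ")\n", sep = "")
  tab <- table(x$participants$group)
  cat("  Cohort: ", paste(sprintf("%s n=%d", names(tab), tab),
                          collapse = ", "), "\n", sep = "")
  for (g in names(x$group_anosim)) {
    a <- x$group_anosim[[g]]
    cat(sprintf("  ANOSIM [%s]: R = %.3f, P = %.3f\n", g, a$R, a$P))
  }
  cat(sprintf("  Mantel between group RDMs: R = %.3f, P = %.4g\n",
              x$mantel$R, x$mantel$P))
  if (inherits(x$activation$chisq, "chi_square_result"))
    cat(sprintf("  Activation ratio: chi2(1) = %.3f, P = %.3f, V = %.2f\n",
                x$activation$chisq$statistic, x$activation$chisq$p,
                x$activation$chisq$cramers_v))
  else cat("  Activation ratio: ", x$activation$chisq, "\n", sep = "")
  cat(sprintf("  Mean FD (child vs adult): t(%.1f) = %.3f, P = %.3g, d = %.2f\n",
              x$fd_t$df, x$fd_t$t, x$fd_t$p, x$fd_t$cohens_d))
  if (!is.null(x$decoding)) {
    for (g in x$decoding$by_group)
      cat(sprintf(
        "  Decoding [%s]: accuracy - chance = %.3f, t(%g) = %.2f, P = %.3g\n",
        g$group, g$mean, g$df, g$t, g$p))
  }
  if (!is.na(x$traits$top_trait) && is.list(x$traits$partial_fd))
    cat(sprintf(
      "  Top trait correlate (child group): %s, partial r(%d) = %.3f, P = %.3f\n",
      x$traits$top_trait, x$traits$partial_fd$df,
      x$traits$partial_fd$r, x$traits$partial_fd$p))
  invisible(x)
}

#' Summarize a completed pipeline run
#'
#' Prints the run's headline statistics (ANOSIM R and P per group, Mantel R,
#' activation chi-square, FD group t-test, ANOVA/ANCOVA F values, decoding
#' statistics, trait correlations). Accepts a `run_report` object or a
#' directory written by [run_pipeline()].
#'
#' @param run A `run_report` or a path to a run output directory.
#' @return The summary list, invisibly.
#' @export
report <- function(run) {
  if (inherits(run, "run_report")) {
    print(run)
    return(invisible(summary_list(run)))
  }
  stopifnot(is.character(run))
  f <- file.path(run, "summary.json")
  missing <- setdiff(c("summary.json", "participants.csv",
                       "within_between.csv"), list.files(run))
  if (length(missing))
    stop("report: missing stage outputs in ", run, ": ",
         paste(missing, collapse = ", "))
  s <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  cat("Pipeline run (seed ", s$seed, ")\n", sep = "")
  for (a in s$anosim)
    cat(sprintf("  ANOSIM [%s]: R = %.3f, P = %.3f\n", a$group, a$R, a$P))
  cat(sprintf("  Mantel between group RDMs: R = %.3f, P = %.4g\n",
              s$mantel$R, s$mantel$P))
  if (!is.null(s$activation_chisq$statistic))
    cat(sprintf("  Activation ratio: chi2(1) = %.3f, P = %.3f, V = %.2f\n",
                s$activation_chisq$statistic, s$activation_chisq$p,
                s$activation_chisq$cramers_v))
  cat(sprintf("  Mean FD: t(%.1f) = %.3f, P = %.3g, d = %.2f\n",
              s$fd_t$df, s$fd_t$t, s$fd_t$p, s$fd_t$cohens_d))
  invisible(s)
}
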