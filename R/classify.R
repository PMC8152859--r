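#' Leave-one-run-out cross-validation folds
#'
#' @param n_runs Number of runs (>= 2).
#' @return List of folds, each `list(train, test)` of run indices.
#' @export
loro_folds <- function(n_runs) {
  if (n_runs < 2) stop("loro_folds: need >= 2 runs")
  lapply(seq_len(n_runs), function(r)
    list(train = setdiff(seq_len(n_runs), r), test = r))
}

# samples: one row per (run, condition) with the run-level beta pattern
build_sample_set <- function(roi_betas, partition) {
  conds <- names(partition)
  X <- do.call(rbind, lapply(seq_along(roi_betas), function(r)
    as.matrix(roi_betas[[r]])[conds, , drop = FALSE]))
  meta <- data.frame(run = rep(seq_along(roi_betas), each = length(conds)),
                     condition = rep(conds, length(roi_betas)),
                     class = factor(rep(unname(partition),
                                        length(roi_betas))),
                     stringsAsFactors = FALSE)
  list(meta = meta, features = X)
}

#' Balanced bootstrap subsamples of an unbalanced training set
#'
#' For a design with unequal class sizes (4 effector vs 2 noneffector vs 2
#' face conditions), each bootstrap draws, without replacement, `min` class
#' count samples from every class, yielding balanced training sets.
#' Deterministic given `seed`.
#'
#' @param classes Factor/vector of class labels, one per training sample.
#' @param n_bootstraps Number of subsamples (default 100).
#' @param seed Integer seed.
#' @return List of integer index vectors into the training samples.
#' @export
balanced_subsample <- function(classes, n_bootstraps = 100, seed = 1L) {
  classes <- as.factor(classes)
  counts <- table(classes)
  if (any(counts == 0)) stop("balanced_subsample: empty class")
  m <- min(counts)
  by_class <- split(seq_along(classes), classes)
  with_seed(derive_seed(seed, 601L),
    lapply(seq_len(n_bootstraps), function(b)
      unlist(lapply(by_class, function(ix)
        if (length(ix) == m) sample(ix) else sample(ix, m)),
        use.names = FALSE)))
}

#' Three-class linear SVM decoding with leave-one-run-out cross-validation
#'
#' One sample per condition per run (the run-level ROI beta pattern), labeled
#' by the partition's classes. For each fold, features are standardized with
#' training-fold statistics (zero-variance features dropped with a warning),
#' the unbalanced training set is reduced to balanced bootstrap subsamples,
#' and a linear soft-margin SVM (one-vs-one multiclass) is trained per
#' subsample and evaluated on the held-out run. Accuracy is averaged over
#' bootstraps, then folds, and reported against the 1/3 chance level.
#'
#' @param roi_betas List of per-run condition x voxel beta matrices.
#' @param partition Named class assignment over the conditions to decode
#'   (default the hypothesized three-category model).
#' @param svm_cost Soft-margin cost (default 1).
#' @param n_bootstraps Balanced subsamples per fold (default 100).
#' @param seed Integer seed.
#' @return Object of class `cv_result`: `fold_accuracy`, `accuracy`,
#'   `accuracy_minus_chance`, `chance`, `n_bootstraps`.
#' @export
decode <- function(roi_betas, partition = hypothesized_partition(),
                   svm_cost = 1, n_bootstraps = 100, seed = 1L) {
  if (length(roi_betas) < 2) stop("decode: need >= 2 runs")
  ss <- build_sample_set(roi_betas, partition)
  n_classes <- nlevels(ss$meta$class)
  folds <- loro_folds(length(roi_betas))
  fold_acc <- vapply(seq_along(folds), function(fi) {
    f <- folds[[fi]]
    tr <- ss$meta$run %in% f$train
    Xtr <- ss$features[tr, , drop = FALSE]
    Xte <- ss$features[!tr, , drop = FALSE]
    mu <- colMeans(Xtr)
    sdv <- apply(Xtr, 2, stats::sd)
    keep <- sdv > 0
    if (!all(keep))
      warning(sprintf("decode: dropping %d zero-variance feature(s) in fold %d",
                      sum(!keep), fi))
    Xtr <- scale(Xtr[, keep, drop = FALSE], mu[keep], sdv[keep])
    Xte <- scale(Xte[, keep, drop = FALSE], mu[keep], sdv[keep])
    ytr <- ss$meta$class[tr]
    yte <- ss$meta$class[!tr]
    boots <- balanced_subsample(ytr, n_bootstraps,
                                seed = derive_seed(seed, 607L, fi))
    accs <- vapply(boots, function(ix) {
      fit <- e1071::svm(Xtr[ix, , drop = FALSE], ytr[ix],
                        kernel = "linear", cost = svm_cost, scale = FALSE)
      mean(stats::predict(fit, Xte) == yte)
    }, 0)
    mean(accs)
  }, 0)
  acc <- mean(fold_acc)
  structure(list(fold_accuracy = fold_acc,
                 accuracy = acc,
                 chance = 1 / n_classes,
                 accuracy_minus_chance = acc - 1 / n_classes,
                 n_bootstraps = n_bootstraps),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "Leave-one-run-out decoding: accuracy %.1f%% (chance %.1f%%, +%.1f pts; %d bootstraps)\n",
    100 * x$accuracy, 100 * x$chance, 100 * x$accuracy_minus_chance,
    x$n_bootstraps))
  invisible(x)
}

#' Complete-enumeration class-label permutation test for decoding
#'
#' Runs the full cross-validated decoder for every labeled (4, 2, 2)
#' assignment of the eight conditions to the three classes — all 420
#' combinations, the hypothesized labeling included once. P counts
#' alternatives whose accuracy-minus-chance strictly exceeds the
#' hypothesized one, plus one: `P = (1 + #{acc_alt > acc_hyp}) / 420`.
#'
#' @param roi_betas List of per-run condition x voxel beta matrices.
#' @param hypothesized The class assignment under test.
#' @param sizes Class sizes for the enumeration.
#' @param svm_cost,n_bootstraps,seed Passed to [decode()].
#' @return Object of class `class_permutation_result`: `observed`, `null`
#'   (420 accuracy-minus-chance values), `P`, `rank`.
#' @export
partition_permutation_test <- function(roi_betas,
                                       hypothesized = hypothesized_partition(),
                                       sizes = c(4L, 2L, 2L),
                                       svm_cost = 1, n_bootstraps = 100,
                                       seed = 1L) {
  parts <- enumerate_partitions(names(hypothesized), sizes)
  null_acc <- vapply(seq_len(nrow(parts)), function(i) {
    p <- parts[i, ]
    decode(roi_betas, p, svm_cost = svm_cost, n_bootstraps = n_bootstraps,
           seed = derive_seed(seed, 613L, i))$accuracy_minus_chance
  }, 0)
  hyp_idx <- which(apply(parts, 1, function(p)
    all(p == hypothesized[colnames(parts)])))
  if (length(hyp_idx) != 1L)
    stop("partition_permutation_test: hypothesized labeling not found once")
  obs <- null_acc[hyp_idx]
  n_greater <- sum(null_acc[-hyp_idx] > obs)
  structure(list(observed = obs, null = null_acc,
                 P = (1 + n_greater) / nrow(parts),
                 rank = 1L + n_greater,
                 n_partitions = nrow(parts)),
            class = "class_permutation_result")
}

#' @export
print.class_permutation_result <- function(x, ...) {
  cat(sprintf(
    "Label-permutation decoding test: observed accuracy - chance = %.3f, P = %.3f (%d labelings)\n",
    x$observed, x$P, x$n_partitions))
  invisible(x)
}
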