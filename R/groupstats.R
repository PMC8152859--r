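#' 2 x 2 chi-square test with Cramer's V
#'
#' Pearson chi-square on a 2 x 2 contingency table (group x activated), by
#' default without Yates continuity correction, plus Cramer's V
#' (`sqrt(chi2 / N)`).
#'
#' @param table 2 x 2 matrix of nonnegative counts.
#' @param continuity_correction Apply the Yates correction (default FALSE).
#' @return Object of class `chi_square_result`: `statistic`, `df`, `p`,
#'   `cramers_v`, `n`.
#' @export
chi_square_2x2 <- function(table, continuity_correction = FALSE) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("chi_square_2x2: zero marginal, statistic undefined")
  ct <- suppressWarnings(stats::chisq.test(table,
                                           correct = continuity_correction))
  structure(list(statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p = ct$p.value,
                 cramers_v = sqrt(unname(ct$statistic) / sum(table)),
                 n = sum(table)),
            class = "chi_square_result")
}

#' @export
print.chi_square_result <- function(x, ...) {
  cat(sprintf("chi2(%d) = %.3f, P = %.3f, Cramer's V = %.2f (N = %d)\n",
              x$df, x$statistic, x$p, x$cramers_v, x$n))
  invisible(x)
}

#' Two-sample t-test with Cohen's d
#'
#' Student or Welch two-sample t-test, from raw samples or from per-group
#' summary statistics `list(mean =, sd =, n =)`. Cohen's d always uses the
#' pooled SD (the conventional reporting choice, also alongside Welch t).
#'
#' @param x,y Numeric samples, or summary lists.
#' @param mode `"welch"` (default) or `"student"`.
#' @return Object of class `t_test_result`: `t`, `df` (fractional for Welch),
#'   `p` (two-sided), `cohens_d`, `mode`.
#' @export
two_sample_t <- function(x, y, mode = c("welch", "student")) {
  mode <- match.arg(mode)
  summarize <- function(v) {
    if (is.list(v)) {
      stopifnot(all(c("mean", "sd", "n") %in% names(v)))
      v
    } else {
      if (length(v) < 2) stop("two_sample_t: each sample needs n >= 2")
      list(mean = mean(v), sd = stats::sd(v), n = length(v))
    }
  }
  a <- summarize(x); b <- summarize(y)
  if (a$sd == 0 && b$sd == 0)
    stop("two_sample_t: zero variance in both samples")
  v1 <- a$sd^2 / a$n; v2 <- b$sd^2 / b$n
  if (mode == "welch") {
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (a$n - 1) + v2^2 / (b$n - 1))
  } else {
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
    df <- a$n + b$n - 2
  }
  t <- (a$mean - b$mean) / se
  sp <- sqrt(((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2))
  structure(list(t = t, df = df,
                 p = 2 * stats::pt(-abs(t), df),
                 cohens_d = (a$mean - b$mean) / sp,
                 mode = mode),
            class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("t(%.4g) = %.3f, P = %.3g, d = %.2f (%s)\n",
              x$df, x$t, x$p, x$cohens_d, x$mode))
  invisible(x)
}

#' Mixed-design two-way ANOVA with partial eta squared
#'
#' Classical mixed-model sums of squares for one between-subject factor and
#' one within-subject factor on a balanced long table: the between effect (and
#' an optional participant-level covariate, grand-mean centered) is tested
#' against the subject-within-group error; the within effect and the
#' interaction against the subject x within error. Partial eta squared is
#' `SS_effect / (SS_effect + SS_error)` with the effect's own error stratum.
#'
#' @param data Long data frame.
#' @param dv Name of the response column.
#' @param within Name of the within-subject factor column.
#' @param between Name of the between-subject factor column.
#' @param subject Name of the subject identifier column.
#' @param covariate Optional name of a participant-level covariate column.
#' @return Object of class `mixed_anova_result`: data frame `effects` with
#'   columns effect, ss, df1, df2, F, p, partial_eta_sq.
#' @export
mixed_anova <- function(data, dv, within, between, subject,
                        covariate = NULL) {
  d <- data.frame(y = data[[dv]],
                  w = factor(data[[within]]),
                  b = factor(data[[between]]),
                  s = factor(data[[subject]]))
  tab <- table(d$s, d$w)
  if (any(tab != 1))
    stop("mixed_anova: design must be balanced (every subject x within cell ",
         "exactly once)")
  if (!is.null(covariate)) {
    cv <- tapply(data[[covariate]], d$s, function(v) v[1])
    d$cov <- as.numeric(cv[as.character(d$s)]) -
      mean(as.numeric(cv[as.character(d$s)]))
    fit <- stats::aov(y ~ cov + b * w + Error(s), data = d)
  } else {
    fit <- stats::aov(y ~ b * w + Error(s), data = d)
  }
  sm <- summary(fit)
  rows <- list()
  for (stratum in sm) {
    st <- stratum[[1]]
    terms <- trimws(rownames(st))
    err <- which(terms == "Residuals")
    ss_err <- st[err, "Sum Sq"]; df_err <- st[err, "Df"]
    for (i in setdiff(seq_len(nrow(st)), err)) {
      ss <- st[i, "Sum Sq"]
      rows[[length(rows) + 1L]] <- data.frame(
        effect = terms[i], ss = ss, df1 = st[i, "Df"], df2 = df_err,
        F = st[i, "F value"], p = st[i, "Pr(>F)"],
        partial_eta_sq = ss / (ss + ss_err))
    }
  }
  eff <- do.call(rbind, rows)
  eff$effect <- sub("^cov$", covariate %||% "cov",
                    sub("^b$", between,
                        sub("^w$", within,
                            sub("^b:w$", paste(between, within, sep = ":"),
                                eff$effect))))
  structure(list(effects = eff,
                 within = within, between = between,
                 covariate = covariate),
            class = "mixed_anova_result")
}

#' @export
print.mixed_anova_result <- function(x, ...) {
  cat(sprintf("Mixed ANOVA (%s between x %s within%s)\n", x$between,
              x$within,
              if (!is.null(x$covariate))
                paste0(", covariate ", x$covariate) else ""))
  e <- x$effects
  for (i in seq_len(nrow(e)))
    cat(sprintf("  %-20s F(%g, %g) = %.3f, P = %.3f, p-eta2 = %.3f\n",
                e$effect[i], e$df1[i], e$df2[i], e$F[i], e$p[i],
                e$partial_eta_sq[i]))
  invisible(x)
}

#' Bonferroni-corrected pairwise paired comparisons of a within factor
#'
#' Paired t-tests between every pair of within-factor levels, with corrected
#' p = min(1, m * raw p) for m comparisons.
#'
#' @param data Long data frame (balanced over subjects).
#' @param dv,within,subject Column names.
#' @param correction `"bonferroni"` (the only option) or `"none"`.
#' @return Data frame: level_a, level_b, t, df, p_raw, p_corrected.
#' @export
posthoc_pairwise <- function(data, dv, within, subject,
                             correction = c("bonferroni", "none")) {
  correction <- match.arg(correction)
  w <- factor(data[[within]])
  lev <- levels(w)
  m <- choose(length(lev), 2)
  y <- data[[dv]]
  s <- factor(data[[subject]])
  out <- list()
  for (i in seq_along(lev)) for (j in seq_along(lev)) {
    if (i >= j) next
    yi <- y[w == lev[i]][order(s[w == lev[i]])]
    yj <- y[w == lev[j]][order(s[w == lev[j]])]
    diffs <- yi - yj
    if (stats::sd(diffs) == 0) {
      t <- 0; df <- length(diffs) - 1; p <- 1
    } else {
      tt <- stats::t.test(yi, yj, paired = TRUE)
      t <- unname(tt$statistic); df <- unname(tt$parameter); p <- tt$p.value
    }
    out[[length(out) + 1L]] <- data.frame(
      level_a = lev[i], level_b = lev[j], t = t, df = df, p_raw = p,
      p_corrected = if (correction == "bonferroni") min(1, m * p) else p)
  }
  do.call(rbind, out)
}

#' Spearman correlations against a set of trait scores, Bonferroni-corrected
#'
#' Rank correlation (average ranks for ties) of `x` with each score column;
#' the corrected significance threshold is `alpha / m` for m scores
#' (0.05 / 10 = 0.005 for the default ten-trait battery).
#'
#' @param x Numeric vector (e.g. per-participant ANOSIM R values).
#' @param scores Data frame or matrix of trait scores (one column per score).
#' @param alpha Familywise level (default 0.05).
#' @return Object of class `correlation_report`: data frame `table` (score,
#'   rho, n, p, significant_uncorrected, significant_corrected) and
#'   `corrected_threshold`.
#' @export
spearman_with_bonferroni <- function(x, scores, alpha = 0.05) {
  scores <- as.data.frame(scores)
  m <- ncol(scores)
  if (m < 1) stop("spearman_with_bonferroni: need >= 1 score")
  thr <- alpha / m
  rows <- lapply(names(scores), function(nm) {
    y <- scores[[nm]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 4)
      stop("spearman_with_bonferroni: need n >= 4 for score ", nm)
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      stop("spearman_with_bonferroni: constant vector for score ", nm)
    ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = "spearman"))
    data.frame(score = nm, rho = unname(ct$estimate), n = sum(ok),
               p = ct$p.value,
               significant_uncorrected = ct$p.value < alpha,
               significant_corrected = ct$p.value < thr)
  })
  structure(list(table = do.call(rbind, rows),
                 corrected_threshold = thr, alpha = alpha),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("Spearman correlations (Bonferroni threshold %.4g)\n",
              x$corrected_threshold))
  t <- x$table
  for (i in seq_len(nrow(t)))
    cat(sprintf("  %-24s rho(%d) = %+.3f, P = %.3f%s\n", t$score[i],
                t$n[i] - 2, t$rho[i], t$p[i],
                if (t$significant_corrected[i]) " *"
                else if (t$significant_uncorrected[i]) " ." else ""))
  invisible(x)
}

#' Partial correlation controlling for one covariate
#'
#' Pearson correlation between the residuals of `x` and `y` after each is
#' regressed on the covariate; tested on n - 3 degrees of freedom.
#'
#' @param x,y Numeric vectors.
#' @param covariate Numeric vector.
#' @return List: `r`, `df` (= n - 3), `p` (two-sided).
#' @export
partial_correlation <- function(x, y, covariate) {
  ok <- is.finite(x) & is.finite(y) & is.finite(covariate)
  x <- x[ok]; y <- y[ok]; z <- covariate[ok]
  n <- length(x)
  if (n < 4) stop("partial_correlation: need n >= 4")
  rx <- stats::lm.fit(cbind(1, z), x)$residuals
  ry <- stats::lm.fit(cbind(1, z), y)$residuals
  if (stats::sd(rx) < 1e-10 * (stats::sd(x) + 1) ||
      stats::sd(ry) < 1e-10 * (stats::sd(y) + 1))
    stop("partial_correlation: covariate collinear with x or y")
  r <- stats::cor(rx, ry)
  df <- n - 3
  t <- r * sqrt(df / (1 - r^2))
  list(r = r, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Framewise displacement from a motion trace
#'
#' `FD_t = sum |delta translations| + radius * sum |delta rotations|` for
#' volumes t >= 2, FD_1 = 0; rotations are converted to mm as arc length on a
#' 50-mm sphere (the standard convention).
#'
#' @param motion n_volumes x 6 matrix: 3 translations (mm), 3 rotations
#'   (radians).
#' @param rotation_radius_mm Sphere radius for the rotation conversion.
#' @return Object of class `fd_series`: `fd` (per volume, mm), `mean_fd`.
#' @export
framewise_displacement <- function(motion, rotation_radius_mm = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) stop("framewise_displacement: need 6 columns")
  n <- nrow(motion)
  fd <- numeric(n)
  if (n > 1) {
    d <- abs(diff(motion))
    fd[-1] <- rowSums(d[, 1:3, drop = FALSE]) +
      rotation_radius_mm * rowSums(d[, 4:6, drop = FALSE])
  }
  structure(list(fd = fd, mean_fd = mean(fd)), class = "fd_series")
}

#' @export
print.fd_series <- function(x, ...) {
  cat(sprintf("Framewise displacement: mean %.3f mm over %d volumes\n",
              x$mean_fd, length(x$fd)))
  invisible(x)
}
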