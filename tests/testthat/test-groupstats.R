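test_that("chi-square worked examples reproduce the printed statistics", {
  a <- chi_square_2x2(rbind(c(26, 0), c(17, 5)))
  expect_equal(round(a$statistic, 3), 6.596)
  expect_equal(round(a$cramers_v, 2), 0.37)
  expect_equal(round(a$p, 3), 0.010)
  b <- chi_square_2x2(rbind(c(26, 0), c(21, 1)))
  expect_equal(round(b$statistic, 3), 1.207)
  expect_equal(round(b$cramers_v, 2), 0.16)
  eq <- chi_square_2x2(rbind(c(10, 5), c(10, 5)))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$cramers_v, 0)
  expect_error(chi_square_2x2(rbind(c(5, 0), c(7, 0))), "marginal")
})

test_that("chi-square equals the closed form over a grid of tables", {
  for (a in 1:4) for (b in 1:4) for (c in 1:4) for (d in 1:4) {
    tab <- rbind(c(a, b), c(c, d))
    N <- sum(tab)
    closed <- N * (a * d - b * c)^2 /
      ((a + b) * (c + d) * (a + c) * (b + d))
    expect_equal(chi_square_2x2(tab)$statistic, closed)
  }
})

test_that("Welch t from summary statistics reproduces the printed df", {
  w <- two_sample_t(list(mean = 0.19, sd = 0.14, n = 22),
                    list(mean = 0.10, sd = 0.06, n = 26), mode = "welch")
  expect_equal(round(w$df, 1), 27.5)
  expect_gt(w$t, 0)
  expect_lt(w$p, 0.05)

  s <- two_sample_t(list(mean = 1, sd = 1, n = 10),
                    list(mean = 0, sd = 2, n = 10), mode = "student")
  expect_equal(s$df, 18)
})

test_that("t-test is antisymmetric and agrees with stats::t.test", {
  set.seed(4)
  x <- rnorm(15, 1); y <- rnorm(20)
  w <- two_sample_t(x, y, mode = "welch")
  ref <- t.test(x, y)
  expect_equal(w$t, unname(ref$statistic))
  expect_equal(w$df, unname(ref$parameter))
  expect_equal(w$p, ref$p.value)
  flipped <- two_sample_t(y, x, mode = "welch")
  expect_equal(flipped$t, -w$t)
  expect_equal(flipped$cohens_d, -w$cohens_d)
  same <- two_sample_t(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$cohens_d, 0)
  expect_error(two_sample_t(rep(1, 5), rep(1, 5)), "zero variance")
})

# independent mixed-design decomposition straight from the SS formulas
brute_mixed_ss <- function(d) {
  gm <- mean(d$y)
  subj_means <- tapply(d$y, d$s, mean)
  grp_of_subj <- tapply(as.character(d$b), d$s, `[`, 1)
  grp_means <- tapply(d$y, d$b, mean)
  w_means <- tapply(d$y, d$w, mean)
  cell_means <- tapply(d$y, list(d$b, d$w), mean)
  n_w <- nlevels(d$w)
  n_per_grp <- table(grp_of_subj)
  ss_between_subj <- n_w * sum((subj_means - gm)^2)
  ss_group <- n_w * sum(n_per_grp * (grp_means[names(n_per_grp)] - gm)^2)
  ss_subj_err <- ss_between_subj - ss_group
  ss_within_total <- sum((d$y - subj_means[as.character(d$s)])^2)
  ss_w <- sum(table(d$w) * (w_means - gm)^2)
  ss_cells <- 0
  for (g in levels(d$b)) for (l in levels(d$w)) {
    n_cell <- sum(d$b == g & d$w == l)
    ss_cells <- ss_cells + n_cell * (cell_means[g, l] - gm)^2
  }
  ss_int <- ss_cells - ss_group - ss_w
  ss_w_err <- ss_within_total - ss_w - ss_int
  list(group = ss_group, subj_err = ss_subj_err, within = ss_w,
       interaction = ss_int, within_err = ss_w_err)
}

test_that("mixed ANOVA matches a brute-force sums-of-squares oracle", {
  set.seed(10)
  d <- expand.grid(s = factor(sprintf("s%02d", 1:8)),
                   w = factor(paste0("lvl", 1:4)))
  d$b <- factor(ifelse(as.integer(d$s) <= 4, "g1", "g2"))
  d$y <- rnorm(nrow(d)) + as.integer(d$w) * 0.5 +
    (d$b == "g2") * 1 + rnorm(8)[as.integer(d$s)]
  res <- mixed_anova(d, "y", within = "w", between = "b", subject = "s")
  ss <- brute_mixed_ss(d)
  e <- res$effects
  g <- e[e$effect == "b", ]
  expect_equal(g$F, (ss$group / 1) / (ss$subj_err / 6))
  expect_equal(g$partial_eta_sq, ss$group / (ss$group + ss$subj_err))
  wr <- e[e$effect == "w", ]
  expect_equal(wr$F, (ss$within / 3) / (ss$within_err / 18))
  ir <- e[e$effect == "b:w", ]
  expect_equal(ir$F, (ss$interaction / 3) / (ss$within_err / 18))
  expect_equal(ir$partial_eta_sq,
               ss$interaction / (ss$interaction + ss$within_err))
  # conservation: component SS add up to the total
  expect_equal(ss$group + ss$subj_err + ss$within + ss$interaction +
                 ss$within_err, sum((d$y - mean(d$y))^2))
  # partial eta squared bounded in [0, 1] on random data
  for (s in 1:20) {
    set.seed(s + 100)
    d$y <- rnorm(nrow(d))
    pe <- mixed_anova(d, "y", "w", "b", "s")$effects$partial_eta_sq
    expect_true(all(pe >= 0 & pe <= 1))
  }
})

test_that("identical groups yield a null group effect", {
  d <- expand.grid(s = factor(1:6), w = factor(c("a", "b")))
  d$b <- factor(rep(c("g1", "g2"), 3)[as.integer(d$s)])
  # subject offsets mirrored across groups: subjects vary, groups identical
  d$y <- c(0, 0, 1, 1, 2, 2)[as.integer(d$s)] + (d$w == "b")
  res <- mixed_anova(d, "y", "w", "b", "s")
  expect_lt(res$effects$F[res$effects$effect == "b"], 1e-10)
  expect_error(mixed_anova(d[-1, ], "y", "w", "b", "s"), "balanced")
})

test_that("ANCOVA enters the covariate in the between-subject stratum", {
  set.seed(12)
  subj <- sprintf("s%02d", 1:12)
  cov_val <- rnorm(12)
  d <- expand.grid(s = factor(subj), w = factor(c("a", "b")))
  d$b <- factor(rep(c("g1", "g2"), 6)[as.integer(d$s)])
  d$cv <- cov_val[as.integer(d$s)]
  d$y <- rnorm(nrow(d)) + 2 * d$cv
  res <- mixed_anova(d, "y", "w", "b", "s", covariate = "cv")
  e <- res$effects
  expect_true("cv" %in% e$effect)
  # covariate consumes one between-subject df
  expect_equal(e$df2[e$effect == "b"], 12 - 3)
  expect_gt(e$F[e$effect == "cv"], e$F[e$effect == "b"])
})

test_that("post hoc pairwise comparisons apply the Bonferroni correction", {
  set.seed(13)
  d <- expand.grid(s = factor(1:10), w = factor(paste0("c", 1:8)))
  d$y <- rnorm(nrow(d)) + as.integer(d$w)
  ph <- posthoc_pairwise(d, "y", "w", "s")
  expect_equal(nrow(ph), 28)
  expect_equal(ph$p_corrected, pmin(1, 28 * ph$p_raw))
  # identical levels: corrected p = 1
  d$y <- rep(rnorm(10), 8)
  ph0 <- posthoc_pairwise(d, "y", "w", "s")
  expect_true(all(ph0$p_corrected == 1))
})

test_that("Spearman trait screening uses the corrected threshold", {
  set.seed(14)
  x <- rnorm(22)
  scores <- data.frame(matrix(rnorm(22 * 10), 22))
  names(scores) <- TRAIT_NAMES
  rep10 <- spearman_with_bonferroni(x, scores)
  expect_equal(rep10$corrected_threshold, 0.005)
  expect_equal(nrow(rep10$table), 10)
  expect_true(all(rep10$table$rho >= -1 & rep10$table$rho <= 1))
  # perfectly monotone pair and monotone-transform invariance
  one <- spearman_with_bonferroni(x, data.frame(m = exp(x)))
  expect_equal(one$table$rho, 1)
  # rho invariant under strictly monotone transforms of either variable
  r1 <- spearman_with_bonferroni(x, data.frame(v = scores[[1]]))$table$rho
  r2 <- spearman_with_bonferroni(exp(x),
                                 data.frame(v = scores[[1]]^3 +
                                              scores[[1]]))$table$rho
  expect_equal(r2, r1)
  expect_error(spearman_with_bonferroni(rep(1, 22), scores), "constant")
})

test_that("partial correlation controls the covariate", {
  # independent covariate: partial r tracks the zero-order r
  diffs <- sapply(1:50, function(s) {
    set.seed(s)
    x <- rnorm(40); y <- 0.5 * x + rnorm(40); z <- rnorm(40)
    partial_correlation(x, y, z)$r - cor(x, y)
  })
  expect_lt(abs(mean(diffs)), 0.02)
  # y driven by the covariate only: partial r ~ 0
  prs <- sapply(1:50, function(s) {
    set.seed(s + 500)
    z <- rnorm(40); y <- z + rnorm(40, sd = 0.3); x <- rnorm(40)
    partial_correlation(x, y, z)$r
  })
  expect_lt(abs(mean(prs)), 0.05)
  pc <- partial_correlation(rnorm(21), rnorm(21), rnorm(21))
  expect_equal(pc$df, 18)
  z <- rnorm(20)
  expect_error(partial_correlation(z, rnorm(20), z), "collinear")
})

test_that("framewise displacement follows the displacement formula", {
  m <- matrix(0, 10, 6)
  expect_equal(framewise_displacement(m)$fd, rep(0, 10))
  m2 <- m; m2[5:10, 1] <- 1       # single 1-mm translation step
  fd2 <- framewise_displacement(m2)
  expect_equal(fd2$fd[5], 1)
  expect_equal(sum(fd2$fd), 1)
  m3 <- m; m3[3:10, 4:6] <- 0.02  # simultaneous rotation steps
  expect_equal(framewise_displacement(m3)$fd[3], 50 * 0.06)
  # offset invariance
  expect_equal(framewise_displacement(m2 + 5)$fd, fd2$fd)
  expect_equal(framewise_displacement(m[1, , drop = FALSE])$fd, 0)
})
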