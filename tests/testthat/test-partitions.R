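test_that("the (4,2,2) enumeration has 420 labeled partitions", {
  parts <- enumerate_partitions()
  expect_equal(nrow(parts), 420L)
  expect_true(all(apply(parts, 1, function(p)
    identical(as.integer(table(p)), c(4L, 2L, 2L)))))
  # hypothesized partition occurs exactly once
  hyp <- hypothesized_partition()
  expect_equal(sum(apply(parts, 1, function(p) all(p == hyp))), 1L)
  # no duplicated labeled partitions
  expect_equal(anyDuplicated(apply(parts, 1, paste, collapse = "")), 0L)
  # collapsing the two size-2 class labels leaves 210 unlabeled groupings
  unlabeled <- apply(parts, 1, function(p) {
    pairs <- sort(c(paste(which(p == 2L), collapse = "-"),
                    paste(which(p == 3L), collapse = "-")))
    paste(paste(which(p == 1L), collapse = "-"),
          pairs[1], pairs[2], sep = "|")
  })
  expect_equal(length(unique(unlabeled)), 210L)
})

test_that("ANOSIM R matches its rank-based definition", {
  # maximal separation: R = 1
  r <- clustered_rdm(seed = 1)
  expect_equal(anosim_r(r, hypothesized_partition()), 1)
  # no structure at all: all dissimilarities tied -> R = 0
  flat <- matrix(1, 8, 8); diag(flat) <- 0
  dimnames(flat) <- list(BODY_PART_CONDITIONS, BODY_PART_CONDITIONS)
  expect_equal(anosim_r(flat, hypothesized_partition()), 0)

  # 4-item toy, two classes of two, hand-computed rank means:
  # within ranks {1, 4}, between {2, 3, 5, 6} -> R = (4 - 2.5) / 3 = 0.5
  toy <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  toy["a", "b"] <- toy["b", "a"] <- 0.10   # within class 1, rank 1
  toy["a", "c"] <- toy["c", "a"] <- 0.20   # between, rank 2
  toy["a", "d"] <- toy["d", "a"] <- 0.30   # between, rank 3
  toy["b", "c"] <- toy["c", "b"] <- 0.40   # between, rank 5 (see below)
  toy["c", "d"] <- toy["d", "c"] <- 0.35   # within class 2, rank 4
  toy["b", "d"] <- toy["d", "b"] <- 0.50   # between, rank 6
  part <- c(a = 1L, b = 1L, c = 2L, d = 2L)
  expect_equal(anosim_r(toy, part), 0.5)
})

test_that("ANOSIM R is rank-invariant and class-label symmetric", {
  for (s in 1:20) {
    r <- random_rdm(s)
    hyp <- hypothesized_partition()
    R0 <- anosim_r(r, hyp)
    expect_equal(anosim_r(exp(r), hyp), R0)
    r_log <- r; r_log[lower.tri(r_log) | upper.tri(r_log)] <-
      log(r[lower.tri(r) | upper.tri(r)] + 1)
    expect_equal(anosim_r(r_log, hyp), R0)
    swapped <- hyp
    swapped[hyp == 2L] <- 3L
    swapped[hyp == 3L] <- 2L
    expect_equal(anosim_r(r, swapped), R0)
  }
})

test_that("ANOSIM matches a brute-force oracle on (2,2,2) toy problems", {
  # independent implementation straight from the definition
  brute_r <- function(m, part) {
    pairs <- combn(nrow(m), 2)
    d <- apply(pairs, 2, function(ij) m[ij[1], ij[2]])
    rk <- rank(d)
    same <- apply(pairs, 2, function(ij) part[ij[1]] == part[ij[2]])
    (mean(rk[!same]) - mean(rk[same])) / (length(d) / 2)
  }
  labels <- letters[1:6]
  parts6 <- enumerate_partitions(labels, sizes = c(2L, 2L, 2L))
  expect_equal(nrow(parts6), choose(6, 2) * choose(4, 2))   # 90
  for (s in 1:5) {
    set.seed(s)
    m <- matrix(0, 6, 6, dimnames = list(labels, labels))
    m[lower.tri(m)] <- runif(15)
    m <- m + t(m)
    for (i in seq_len(nrow(parts6))) {
      p <- parts6[i, ]
      expect_equal(anosim_r(m, p), brute_r(m, unname(p)))
    }
  }
})

test_that("the complete permutation test calibrates P on the 1/420 grid", {
  res <- anosim_permutation_test(clustered_rdm(seed = 2))
  expect_equal(res$R, 1)
  expect_equal(res$P, 1 / 420)
  expect_equal(round(res$P, 3), 0.002)
  expect_equal(res$rank, 1L)
  expect_length(res$null_R, 420)
  # exact enumeration property: the 420 R values average to zero
  expect_lt(abs(mean(res$null_R)), 1e-12)
  for (s in 1:10)
    expect_lt(abs(mean(anosim_permutation_test(random_rdm(s))$null_R)), 1e-12)
  # P lives on the k/420 grid
  ps <- sapply(1:20, function(s)
    anosim_permutation_test(random_rdm(s + 50))$P)
  expect_true(all(abs(ps * 420 - round(ps * 420)) < 1e-9))
})

test_that("hypothesized-partition P falls with planted cohesion", {
  p_at <- function(kappa, seeds) mean(sapply(seeds, function(s) {
    sim <- simulate_participant_betas(kappa, noise_sd = 1.5, n_voxels = 60,
                                      seed = s, whitening = "none",
                                      drift_amplitude = 0, ar1_coeff = 0)
    anosim_permutation_test(split_half_rdm(sim$body_betas))$P
  }))
  expect_lt(p_at(0.9, 1:5), p_at(0, 6:10))
})

test_that("Mantel test statistics and invariances", {
  a <- random_rdm(11)
  self <- mantel_test(a, a, n_permutations = 199, seed = 1)
  expect_equal(self$R, 1)
  affine <- mantel_test(a, 0.2 + 0.5 * a, n_permutations = 199, seed = 1)
  expect_equal(affine$R, 1)
  expect_lte(self$P, 0.05)
  b <- random_rdm(12)
  mt <- mantel_test(a, b, n_permutations = 499, seed = 2)
  expect_true(mt$P > 0 && mt$P <= 1)
  const <- matrix(1, 8, 8); diag(const) <- 0
  dimnames(const) <- list(BODY_PART_CONDITIONS, BODY_PART_CONDITIONS)
  expect_error(mantel_test(a, const), "constant")
  # exact enumeration agrees with the identity being extreme for a = b
  ex <- mantel_test(a, a, exact = TRUE)
  expect_equal(ex$n_permutations, factorial(8))
  expect_lt(ex$P, 0.001)
})

test_that("Mantel P is near-uniform under independence", {
  ps <- sapply(1:60, function(s)
    mantel_test(random_rdm(s + 300), random_rdm(s + 7000),
                n_permutations = 199, seed = s)$P)
  expect_equal(mean(ps), 0.5, tolerance = 0.12)
})

test_that("statistics agree with the vegan reference implementations", {
  suppressPackageStartupMessages(requireNamespace("vegan"))
  for (s in 1:10) {
    m <- random_rdm(s + 40)
    hyp <- hypothesized_partition()
    ref <- vegan::anosim(as.dist(m), grouping = factor(hyp),
                         permutations = 0)
    expect_equal(anosim_r(m, hyp), unname(ref$statistic))
    m2 <- random_rdm(s + 80)
    refm <- vegan::mantel(as.dist(m), as.dist(m2), permutations = 0)
    expect_equal(mantel_test(m, m2, n_permutations = 9)$R,
                 unname(refm$statistic))
  }
})
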