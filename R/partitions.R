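#' The hypothesized three-category partition
#'
#' Action effectors (hand, arm, leg, foot), noneffectors (chest, waist) and
#' face parts (upper face, lower face).
#'
#' @param conditions The eight body-part condition labels.
#' @return Named integer vector mapping each condition to class 1, 2 or 3.
#' @export
hypothesized_partition <- function(conditions = BODY_PART_CONDITIONS) {
  cats <- condition_categories(conditions)
  cls <- c(effector = 1L, noneffector = 2L, face = 3L)[cats]
  names(cls) <- conditions
  if (anyNA(cls))
    stop("hypothesized_partition: conditions outside the three categories")
  cls
}

#' Enumerate all labeled (4, 2, 2) partitions
#'
#' Every assignment of the `n` conditions to three labeled classes of sizes
#' given by `sizes`: choose the size-4 class, then the first size-2 class from
#' the remainder — `8C4 x 4C2 = 420` partitions for the default design, in
#' deterministic lexicographic order. The hypothesized partition occurs
#' exactly once.
#'
#' @param conditions Condition labels.
#' @param sizes Class sizes (default `c(4, 2, 2)`).
#' @return Integer matrix, one row per partition, one column per condition,
#'   entries in `1:length(sizes)`.
#' @export
enumerate_partitions <- function(conditions = BODY_PART_CONDITIONS,
                                 sizes = c(4L, 2L, 2L)) {
  n <- length(conditions)
  if (sum(sizes) != n)
    stop("enumerate_partitions: sizes must sum to the number of conditions")
  rows <- list()
  first <- utils::combn(n, sizes[1])
  for (i in seq_len(ncol(first))) {
    c1 <- first[, i]
    rest <- setdiff(seq_len(n), c1)
    if (length(sizes) == 3L) {
      second <- utils::combn(length(rest), sizes[2])
      for (j in seq_len(ncol(second))) {
        c2 <- rest[second[, j]]
        cls <- integer(n)
        cls[c1] <- 1L; cls[c2] <- 2L; cls[setdiff(rest, c2)] <- 3L
        rows[[length(rows) + 1L]] <- cls
      }
    } else if (length(sizes) == 2L) {
      cls <- integer(n)
      cls[c1] <- 1L; cls[rest] <- 2L
      rows[[length(rows) + 1L]] <- cls
    } else stop("enumerate_partitions: only 2 or 3 classes supported")
  }
  m <- do.call(rbind, rows)
  colnames(m) <- conditions
  m
}

# pair-level "same class" mask for one partition, in rdm_vector order
pair_same_class <- function(partition) {
  n <- length(partition)
  idx <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  partition[idx[, "row"]] == partition[idx[, "col"]]
}

#' ANOSIM R statistic
#'
#' Ranks the pairwise dissimilarities (ascending, average ranks for ties) and
#' contrasts between-class and within-class mean ranks:
#' `R = (mean between rank - mean within rank) / (M / 2)`, `M` the number of
#' pairs. `R` is 1 when every within-class dissimilarity falls below every
#' between-class one, 0 when class structure is absent.
#'
#' @param rdm A symmetrized `rdm` (or matrix).
#' @param partition Named/ordered class assignment over the RDM's conditions.
#' @return The R statistic.
#' @export
anosim_r <- function(rdm, partition) {
  r <- as_rdm(rdm)
  if (!r$symmetrized) stop("anosim_r: RDM must be symmetrized")
  d <- r$matrix[lower.tri(r$matrix)]
  rk <- rank(d)
  same <- pair_same_class(align_partition(partition, rownames(r$matrix)))
  (mean(rk[!same]) - mean(rk[same])) / (length(d) / 2)
}

align_partition <- function(partition, labels) {
  if (!is.null(names(partition)) && !is.null(labels)) {
    if (!setequal(names(partition), labels))
      stop("partition labels do not match RDM conditions")
    partition <- partition[labels]
  }
  partition
}

#' Complete-enumeration ANOSIM permutation test
#'
#' Computes R for the hypothesized partition and for all labeled (4, 2, 2)
#' reassignments of conditions to classes (420 in total). The P value counts
#' alternatives whose R strictly exceeds the hypothesized R, plus one for the
#' hypothesized model itself: `P = (1 + #{R_alt > R_hyp}) / 420`, so the
#' minimum attainable P is 1/420 (printed as 0.002).
#'
#' @param rdm A symmetrized `rdm`.
#' @param hypothesized Class assignment to test (default the three-category
#'   body-part model).
#' @param sizes Class sizes for the enumeration.
#' @return Object of class `anosim_result`: `R`, `P`, `rank` of the
#'   hypothesized partition, `null_R` (all 420 values in enumeration order),
#'   `n_partitions`.
#' @export
anosim_permutation_test <- function(rdm,
                                    hypothesized = hypothesized_partition(),
                                    sizes = c(4L, 2L, 2L)) {
  r <- as_rdm(rdm)
  labels <- rownames(r$matrix)
  hypothesized <- align_partition(hypothesized, labels)
  parts <- enumerate_partitions(labels %||% names(hypothesized) %||%
                                  seq_along(hypothesized), sizes)
  d <- r$matrix[lower.tri(r$matrix)]
  rk <- rank(d)
  M <- length(d)
  n <- nrow(r$matrix)
  idx <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  same <- parts[, idx[, "row"]] == parts[, idx[, "col"]]   # partitions x pairs
  nw <- rowSums(same)
  within_mean <- drop(same %*% rk) / nw
  between_mean <- drop((!same) %*% rk) / (M - nw)
  null_R <- (between_mean - within_mean) / (M / 2)
  hyp_idx <- which(apply(parts, 1, function(p) all(p == hypothesized)))
  if (length(hyp_idx) != 1L)
    stop("anosim_permutation_test: hypothesized partition not found exactly ",
         "once in the enumeration")
  R <- null_R[hyp_idx]
  n_greater <- sum(null_R[-hyp_idx] > R)
  structure(list(R = R,
                 P = (1 + n_greater) / nrow(parts),
                 rank = 1L + n_greater,
                 null_R = null_R,
                 hypothesized_index = hyp_idx,
                 n_partitions = nrow(parts)),
            class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf(
    "ANOSIM: R = %.3f, P = %.3f (complete enumeration, %d partitions, rank %d)\n",
    x$R, x$P, x$n_partitions, x$rank))
  invisible(x)
}

#' Mantel test between two RDMs
#'
#' The test statistic is the Pearson correlation between the two lower-
#' triangle vectors. The null distribution permutes the condition labels of
#' the second matrix (simultaneous row/column permutation); with
#' `exact = TRUE` all `n!` relabelings are enumerated, otherwise
#' `n_permutations` random relabelings are drawn. P is the fraction of null
#' statistics at least as large as the observed one, counting the identity /
#' observed statistic once.
#'
#' @param rdm_a,rdm_b Symmetrized `rdm`s with the same condition labels.
#' @param n_permutations Random permutations (default 9999; ignored when
#'   exact).
#' @param seed Integer seed.
#' @param exact Enumerate all relabelings (feasible for 8 conditions:
#'   40320).
#' @return Object of class `mantel_result`: `R`, `P`, `n_permutations`,
#'   `exact`.
#' @export
mantel_test <- function(rdm_a, rdm_b, n_permutations = 9999, seed = 1L,
                        exact = FALSE) {
  a <- as_rdm(rdm_a); b <- as_rdm(rdm_b)
  if (!a$symmetrized || !b$symmetrized)
    stop("mantel_test: RDMs must be symmetrized")
  la <- rownames(a$matrix); lb <- rownames(b$matrix)
  if (!is.null(la) && !is.null(lb)) {
    if (!setequal(la, lb)) stop("mantel_test: condition labels differ")
    b$matrix <- b$matrix[la, la]
  }
  va <- rdm_vector(a)
  if (stats::sd(va) == 0 || stats::sd(rdm_vector(b)) == 0)
    stop("mantel_test: constant RDM vector, correlation undefined")
  n <- nrow(a$matrix)
  stat <- function(perm) {
    m <- b$matrix[perm, perm]
    stats::cor(va, m[lower.tri(m)])
  }
  R <- stat(seq_len(n))
  if (exact) {
    perms <- e1071::permutations(n)
    null_R <- apply(perms, 1, stat)    # includes the identity
    P <- mean(null_R >= R - 1e-12)
    n_perm <- nrow(perms)
  } else {
    null_R <- with_seed(derive_seed(seed, 509L),
      vapply(seq_len(n_permutations), function(i) stat(sample(n)), 0))
    P <- (1 + sum(null_R >= R - 1e-12)) / (n_permutations + 1)
    n_perm <- n_permutations
  }
  structure(list(R = R, P = P, n_permutations = n_perm, exact = exact),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: R = %.3f, P = %.4g (%s, %d permutations)\n",
              x$R, x$P, if (x$exact) "exact" else "Monte Carlo",
              x$n_permutations))
  invisible(x)
}
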