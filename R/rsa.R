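#' Split-half representational dissimilarity matrix
#'
#' Averages per-condition beta patterns over odd runs (1, 3, ...) and even
#' runs (2, 4, ...) separately, then sets `D[i, j] = 1 - r` where `r` is the
#' Pearson correlation between condition i's odd-run pattern and condition j's
#' even-run pattern. The directional odd-vs-even matrix is symmetrized as
#' `(D + t(D)) / 2`; its diagonal is `1 -` split-half reliability, not forced
#' to zero.
#'
#' @param run_betas List of condition x voxel matrices, one per run in
#'   acquisition order (>= 1 odd and >= 1 even run, >= 2 voxels).
#' @param symmetrize Average with the transpose (default TRUE).
#' @return Object of class `rdm`: the dissimilarity `matrix` with condition
#'   dimnames and a `symmetrized` flag.
#' @export
split_half_rdm <- function(run_betas, symmetrize = TRUE) {
  stopifnot(length(run_betas) >= 2)
  run_betas <- lapply(run_betas, as.matrix)
  odd <- seq(1, length(run_betas), by = 2)
  even <- seq(2, length(run_betas), by = 2)
  if (ncol(run_betas[[1]]) < 2)
    stop("split_half_rdm: need >= 2 voxels")
  mean_half <- function(idx) Reduce(`+`, run_betas[idx]) / length(idx)
  A <- mean_half(odd)    # condition x voxel, odd-run mean
  B <- mean_half(even)
  flat <- function(M, side) {
    sds <- apply(M, 1, stats::sd)
    if (any(sds == 0))
      stop("split_half_rdm: zero-variance pattern in ", side, " half for: ",
           paste(rownames(M)[sds == 0], collapse = ", "))
  }
  flat(A, "odd"); flat(B, "even")
  D <- 1 - stats::cor(t(A), t(B))
  if (symmetrize) D <- (D + t(D)) / 2
  dimnames(D) <- list(rownames(run_betas[[1]]), rownames(run_betas[[1]]))
  structure(list(matrix = D, symmetrized = symmetrize), class = "rdm")
}

as_rdm <- function(m, symmetrized = NULL) {
  if (inherits(m, "rdm")) return(m)
  m <- as.matrix(m)
  structure(list(matrix = m,
                 symmetrized = symmetrized %||% isSymmetric(unname(m))),
            class = "rdm")
}

#' @export
print.rdm <- function(x, digits = 3, ...) {
  cat(sprintf("%dx%d RDM (1 - r)%s\n", nrow(x$matrix), ncol(x$matrix),
              if (x$symmetrized) ", symmetrized" else ""))
  print(round(x$matrix, digits))
  invisible(x)
}

#' Entrywise mean RDM
#'
#' @param rdms List of `rdm` objects with matching labels.
#' @param leave_out Optional index (or name) of one RDM to exclude, for
#'   leave-one-out group means.
#' @return An `rdm`.
#' @export
mean_rdm <- function(rdms, leave_out = NULL) {
  if (!is.null(leave_out)) {
    keep <- if (is.character(leave_out)) setdiff(names(rdms), leave_out)
            else setdiff(seq_along(rdms), leave_out)
    rdms <- rdms[keep]
  }
  if (!length(rdms)) stop("mean_rdm: no RDMs after exclusion")
  mats <- lapply(rdms, function(r) as_rdm(r)$matrix)
  as_rdm(Reduce(`+`, mats) / length(mats),
         symmetrized = all(vapply(rdms, function(r) as_rdm(r)$symmetrized,
                                  TRUE)))
}

#' Vectorize the lower triangle of an RDM
#'
#' Off-diagonal lower-triangle entries in a fixed order (column-major, the
#' same order used by every pairwise statistic in the package); for an 8 x 8
#' RDM this is the 28 unordered condition pairs.
#'
#' @param rdm An `rdm` (symmetrized) or matrix.
#' @param include_diagonal Also include the diagonal entries (appended last).
#' @return Numeric vector of length `n (n - 1) / 2` (+ n with diagonal).
#' @export
rdm_vector <- function(rdm, include_diagonal = FALSE) {
  r <- as_rdm(rdm)
  if (!r$symmetrized) stop("rdm_vector: RDM must be symmetrized")
  m <- r$matrix
  v <- m[lower.tri(m)]
  if (include_diagonal) v <- c(v, diag(m))
  v
}

# one SMACOF run: Guttman-transform majorization of raw stress
# sum_{i<j} (dist_ij(X) - delta_ij)^2; returns the configuration and
# Kruskal stress-1 sqrt(raw stress / sum dist^2)
smacof_fit <- function(delta, X, max_iter = 300, tol = 1e-10) {
  n <- nrow(delta)
  raw <- function(X) {
    D <- as.matrix(stats::dist(X))
    sum((D[lower.tri(D)] - delta[lower.tri(delta)])^2)
  }
  s_old <- raw(X)
  for (it in seq_len(max_iter)) {
    D <- as.matrix(stats::dist(X))
    ratio <- ifelse(D > 0, delta / D, 0)
    B <- -ratio
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    X <- B %*% X / n
    s_new <- raw(X)
    if (s_old - s_new < tol * (s_old + tol)) break
    s_old <- s_new
  }
  D <- as.matrix(stats::dist(X))
  list(points = X,
       stress = sqrt(raw(X) / sum(D[lower.tri(D)]^2)))
}

#' MDS embedding of an RDM
#'
#' Metric least-squares scaling: stress majorization (SMACOF) of the squared
#' misfit between embedded distances and the dissimilarities, reported as
#' Kruskal stress-1. The first start is the classical-scaling configuration,
#' further restarts are random; the lowest stress wins. `type = "nonmetric"`
#' switches to Kruskal nonmetric scaling (MASS::isoMDS).
#'
#' @param rdm A symmetrized `rdm`.
#' @param k Embedding dimension (default 2; must be < number of conditions).
#' @param n_restarts Number of random restarts beyond the metric start.
#' @param seed Integer seed for the restarts.
#' @param type `"metric"` (default) or `"nonmetric"`.
#' @return Object of class `mds_embedding`: `points` (condition x k), `stress`,
#'   `type`, `seed`.
#' @export
mds_embed <- function(rdm, k = 2, n_restarts = 8, seed = 1L,
                      type = c("metric", "nonmetric")) {
  type <- match.arg(type)
  r <- as_rdm(rdm)
  if (!r$symmetrized) stop("mds_embed: RDM must be symmetrized")
  m <- r$matrix
  n <- nrow(m)
  if (k >= n) stop("mds_embed: k must be below the number of conditions")
  delta <- unname(m)
  diag(delta) <- 0
  cmd <- suppressWarnings(stats::cmdscale(stats::as.dist(delta), k = k))
  if (ncol(cmd) < k)
    cmd <- cbind(cmd, matrix(0, n, k - ncol(cmd)))
  if (type == "nonmetric") {
    fit <- MASS::isoMDS(stats::as.dist(pmax(delta, 1e-12)), y = cmd, k = k,
                        trace = FALSE)
    pts <- fit$points
    stress <- fit$stress / 100
  } else {
    fits <- with_seed(derive_seed(seed, 433L), {
      starts <- c(list(cmd), lapply(seq_len(n_restarts), function(i)
        matrix(stats::rnorm(n * k), n, k)))
      lapply(starts, function(y0) smacof_fit(delta, y0))
    })
    best <- fits[[which.min(vapply(fits, `[[`, 0, "stress"))]]
    pts <- best$points
    stress <- best$stress
  }
  rownames(pts) <- rownames(m)
  colnames(pts) <- paste0("dim", seq_len(k))
  structure(list(points = pts, stress = stress, type = type, seed = seed),
            class = "mds_embedding")
}

#' @export
print.mds_embedding <- function(x, ...) {
  cat(sprintf("%s MDS embedding in %d dims, stress %.4g\n",
              x$type, ncol(x$points), x$stress))
  print(round(x$points, 3))
  invisible(x)
}

#' Within- and between-group representational correlations
#'
#' For each participant, the Pearson correlation between their RDM vector and
#' (a) the leave-one-out mean RDM of their own group and (b) the mean RDM of
#' the other group.
#'
#' @param rdms List of participant `rdm`s.
#' @param groups Character/factor group label per participant (exactly two
#'   groups, >= 2 participants each).
#' @return Data frame: `id`, `group`, `within`, `between`.
#' @export
within_between_correlations <- function(rdms, groups) {
  groups <- as.character(groups)
  stopifnot(length(rdms) == length(groups))
  gl <- unique(groups)
  if (length(gl) != 2) stop("within_between_correlations: need two groups")
  if (any(table(groups) < 2))
    stop("within_between_correlations: need >= 2 participants per group")
  vecs <- lapply(rdms, rdm_vector)
  if (any(vapply(vecs, stats::sd, 0) == 0))
    stop("within_between_correlations: zero-variance RDM vector")
  other_mean <- lapply(gl, function(g)
    rdm_vector(mean_rdm(rdms[groups == g])))
  names(other_mean) <- gl
  out <- lapply(seq_along(rdms), function(i) {
    g <- groups[i]
    own_idx <- setdiff(which(groups == g), i)
    within <- stats::cor(vecs[[i]], rdm_vector(mean_rdm(rdms[own_idx])))
    between <- stats::cor(vecs[[i]], other_mean[[setdiff(gl, g)]])
    data.frame(id = if (is.null(names(rdms))) i else names(rdms)[i],
               group = g,
               within = within, between = between)
  })
  do.call(rbind, out)
}
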