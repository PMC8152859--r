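# shared fixtures, built in code

# per-run betas from one simulated participant, after the full GLM stage
simulate_participant_betas <- function(kappa, noise_sd = 1, n_voxels = 80,
                                       seed = 1, whitening = "ar1_global",
                                       drift_amplitude = 1, ar1_coeff = 0.2) {
  sp <- design_spec()
  pat <- generate_patterns(n_voxels, kappa, seed = seed)
  sched <- build_design(sp, seed = seed + 1)
  fits <- lapply(sched, function(s) {
    bold <- simulate_bold(s, pat, noise_sd = noise_sd, ar1_coeff = ar1_coeff,
                          drift_amplitude = drift_amplitude,
                          seed = seed * 1000 + s$run_index)
    run <- discard_dummies(bold, s)
    X <- build_design_matrix(run$events, run$n_volumes, run$tr,
                             conditions = run$conditions)
    fit_glm(t(run$bold), X, whitening = whitening)
  })
  list(fits = fits,
       body_betas = extract_roi_betas(fits,
                                      conditions = BODY_PART_CONDITIONS),
       patterns = pat)
}

# RDM with planted three-cluster structure: within-class entries below `lo`,
# between-class entries above `hi`
clustered_rdm <- function(lo = 0.3, hi = 0.7, seed = 1,
                          partition = hypothesized_partition()) {
  n <- length(partition)
  m <- matrix(0, n, n, dimnames = list(names(partition), names(partition)))
  set.seed(seed)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    m[i, j] <- m[j, i] <- if (partition[i] == partition[j])
      runif(1, 0.05, lo) else runif(1, hi, 1.3)
  }
  m
}

# RDM with i.i.d. off-diagonal entries (no structure)
random_rdm <- function(seed, labels = BODY_PART_CONDITIONS) {
  n <- length(labels)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  set.seed(seed)
  m[lower.tri(m)] <- runif(n * (n - 1) / 2)
  m + t(m)
}

# pure-noise per-run beta matrices (no category signal)
noise_betas <- function(seed, n_runs = 4, n_voxels = 40,
                        conditions = BODY_PART_CONDITIONS) {
  set.seed(seed)
  lapply(seq_len(n_runs), function(r) {
    b <- matrix(rnorm(length(conditions) * n_voxels), length(conditions))
    rownames(b) <- conditions
    b
  })
}
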