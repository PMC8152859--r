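#' Body-part condition labels
#'
#' The ten stimulus conditions of the block design, in canonical order, and
#' the eight body-part conditions entering the representational analyses.
#'
#' @format Character vectors.
#' @export
CONDITIONS <- c("whole_body", "chair", "hand", "foot", "arm", "leg",
                "chest", "waist", "upper_face", "lower_face")

#' @rdname CONDITIONS
#' @export
BODY_PART_CONDITIONS <- c("hand", "foot", "arm", "leg",
                          "chest", "waist", "upper_face", "lower_face")

#' Construct a block-design specification
#'
#' Describes one run of the body-part localizer: 20 task blocks (10 conditions
#' x 2 repetitions) of 12 s each, a 27-s initial fixation baseline, 12-s
#' baselines after the 5th, 10th and 15th block, and a 15-s final baseline,
#' giving a 318-s run sampled at a 3-s TR (106 volumes). Each block shows 12
#' pictures for 500 ms with a 500-ms inter-stimulus interval; the full stimulus
#' set holds 44 pictures per condition.
#'
#' @param n_runs Number of runs (default 4).
#' @param conditions Ordered condition labels (default the 10 canonical ones).
#' @param blocks_per_condition_per_run Block repetitions per condition per run.
#' @param block_duration Block length in seconds.
#' @param tr Repetition time in seconds.
#' @param baseline_initial,baseline_interior,baseline_final Fixation baseline
#'   durations in seconds; the interior baseline is inserted after blocks 5,
#'   10 and 15.
#' @param n_dummy_volumes Leading volumes discarded before analysis.
#' @param pictures_per_block,picture_duration,isi Within-block stimulus timing
#'   (durations in milliseconds).
#' @param pictures_per_condition_in_set Stimulus-set size per condition.
#' @return An object of class `design_spec`.
#' @examples
#' sp <- design_spec()
#' run_duration(sp)      # 318
#' @export
design_spec <- function(n_runs = 4L,
                        conditions = CONDITIONS,
                        blocks_per_condition_per_run = 2L,
                        block_duration = 12,
                        tr = 3,
                        baseline_initial = 27,
                        baseline_interior = 12,
                        baseline_final = 15,
                        n_dummy_volumes = 5L,
                        pictures_per_block = 12L,
                        picture_duration = 500,
                        isi = 500,
                        pictures_per_condition_in_set = 44L) {
  spec <- structure(list(
    n_runs = as.integer(n_runs),
    conditions = as.character(conditions),
    blocks_per_condition_per_run = as.integer(blocks_per_condition_per_run),
    block_duration = block_duration,
    tr = tr,
    baseline_initial = baseline_initial,
    baseline_interior = baseline_interior,
    baseline_final = baseline_final,
    n_dummy_volumes = as.integer(n_dummy_volumes),
    pictures_per_block = as.integer(pictures_per_block),
    picture_duration = picture_duration,
    isi = isi,
    pictures_per_condition_in_set = as.integer(pictures_per_condition_in_set)
  ), class = "design_spec")
  validate_design_spec(spec)
  spec
}

validate_design_spec <- function(spec) {
  stopifnot(inherits(spec, "design_spec"))
  if (spec$n_runs < 1L) stop("design_spec: n_runs must be >= 1")
  if (length(spec$conditions) < 1L || anyDuplicated(spec$conditions))
    stop("design_spec: conditions must be unique labels")
  dur <- run_duration(spec)
  if (abs(dur %% spec$tr) > 1e-9)
    stop(sprintf(
      "design_spec: run duration (%g s) is not divisible by tr (%g s)",
      dur, spec$tr))
  stim <- spec$pictures_per_block * (spec$picture_duration + spec$isi) / 1000
  if (abs(stim - spec$block_duration) > 1e-9)
    stop(sprintf(paste0(
      "design_spec: pictures_per_block x (picture_duration + isi) = %g s ",
      "does not fill the %g-s block"), stim, spec$block_duration))
  invisible(spec)
}

n_blocks_per_run <- function(spec) {
  length(spec$conditions) * spec$blocks_per_condition_per_run
}

#' Run duration implied by a design specification
#'
#' Total time of one run: initial baseline + all task blocks + the three
#' interior baselines + final baseline.
#'
#' @param spec A `design_spec`.
#' @return Duration in seconds.
#' @export
run_duration <- function(spec) {
  spec$baseline_initial + 3 * spec$baseline_interior + spec$baseline_final +
    n_blocks_per_run(spec) * spec$block_duration
}

#' Build per-run stimulus schedules
#'
#' Lays out the block onsets for each run. Block order is an independent
#' uniform permutation per run, subject to each condition appearing the
#' configured number of times; a fixation baseline precedes block 1 and
#' follows blocks 5, 10, 15 and 20. Deterministic given `seed`.
#'
#' @param spec A `design_spec`.
#' @param seed Integer seed controlling the block orders.
#' @return A list with one `stimulus_schedule` per run; each has an `events`
#'   data frame (condition, onset, duration, seconds), `total_duration` and
#'   `n_volumes`.
#' @examples
#' sched <- build_design(design_spec(), seed = 1)
#' sched[[1]]$n_volumes   # 106
#' @export
build_design <- function(spec, seed = 1L) {
  validate_design_spec(spec)
  total <- run_duration(spec)
  n_vol <- as.integer(round(total / spec$tr))
  nb <- n_blocks_per_run(spec)
  pool <- rep(spec$conditions, each = spec$blocks_per_condition_per_run)
  # interior baselines follow blocks at the quarter points of the run
  interior_after <- n_blocks_per_run(spec) / 4 * c(1, 2, 3)
  lapply(seq_len(spec$n_runs), function(r) {
    order_r <- with_seed(derive_seed(seed, 101L, r),
                         sample(pool, length(pool)))
    onset <- spec$baseline_initial
    onsets <- numeric(nb)
    for (b in seq_len(nb)) {
      onsets[b] <- onset
      onset <- onset + spec$block_duration
      if (b %in% interior_after) onset <- onset + spec$baseline_interior
    }
    structure(list(
      run_index = r,
      events = data.frame(condition = order_r,
                          onset = onsets,
                          duration = rep(spec$block_duration, nb),
                          stringsAsFactors = FALSE),
      total_duration = total,
      n_volumes = n_vol,
      tr = spec$tr,
      conditions = spec$conditions
    ), class = "stimulus_schedule")
  })
}

#' Summarize design arithmetic
#'
#' @param spec A `design_spec`.
#' @return A list: `run_duration` (s), `n_volumes` per run, `analyzed_volumes`
#'   over all runs after discarding the leading dummy volumes, and
#'   `stimulus_set_size` (pictures across all conditions).
#' @examples
#' design_summary(design_spec())   # 318 s, 106, 404, 440
#' @export
design_summary <- function(spec) {
  validate_design_spec(spec)
  total <- run_duration(spec)
  n_vol <- as.integer(round(total / spec$tr))
  list(
    run_duration = total,
    n_volumes = n_vol,
    analyzed_volumes = (n_vol - spec$n_dummy_volumes) * spec$n_runs,
    stimulus_set_size = spec$pictures_per_condition_in_set *
      length(spec$conditions)
  )
}

#' @export
print.stimulus_schedule <- function(x, ...) {
  cat(sprintf("Stimulus schedule, run %d: %d blocks, %g s (%d volumes)\n",
              x$run_index, nrow(x$events), x$total_duration, x$n_volumes))
  invisible(x)
}
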