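#' Derive a per-trial seed from a master seed
#'
#' Counter-based scheme: seeds are bound to trial indices, not to execution
#' order, so results are invariant to how trials are scheduled.
#'
#' @param master_seed Integer master seed.
#' @param index Trial counter (1-based).
#' @return An integer seed below 2^31.
#' @export
derive_seed <- function(master_seed, index) {
  as.integer((as.double(master_seed) %% 2147483647 * 48271 + index * 7919) %% 2147483647)
}

exp_cells <- function(experiment_id) {
  switch(as.character(experiment_id),
    "1" = expand.grid(condition = c("baseline", "object_low", "object_high"),
                      contrast = LADDER_EXP13, stringsAsFactors = FALSE),
    "2" = expand.grid(condition = c("baseline", "object"),
                      isi_ms = c(107, 200, 307, 400, 507, 600, 707, 800),
                      stringsAsFactors = FALSE),
    "3" = expand.grid(condition = c("baseline", "object"),
                      contrast = LADDER_EXP13, stringsAsFactors = FALSE),
    "4" = data.frame(n_presentations = 2:9),
    "5" = rbind(
      expand.grid(direction = "ascending", end_contrast = LADDER_MAIN[2:9],
                  stringsAsFactors = FALSE),
      expand.grid(direction = "descending", end_contrast = LADDER_MAIN[1:8],
                  stringsAsFactors = FALSE)),
    "6" = merge(exp_cells(5), data.frame(start_reps = c(1, 4))),
    "7" = merge(exp_cells(5), data.frame(end_reps = c(1, 4))),
    "8" = exp_cells(5),
    "9" = rbind(
      expand.grid(direction = "ascending", end_contrast = LADDER_EXP9[2:9],
                  stringsAsFactors = FALSE),
      expand.grid(direction = "descending", end_contrast = LADDER_EXP9[1:8],
                  stringsAsFactors = FALSE)),
    "10" = expand.grid(condition = c("baseline", "object_low", "object_high"),
                       gap_arcmin = c(0, 1.65, 3.3, 4.95, 6.6, 9.9, 13.2, 16.5),
                       stringsAsFactors = FALSE),
    stop("invalid input: unknown experiment ", experiment_id, call. = FALSE))
}

build_cell_protocol <- function(experiment_id, cell) {
  switch(as.character(experiment_id),
    "1" = build_pair_trial(1, cell$condition, probe_contrast = cell$contrast),
    "2" = build_pair_trial(2, cell$condition, isi_ms = cell$isi_ms),
    "3" = build_pair_trial(3, cell$condition, probe_contrast = cell$contrast),
    "4" = build_stability_trial(cell$n_presentations),
    "5" = build_ladder_trial(cell$direction, cell$end_contrast),
    "6" = build_ladder_trial(cell$direction, cell$end_contrast,
                             start_reps = cell$start_reps),
    "7" = build_ladder_trial(cell$direction, cell$end_contrast,
                             end_reps = cell$end_reps),
    "8" = build_ladder_trial(cell$direction, cell$end_contrast, blank_ms = 614),
    "9" = build_ladder_trial(cell$direction, cell$end_contrast, frame_ms = 116))
}

#' Run a full simulated experiment
#'
#' Enumerates the design cells of one of the ten experiments, builds a fresh
#' randomized protocol per trial, simulates the field, and scores every
#' trial. Trial seeds are derived deterministically from the master seed, so
#' the run is fully reproducible from `(params, master_seed)`.
#'
#' @param experiment_id 1..10.
#' @param params A `field_params` object (the single shared set; pass an
#'   [ablate()]d copy for ablation analyses).
#' @param n_trials_per_cell Simulated trials per design cell.
#' @param master_seed Integer master seed.
#' @param ablations Character vector of component ablations applied to
#'   `params` before running.
#' @param criterion Visibility criterion fraction.
#' @return An `experiment_run`: list with `results` (one row per trial),
#'   `experiment_id`, `params_hash`, `master_seed`, `ablations`.
#' @export
run_experiment <- function(experiment_id, params = default_params(),
                           n_trials_per_cell = 200, master_seed = 1,
                           ablations = character(), criterion = 0.25) {
  for (ab in ablations) params <- ablate(params, ab)
  if (experiment_id == 10)
    return(run_experiment10(params, n_trials_per_cell, master_seed, ablations,
                            criterion))
  cells <- exp_cells(experiment_id)
  rows <- vector("list", nrow(cells) * n_trials_per_cell)
  idx <- 0L
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, , drop = FALSE]
    for (tr in seq_len(n_trials_per_cell)) {
      idx <- idx + 1L
      seed <- derive_seed(master_seed, (ci - 1L) * n_trials_per_cell + tr)
      set.seed(seed)
      prot <- build_cell_protocol(experiment_id, cell)
      prot$experiment_id <- as.integer(experiment_id)
      rec <- simulate_frames(prot, params, seed = NULL, record_stride = 0)
      res <- score_trial(rec, prot, criterion)
      row <- data.frame(
        experiment_id = as.integer(experiment_id),
        seed = seed,
        initial_visible = res$initial_visible,
        n_switches = res$n_switches,
        any_switch = res$any_switch,
        first_switch_direction = res$first_switch_direction,
        visible_seq = paste(ifelse(res$per_frame_visible, "V", "I"),
                            collapse = ""),
        stringsAsFactors = FALSE)
      rows[[idx]] <- cbind(row, cell, row.names = NULL)
    }
  }
  results <- do.call(rbind, rows)
  structure(list(results = results, experiment_id = experiment_id,
                 params_hash = params_hash(params), params = params,
                 master_seed = master_seed, ablations = ablations),
            class = "experiment_run")
}

run_experiment10 <- function(params, n_trials_per_cell, master_seed,
                             ablations, criterion) {
  cells <- exp_cells(10)
  rows <- vector("list", nrow(cells) * n_trials_per_cell)
  idx <- 0L
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, , drop = FALSE]
    for (tr in seq_len(n_trials_per_cell)) {
      idx <- idx + 1L
      seed <- derive_seed(master_seed, (ci - 1L) * n_trials_per_cell + tr)
      st <- staircase_threshold(cell$gap_arcmin, cell$condition, params, seed,
                                criterion = criterion)
      rows[[idx]] <- cbind(
        data.frame(experiment_id = 10L, seed = seed,
                   threshold = st$threshold, ceiling = st$ceiling),
        cell, row.names = NULL)
    }
  }
  structure(list(results = do.call(rbind, rows), experiment_id = 10L,
                 params_hash = params_hash(params), params = params,
                 master_seed = master_seed, ablations = ablations),
            class = "experiment_run")
}

#' @export
print.experiment_run <- function(x, ...) {
  cat("<experiment_run> experiment", x$experiment_id,
      "|", nrow(x$results), "trials | params", x$params_hash,
      if (length(x$ablations)) paste("| ablations:", paste(x$ablations, collapse = ",")) else "",
      "\n")
  invisible(x)
}
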