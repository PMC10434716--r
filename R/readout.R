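#' Was a stimulus visible during a frame?
#'
#' Localized suprathreshold activation in the excitatory field indicates
#' detection. A frame counts as visible when `u` exceeds zero at some grid
#' point within half the input width of the stimulus center for at least the
#' criterion fraction of the frame's sampled instants (a sustained rather
#' than instantaneous rule, so transient noise spikes do not count as
#' percepts).
#'
#' @param record An `activation_record` containing the stored field time
#'   course (`record_stride > 0` in [simulate_frames()]).
#' @param frame_index Which protocol frame (1-based).
#' @param stimulus_center Center of the judged stimulus (field units).
#' @param criterion Minimum suprathreshold fraction of the frame (default
#'   0.25).
#' @return Logical.
#' @export
frame_visible <- function(record, frame_index, stimulus_center,
                          criterion = 0.25) {
  prot <- record$protocol
  inp <- prot$inputs[[frame_index]]
  if (is.null(inp) || nrow(inp) == 0)
    stop("invalid query: frame ", frame_index, " has no stimulus input",
         call. = FALSE)
  if (is.null(record$u_trace))
    stop("record has no stored field time course; rerun simulate_frames() with record_stride > 0",
         call. = FALSE)
  sel <- record$frame_index == frame_index
  if (!any(sel)) return(FALSE)
  p <- record$protocol$params_used
  hw <- attr(record, "judge_halfwidth")
  if (is.null(hw)) hw <- 2  # input_width / 2 at the default calibration
  g_pos <- record$grid_positions
  if (is.null(g_pos)) {
    n <- ncol(record$u_trace)
    g_pos <- (seq_len(n) - (n + 1) / 2)
  }
  cols <- which(abs(g_pos - stimulus_center) <= hw)
  u_win <- record$u_trace[sel, cols, drop = FALSE]
  frac <- mean(apply(u_win, 1, max) > 0)
  frac >= criterion
}

#' Score a simulated trial
#'
#' Applies the visibility readout to every judged stimulus frame of the
#' protocol (probe frames in the object-probe designs, object frames in the
#' relocation designs; blanks are excluded) and derives the initial
#' visibility, switch count, and first switch direction from the boolean
#' sequence. Pure function of the record.
#'
#' @param record An `activation_record` from [simulate_frames()].
#' @param protocol The protocol the record was produced from (defaults to the
#'   one stored in the record).
#' @param criterion Sustained-suprathreshold criterion fraction.
#' @return A `trial_result`: list with `initial_visible`, `per_frame_visible`,
#'   `n_switches`, `first_switch_direction` (`"vis_to_invis"`,
#'   `"invis_to_vis"`, or `"none"`), `any_switch`, and provenance fields.
#' @export
score_trial <- function(record, protocol = record$protocol, criterion = 0.25) {
  judged <- which(!is.na(protocol$frames$judge_center))
  if (length(judged) == 0)
    stop("protocol has no judged stimulus frames", call. = FALSE)
  vis <- record$frac_supra[judged] >= criterion
  switches <- which(diff(vis) != 0)
  first_dir <- if (length(switches) == 0) "none"
               else if (vis[switches[1]]) "vis_to_invis" else "invis_to_vis"
  structure(list(
    initial_visible = vis[1],
    per_frame_visible = vis,
    n_switches = length(switches),
    first_switch_direction = first_dir,
    any_switch = length(switches) > 0,
    experiment_id = protocol$experiment_id,
    condition = protocol$condition,
    end_contrast = protocol$end_contrast),
    class = "trial_result")
}

#' Distance-dependent visibility threshold by descending staircase
#'
#' Repeatedly presents the probe (with or without a flanking object) at fresh
#' random locations, lowering the probe contrast by one step after every
#' visible outcome; the threshold is the contrast at the first invisible
#' outcome.
#'
#' @param gap_arcmin Object-probe gap (arcmin).
#' @param condition `"baseline"`, `"object_low"`, or `"object_high"`.
#' @param params A `field_params` object.
#' @param seed Integer seed.
#' @param start_contrast Starting probe contrast.
#' @param step_down Contrast decrement per visible outcome.
#' @param criterion Visibility criterion fraction.
#' @param floor_contrast Smallest contrast probed before giving up.
#' @return A list with `threshold` (contrast at disappearance) and `ceiling`
#'   (TRUE when the probe was already invisible at `start_contrast`).
#' @export
staircase_threshold <- function(gap_arcmin, condition, params, seed,
                                start_contrast = 0.071, step_down = 0.004,
                                criterion = 0.25, floor_contrast = 0.0005) {
  stopifnot(step_down > 0)
  set.seed(seed)
  obj <- switch(condition, baseline = NA, object_low = 0.071,
                object_high = 0.24,
                stop("invalid input: unknown condition", call. = FALSE))
  contrast <- start_contrast
  first <- TRUE
  repeat {
    prot <- build_threshold_presentation(gap_arcmin, obj, contrast)
    rec <- simulate_frames(prot, params, seed = NULL, record_stride = 0)
    vis <- score_trial(rec, prot, criterion)$initial_visible
    if (!vis) {
      return(list(threshold = contrast, ceiling = first))
    }
    first <- FALSE
    if (contrast - step_down < floor_contrast)
      return(list(threshold = floor_contrast, ceiling = FALSE))
    contrast <- contrast - step_down
  }
}
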