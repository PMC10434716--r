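#' @title Contrast ladders and calibration
#' @description The experiments vary Michelson contrast along a fixed ladder;
#'   the model receives stimulus-initiated input amplitudes. The calibration
#'   maps contrast to amplitude by linear interpolation between the ladder
#'   anchors (0.008 -> 3.8, 0.073 -> 5.4) plus printed per-role overrides for
#'   the object/probe amplitudes quoted with the simulated experiments.
#' @name calibration
NULL

# contrast ladders used by the staircase experiments
LADDER_MAIN <- c(0.008, 0.017, 0.025, 0.033, 0.041, 0.049, 0.057, 0.065, 0.073)
LADDER_EXP9 <- c(0.008, 0.016, 0.025, 0.032, 0.040, 0.048, 0.056, 0.064, 0.071)
LADDER_EXP13 <- c(0.008, 0.016, 0.025, 0.032, 0.040, 0.048, 0.056, 0.064, 0.071)

#' Default contrast-to-amplitude calibration
#'
#' @return A `contrast_calibration`: list with interpolation `anchors` and a
#'   table of exact per-role `overrides`.
#' @export
default_calibration <- function() {
  structure(list(
    anchors = data.frame(contrast = c(0.008, 0.073), amplitude = c(3.8, 5.4)),
    overrides = data.frame(
      role = c("object_low", "object_high", "probe_exp2", "object_exp4"),
      contrast = c(0.071, 0.24, 0.008, 0.041),
      amplitude = c(5.0, 10.0, 4.5, 4.7),
      stringsAsFactors = FALSE)),
    class = "contrast_calibration")
}

#' Map Michelson contrast to stimulus-initiated input amplitude
#'
#' @param contrast Michelson contrast in `[0, 0.25]`.
#' @param cal A `contrast_calibration`.
#' @param role `"ladder"` for the generic linear map, or an override role
#'   (`"object_low"`, `"object_high"`, `"probe_exp2"`, `"object_exp4"`) whose
#'   printed amplitude takes precedence at its printed contrast.
#' @return Input amplitude (activation units).
#' @export
contrast_to_amplitude <- function(contrast, cal = default_calibration(),
                                  role = "ladder") {
  if (any(contrast < 0)) stop("invalid input: negative contrast", call. = FALSE)
  if (role != "ladder") {
    ov <- cal$overrides[cal$overrides$role == role, ]
    if (nrow(ov) == 1 && all(abs(contrast - ov$contrast) < 1e-12))
      return(rep(ov$amplitude, length(contrast)))
  }
  a <- cal$anchors
  slope <- diff(a$amplitude) / diff(a$contrast)
  a$amplitude[1] + (contrast - a$contrast[1]) * slope
}

#' Convert visual angle to field units
#'
#' Linear scale anchored by the printed center-to-center object-probe
#' distance: 6.6 arcmin corresponds to 8 field units.
#'
#' @param d Distance in arcmin (>= 0 not required; sign is preserved).
#' @return Distance in field units.
#' @export
arcmin_to_units <- function(d) d * 8 / 6.6

#' Sample one relocation displacement
#'
#' Stimulus locations are drawn uniformly and independently in
#' `[-window, +window]` arcmin in each of two dimensions. The displacement
#' between two consecutive draws is their 2-D Euclidean distance, mapped to
#' the 1-D field with a random sign.
#'
#' @param window_arcmin Half-width of the uniform location window (arcmin).
#' @return A single signed displacement in field units. Uses the current RNG
#'   state.
#' @export
sample_relocation <- function(window_arcmin) {
  if (window_arcmin == 0) return(0)
  p1 <- stats::runif(2, -window_arcmin, window_arcmin)
  p2 <- stats::runif(2, -window_arcmin, window_arcmin)
  d <- sqrt(sum((p2 - p1)^2))
  sign <- sample(c(-1, 1), 1)
  sign * arcmin_to_units(d)
}

# A sequence of n 1-D field positions emulating random 2-D relocations:
# consecutive 2-D draws in the +/- window, mapped to signed 1-D displacements
# of equal Euclidean magnitude, reflected at +/- bound field units.
relocation_centers <- function(n, window_arcmin, bound = 60) {
  if (n < 1) return(numeric(0))
  pos <- matrix(stats::runif(2 * n, -window_arcmin, window_arcmin), ncol = 2)
  x <- numeric(n)
  x[1] <- 0
  if (n > 1) {
    for (i in 2:n) {
      d <- sqrt(sum((pos[i, ] - pos[i - 1, ])^2))
      s <- sample(c(-1, 1), 1)
      xi <- x[i - 1] + s * arcmin_to_units(d)
      # reflect at the domain edges
      while (xi > bound || xi < -bound) {
        if (xi > bound) xi <- 2 * bound - xi
        if (xi < -bound) xi <- -2 * bound - xi
      }
      x[i] <- xi
    }
  }
  x
}

new_protocol <- function(frames, inputs, experiment_id, condition,
                         end_contrast = NA_real_, meta = list()) {
  stopifnot(nrow(frames) == length(inputs))
  structure(list(
    frames = frames,
    inputs_centers = lapply(inputs, function(d) as.numeric(d$center)),
    inputs_amps = lapply(inputs, function(d) as.numeric(d$amplitude)),
    inputs = inputs,
    experiment_id = experiment_id, condition = condition,
    end_contrast = end_contrast, meta = meta),
    class = "trial_protocol")
}

frame_row <- function(duration, label, judge_center = NA_real_) {
  data.frame(duration = duration, label = label, judge_center = judge_center,
             stringsAsFactors = FALSE)
}

no_input <- function() data.frame(center = numeric(0), amplitude = numeric(0))

#' Object/probe pair protocols (simultaneous, delayed, and displaced probes)
#'
#' Builds one trial of the three object-probe designs: simultaneous
#' presentation of object and probe 8 field units apart (experiment 1), a
#' probe at the object's former location after a variable blank interval
#' (experiment 2), and a probe displaced 8 units from the object's former
#' location after a fixed blank (experiment 3). The baseline condition
#' presents the probe only: the small position marker of the experiments is
#' not modeled as field input.
#'
#' @param experiment 1, 2, or 3.
#' @param condition `"object"` (for experiment 1: `"object_low"` or
#'   `"object_high"`) or `"baseline"`.
#' @param probe_contrast Probe Michelson contrast (ladder value; ignored in
#'   experiment 2, whose probe is fixed at contrast 0.008).
#' @param isi_ms Interstimulus interval for experiment 2 (107..800 ms);
#'   experiment 3 uses its fixed 612-ms blank.
#' @param cal Contrast calibration.
#' @return A `trial_protocol`. The judged stimulus is the probe.
#' @export
build_pair_trial <- function(experiment, condition, probe_contrast = 0.008,
                             isi_ms = 400, cal = default_calibration()) {
  if (experiment == 1) {
    if (!condition %in% c("object_low", "object_high", "baseline"))
      stop("invalid input: condition must be object_low, object_high or baseline",
           call. = FALSE)
    probe_amp <- contrast_to_amplitude(probe_contrast, cal)
    inputs <- if (condition == "baseline") {
      list(data.frame(center = 0, amplitude = probe_amp))
    } else {
      obj_amp <- if (condition == "object_low")
        contrast_to_amplitude(0.071, cal, "object_low")
      else contrast_to_amplitude(0.24, cal, "object_high")
      list(data.frame(center = c(-8, 0), amplitude = c(obj_amp, probe_amp)))
    }
    frames <- frame_row(360, "probe", judge_center = 0)
    return(new_protocol(frames, inputs, 1L, condition, probe_contrast))
  }
  if (!condition %in% c("object", "baseline"))
    stop("invalid input: condition must be object or baseline", call. = FALSE)
  if (experiment == 2) {
    if (!isi_ms %in% c(107, 200, 307, 400, 507, 600, 707, 800))
      stop("invalid input: isi_ms not in the experiment-2 set", call. = FALSE)
    obj_amp <- contrast_to_amplitude(0.071, cal, "object_low")
    probe_amp <- contrast_to_amplitude(0.008, cal, "probe_exp2")
    frames <- rbind(frame_row(360, if (condition == "object") "object" else "baseline"),
                    frame_row(isi_ms, "blank"),
                    frame_row(107, "probe", judge_center = 0))
    inputs <- list(
      if (condition == "object") data.frame(center = 0, amplitude = obj_amp) else no_input(),
      no_input(),
      data.frame(center = 0, amplitude = probe_amp))
    return(new_protocol(frames, inputs, 2L, condition, 0.008,
                        meta = list(isi_ms = isi_ms)))
  }
  if (experiment == 3) {
    obj_amp <- contrast_to_amplitude(0.071, cal, "object_low")
    probe_amp <- contrast_to_amplitude(probe_contrast, cal)
    frames <- rbind(frame_row(360, if (condition == "object") "object" else "baseline"),
                    frame_row(612, "blank"),
                    frame_row(106, "probe", judge_center = 8))
    inputs <- list(
      if (condition == "object") data.frame(center = 0, amplitude = obj_amp) else no_input(),
      no_input(),
      data.frame(center = 8, amplitude = probe_amp))
    return(new_protocol(frames, inputs, 3L, condition, probe_contrast))
  }
  stop("invalid input: experiment must be 1, 2, or 3", call. = FALSE)
}

#' Constant-contrast relocation protocol (stability design)
#'
#' A bistable object (input amplitude 4.7, the printed override for contrast
#' 0.041) presented for 614 ms and then relocated every 360 ms to a freshly
#' sampled random location, with 0-ms interframe intervals.
#'
#' @param n_presentations Number of presentations per trial (2..9).
#' @param window_arcmin Relocation window half-width (arcmin).
#' @param cal Contrast calibration.
#' @return A `trial_protocol`; every frame is judged (object frames).
#' @export
build_stability_trial <- function(n_presentations, window_arcmin = 12.8,
                                  cal = default_calibration()) {
  if (n_presentations < 2 || n_presentations > 9)
    stop("invalid input: n_presentations must be in 2..9", call. = FALSE)
  amp <- contrast_to_amplitude(0.041, cal, "object_exp4")
  centers <- relocation_centers(n_presentations, window_arcmin)
  frames <- do.call(rbind, lapply(seq_len(n_presentations), function(i)
    frame_row(if (i == 1) 614 else 360, "object", judge_center = centers[i])))
  inputs <- lapply(centers, function(ctr)
    data.frame(center = ctr, amplitude = amp))
  new_protocol(frames, inputs, 4L, "object", 0.041,
               meta = list(centers = centers))
}

#' Contrast ladder protocol (modified method of limits)
#'
#' Ascending trials start at the bottom of the contrast ladder, descending
#' trials at the top; contrast moves one ladder step per presentation, each
#' presentation at a freshly sampled random location, ending at
#' `end_contrast`. Variants: repeat the first contrast (`start_reps`, the
#' adaptation design), repeat the final contrast (`end_reps`, the
#' noise-switching design), insert blank frames between presentations
#' (`blank_ms`), or use brief frames with a doubled relocation window
#' (`frame_ms = 116`).
#'
#' @param direction `"ascending"` or `"descending"`.
#' @param end_contrast End-of-trial contrast (must lie on the ladder).
#' @param start_reps,end_reps Number of presentations of the first/last
#'   contrast (1 or 4).
#' @param blank_ms Blank interval inserted between presentations (0 or 614).
#' @param frame_ms Relocation frame duration (360, or 116 for the brief-frame
#'   design, which also doubles the relocation window and uses its own
#'   contrast set).
#' @param window_arcmin Relocation window half-width.
#' @param ladder Contrast ladder to walk.
#' @param cal Contrast calibration.
#' @return A `trial_protocol`; object frames are judged, blanks are not.
#' @export
build_ladder_trial <- function(direction = c("ascending", "descending"),
                               end_contrast,
                               start_reps = 1, end_reps = 1,
                               blank_ms = 0, frame_ms = 360,
                               window_arcmin = if (frame_ms == 116) 25.6 else 12.8,
                               ladder = if (frame_ms == 116) LADDER_EXP9 else LADDER_MAIN,
                               cal = default_calibration()) {
  direction <- match.arg(direction)
  i_end <- which(abs(ladder - end_contrast) < 1e-12)
  if (length(i_end) != 1)
    stop("invalid input: end_contrast is not on the contrast ladder", call. = FALSE)
  contrasts <- if (direction == "ascending") ladder[1:i_end]
               else rev(ladder)[1:(length(ladder) - i_end + 1)]
  if (length(contrasts) < 2)
    stop("invalid input: ladder trial needs at least one contrast step", call. = FALSE)
  if (start_reps > 1)
    contrasts <- c(rep(contrasts[1], start_reps - 1), contrasts)
  if (end_reps > 1)
    contrasts <- c(contrasts, rep(contrasts[length(contrasts)], end_reps - 1))
  n <- length(contrasts)
  centers <- relocation_centers(n, window_arcmin)
  amps <- contrast_to_amplitude(contrasts, cal)

  frames <- list(); inputs <- list()
  for (i in seq_len(n)) {
    dur <- if (frame_ms == 116) 116 else if (i == 1) 614 else 360
    frames[[length(frames) + 1]] <- frame_row(dur, "object", judge_center = centers[i])
    inputs[[length(inputs) + 1]] <- data.frame(center = centers[i], amplitude = amps[i])
    if (blank_ms > 0 && i < n) {
      frames[[length(frames) + 1]] <- frame_row(blank_ms, "blank")
      inputs[[length(inputs) + 1]] <- no_input()
    }
  }
  exp_id <- if (frame_ms == 116) 9L else if (blank_ms > 0) 8L
            else if (start_reps > 1 || end_reps > 1) NA_integer_ else 5L
  new_protocol(do.call(rbind, frames), inputs, exp_id, direction, end_contrast,
               meta = list(contrasts = contrasts, centers = centers,
                           start_reps = start_reps, end_reps = end_reps,
                           blank_ms = blank_ms, frame_ms = frame_ms))
}

#' Single presentation for the distance-threshold staircase
#'
#' One 360-ms frame with an optional object and a probe separated by the gap
#' plus one line width (3.3 arcmin) center-to-center.
#'
#' @param gap_arcmin Spatial gap between object and probe (arcmin, >= 0).
#' @param object_contrast 0.24, 0.071, or `NA` for the probe-only baseline.
#' @param probe_contrast Probe Michelson contrast.
#' @param cal Contrast calibration.
#' @return A `trial_protocol`; the probe is judged.
#' @export
build_threshold_presentation <- function(gap_arcmin, object_contrast = NA,
                                         probe_contrast = 0.041,
                                         cal = default_calibration()) {
  if (gap_arcmin < 0) stop("invalid input: gap must be >= 0", call. = FALSE)
  sep <- arcmin_to_units(gap_arcmin + 3.3)
  probe_amp <- contrast_to_amplitude(probe_contrast, cal)
  if (is.na(object_contrast)) {
    inputs <- list(data.frame(center = 0, amplitude = probe_amp))
    cond <- "baseline"
  } else {
    role <- if (abs(object_contrast - 0.24) < 1e-12) "object_high" else "object_low"
    obj_amp <- contrast_to_amplitude(object_contrast, cal, role)
    inputs <- list(data.frame(center = c(-sep, 0), amplitude = c(obj_amp, probe_amp)))
    cond <- role
  }
  new_protocol(frame_row(360, "probe", judge_center = 0), inputs, 10L, cond,
               probe_contrast, meta = list(gap_arcmin = gap_arcmin))
}
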