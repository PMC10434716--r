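#' Advance the field state by one integration step
#'
#' Single explicit Euler-Maruyama update of the coupled excitatory/inhibitory
#' fields, memory trace, adaptation, and the slow Ornstein-Uhlenbeck
#' resting-level offset. This is the reference (pure R) form of the update;
#' [simulate_frames()] runs the identical scheme in compiled code. Noise draws
#' come from the R RNG, so the caller controls reproducibility via
#' `set.seed()`.
#'
#' @param state A field state as returned by [resting_state()] or a previous
#'   call: list with `u`, `v`, `m`, `a` (vectors over the grid), `n` (scalar
#'   slow offset), `t` (ms).
#' @param raw_input Stimulus input field (same length as the grid).
#' @param params A `field_params` object.
#' @return The updated state.
#' @export
step <- function(state, raw_input, params) {
  p <- params
  g <- field_grid(p)
  n <- g$n_points
  stopifnot(length(raw_input) == n, length(state$u) == n)
  dt <- p$dt
  fu <- sigmoid(state$u, p$beta)
  fv <- sigmoid(state$v, p$beta)
  exc <- conv_open(fu, gaussian_kernel(p$w_uu_amp, p$w_uu_width, g), g$spacing)
  inh <- conv_open(fv, gaussian_kernel(p$w_uv_amp, p$w_uv_width, g), g$spacing)
  drv <- conv_open(fu, gaussian_kernel(p$w_vu_amp, p$w_vu_width, g), g$spacing)
  ms <- if (max(state$m) > 1e-12)
    conv_open(state$m, gaussian_kernel(1, p$trace_spread, g), g$spacing) else numeric(n)
  ms <- pmin(ms, p$trace_sat)
  as <- if (max(state$a) > 1e-12)
    conv_open(state$a, gaussian_kernel(1, p$adapt_spread, g), g$spacing) else numeric(n)

  s_eff <- if (any(raw_input != 0)) effective_input(raw_input, as, p$adapt_gain)
           else numeric(n)
  supra <- state$u > 0

  du <- (-state$u + p$h_u + state$n + p$trace_gain * ms + s_eff + exc - inh) / p$tau_u
  u_new <- state$u + dt * du
  if (p$noise_fast_amp > 0)
    u_new <- u_new + p$noise_fast_amp * sqrt(dt) * stats::rnorm(n)
  v_new <- state$v + dt * (-state$v + p$h_v + drv) / p$tau_v
  m_new <- ifelse(supra,
                  state$m + dt * (fu - state$m) / p$trace_build_tau,
                  state$m + dt * (0 - state$m) / p$trace_decay_tau)
  m_new <- pmax(0, m_new)
  a_new <- ifelse(supra,
                  state$a + dt * (1 - state$a) / p$adapt_tau,
                  state$a + dt * (0 - state$a) / p$adapt_decay_tau)
  a_new <- pmin(1, pmax(0, a_new))
  n_new <- state$n * (1 - dt / p$noise_slow_tau)
  if (p$noise_slow_amp > 0)
    n_new <- n_new + p$noise_slow_amp * sqrt(2 * dt / p$noise_slow_tau) * stats::rnorm(1)

  bad <- c(u = any(!is.finite(u_new)), v = any(!is.finite(v_new)),
           m = any(!is.finite(m_new)), a = any(!is.finite(a_new)))
  if (any(bad))
    stop("integration diverged: non-finite value in field '",
         names(bad)[bad][1], "'", call. = FALSE)
  list(u = u_new, v = v_new, m = m_new, a = a_new, n = n_new, t = state$t + dt)
}

# Zero-padded (open boundary) discrete convolution with a kernel list.
conv_open <- function(x, kernel, spacing) {
  n <- length(x)
  half <- (length(kernel$weights) - 1L) / 2L
  full <- stats::convolve(c(numeric(half), x, numeric(half)),
                          rev(kernel$weights), type = "open")
  full[(2 * half + 1):(2 * half + n)] * spacing
}

#' Resting field state
#'
#' @param params A `field_params` object.
#' @param n_offset Initial slow resting-level offset (default: drawn from its
#'   stationary distribution using the current RNG state).
#' @return A state list suitable for [step()].
#' @export
resting_state <- function(params, n_offset = NULL) {
  n <- params$n_points
  if (is.null(n_offset))
    n_offset <- stats::rnorm(1, 0, params$noise_slow_amp)
  list(u = rep(params$h_u + n_offset, n), v = rep(params$h_v, n),
       m = numeric(n), a = numeric(n), n = n_offset, t = 0)
}

#' Build the stimulus input field for a set of localized inputs
#'
#' Each input is a Gaussian bump with peak amplitude `amplitude` and SD
#' `input_width / 2` centred at `center`.
#'
#' @param centers,amplitudes Vectors of input centers (field units) and peak
#'   amplitudes.
#' @param params A `field_params` object.
#' @return A numeric vector over the grid.
#' @export
input_field <- function(centers, amplitudes, params) {
  g <- field_grid(params)
  sd <- params$input_width / 2
  out <- numeric(g$n_points)
  for (k in seq_along(centers))
    out <- out + amplitudes[k] * exp(-0.5 * (g$positions - centers[k])^2 / sd^2)
  out
}

#' Simulate a trial protocol
#'
#' Integrates the field through the ordered stimulus frames of a protocol.
#' The state carries over across frames (no reset at frame boundaries); the
#' initial state is the resting state with the slow noise offset drawn from
#' its stationary distribution. Fully deterministic given `(protocol, params,
#' seed)`.
#'
#' @param protocol A `trial_protocol` (see [build_stability_trial()] and
#'   friends).
#' @param params A `field_params` object.
#' @param seed Integer seed (`NULL` = use current RNG state).
#' @param record_stride Sampling stride of the activation record in ms; 0
#'   disables storage of the field time course (per-frame suprathreshold
#'   occupancy is still computed at full step resolution).
#' @return An `activation_record`: list with `times`, `frame_index`, `u_trace`
#'   (samples x grid matrix, if recorded), per-frame `frac_supra` (fraction of
#'   integration steps with suprathreshold activation inside the judged
#'   window), and the final state.
#' @export
simulate_frames <- function(protocol, params, seed = NULL, record_stride = 2) {
  stopifnot(inherits(protocol, "trial_protocol"))
  if (!is.null(seed)) set.seed(seed)
  n0 <- stats::rnorm(1, 0, params$noise_slow_amp)
  fr <- protocol$frames
  if (nrow(fr) == 0) {
    st <- resting_state(params, n0)
    return(structure(list(times = 0, frame_index = 0L,
                          u_trace = matrix(st$u, nrow = 1),
                          frac_supra = numeric(0), final_state = st,
                          grid_positions = field_grid(params)$positions,
                          protocol = protocol, params_hash = params_hash(params)),
                     class = "activation_record",
                     judge_halfwidth = params$input_width / 2))
  }
  if (any(fr$duration <= 0)) stop("protocol frames must have positive durations")
  res <- nf_run(fr$duration, protocol$inputs_centers, protocol$inputs_amps,
                unclass(params), n0, fr$judge_center,
                params$input_width / 2, record_stride,
                numeric(0), numeric(0), numeric(0), numeric(0))
  structure(list(
    times = if (record_stride > 0) res$times else NULL,
    frame_index = if (record_stride > 0) res$frame_index else NULL,
    u_trace = if (record_stride > 0) res$u_trace else NULL,
    frac_supra = as.numeric(res$frac_supra),
    final_state = list(u = res$u, v = res$v, m = res$m, a = res$a,
                       n = res$n_offset, t = res$t),
    grid_positions = field_grid(params)$positions,
    protocol = protocol, params_hash = params_hash(params)),
    class = "activation_record",
    judge_halfwidth = params$input_width / 2)
}

#' Stationary states of the deterministic field at a given input level
#'
#' With noise amplitudes forced to zero and trace/adaptation frozen at zero,
#' relaxes the two-layer dynamics from (i) the resting state and (ii) a
#' pre-formed suprathreshold peak, and classifies each attractor as
#' subthreshold or suprathreshold by its peak excitatory activation relative
#' to the zero threshold.
#'
#' @param input_amp Peak stimulus input amplitude (single bump at the field
#'   center).
#' @param params A `field_params` object.
#' @param tol Convergence tolerance on the per-step state change.
#' @param max_steps Step budget per relaxation.
#' @return A list of 1 or 2 distinct stationary states, each a list with
#'   `peak_u`, `class` (`"subthreshold"` / `"suprathreshold"`), and the full
#'   `u`, `v` fields.
#' @export
find_stationary_states <- function(input_amp, params, tol = 1e-8,
                                   max_steps = 60000L) {
  g <- field_grid(params)
  centers <- if (input_amp > 0) 0 else numeric(0)
  amps <- if (input_amp > 0) input_amp else numeric(0)
  lo <- nf_relax(centers, amps, unclass(params), numeric(0), numeric(0),
                 tol, max_steps)
  bump <- params$h_u + (abs(params$h_u) + input_amp + 5) *
    exp(-0.5 * g$positions^2 / params$input_width^2)
  hi <- nf_relax(centers, amps, unclass(params), bump, numeric(0),
                 tol, max_steps)
  if (!lo$converged || !hi$converged)
    stop("no convergence of stationary-state relaxation within the step budget",
         call. = FALSE)
  mk <- function(r) list(peak_u = max(r$u),
                         class = if (max(r$u) > 0) "suprathreshold" else "subthreshold",
                         u = r$u, v = r$v)
  s1 <- mk(lo); s2 <- mk(hi)
  if (abs(s1$peak_u - s2$peak_u) < 1e-3) list(s1) else list(s1, s2)
}

#' Scan input amplitude for the bistable regime
#'
#' Runs [find_stationary_states()] over a ladder of input amplitudes and
#' reports, for each, whether the deterministic field is monostable
#' subthreshold, bistable, or monostable suprathreshold, together with the
#' two regime boundaries: the detection instability (lowest amplitude at
#' which the subthreshold state is lost) and the reverse detection
#' instability (lowest amplitude at which a pre-formed peak survives).
#'
#' @param amps Vector of input amplitudes to scan (increasing).
#' @param params A `field_params` object.
#' @return A list with `scan` (data.frame: amp, regime, peak_lo, peak_hi),
#'   `detection_amp`, and `reverse_amp` (NA when outside the scanned range).
#' @export
scan_bistability <- function(amps, params) {
  amps <- sort(amps)
  rows <- lapply(amps, function(a) {
    st <- find_stationary_states(a, params)
    peaks <- vapply(st, `[[`, 0, "peak_u")
    cls <- vapply(st, `[[`, "", "class")
    regime <- if (length(st) == 2) "bistable"
              else if (cls[1] == "suprathreshold") "monostable_supra"
              else "monostable_sub"
    data.frame(amp = a, regime = regime,
               peak_lo = min(peaks), peak_hi = max(peaks))
  })
  scan <- do.call(rbind, rows)
  det <- scan$amp[scan$regime == "monostable_supra"]
  rev_ <- scan$amp[scan$regime %in% c("bistable", "monostable_supra")]
  list(scan = scan,
       detection_amp = if (length(det)) min(det) else NA_real_,
       reverse_amp = if (length(rev_)) min(rev_) else NA_real_)
}
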