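#' Model parameters for the visibility field
#'
#' Constructs the full parameter set of the stochastic two-layer neural field
#' with memory trace, input adaptation, and slow resting-level noise. A single
#' parameter set is shared across all simulated experiments; the shipped
#' defaults (see [default_params()]) were calibrated once against the
#' bistable-band, initial-detection, and switching-rate benchmarks and are
#' frozen in `inst/extdata/default_params.yaml`.
#'
#' Activation is expressed relative to the visibility threshold at zero, so
#' both resting levels `h_u` and `h_v` are negative. Spatial quantities are in
#' field units (1 field unit ~ 0.825 arcmin, see [arcmin_to_units()]); time is
#' in milliseconds.
#'
#' @param tau_u,tau_v Time constants (ms) of the excitatory and inhibitory
#'   fields.
#' @param h_u,h_v Resting levels (negative) of the two fields.
#' @param beta Steepness of the sigmoidal rate function (1/activation unit).
#' @param w_uu_amp,w_uu_width Amplitude and width (field units) of the
#'   excitatory self-coupling kernel.
#' @param w_uv_amp,w_uv_width Inhibitory-to-excitatory coupling kernel.
#' @param w_vu_amp,w_vu_width Excitatory-to-inhibitory coupling kernel.
#' @param trace_build_tau,trace_decay_tau Build/decay time constants (ms) of
#'   the memory trace.
#' @param trace_gain Resting-level boost per unit (spatially smoothed) trace.
#' @param trace_sat Saturation level of the smoothed trace: the boost is
#'   `trace_gain * min(smoothed trace, trace_sat)`, so preactivation from an
#'   accumulating stimulus history levels off.
#' @param trace_spread Spatial spread (field units) of the trace's
#'   resting-level boost; the trace itself builds only where activation is
#'   above threshold, but its preactivation reaches surrounding locations.
#' @param adapt_tau Build time constant (ms) of adaptation (toward 1 where
#'   activation is above threshold).
#' @param adapt_decay_tau Decay time constant (ms) of adaptation elsewhere.
#' @param adapt_gain Input-weakening strength: effective input is
#'   `raw * (1 - adapt_gain * a)` (clipped at 0), with `a` spatially smoothed
#'   by `adapt_spread`.
#' @param adapt_spread Spatial spread (field units) of adaptation's effect.
#' @param noise_slow_tau Time constant (ms) of the slow Ornstein-Uhlenbeck
#'   resting-level offset.
#' @param noise_slow_amp Stationary SD of the slow offset (activation units).
#' @param noise_fast_amp Per-point fast white-noise magnitude.
#' @param input_width Full spatial width (field units) of a line-segment
#'   input; the input profile is Gaussian with SD `input_width / 2`.
#' @param dt Integration step (ms), explicit Euler-Maruyama.
#' @param n_points,spacing Spatial grid: number of samples and field units per
#'   sample.
#'
#' @return An object of class `field_params` (a validated named list).
#' @seealso [default_params()], [ablate()], [params_hash()]
#' @export
field_params <- function(tau_u = 20, tau_v = 10,
                         h_u = -5.02, h_v = -1.6,
                         beta = 6,
                         w_uu_amp = 6.5, w_uu_width = 6,
                         w_uv_amp = 12, w_uv_width = 12,
                         w_vu_amp = 6, w_vu_width = 10,
                         trace_build_tau = 400, trace_decay_tau = 30000,
                         trace_gain = 14, trace_spread = 25, trace_sat = 0.06,
                         adapt_tau = 1500, adapt_decay_tau = 10000,
                         adapt_gain = 2.6, adapt_spread = 20,
                         noise_slow_tau = 20000, noise_slow_amp = 0.4,
                         noise_fast_amp = 0.05,
                         input_width = 6, dt = 1,
                         n_points = 201, spacing = 1) {
  p <- list(tau_u = tau_u, tau_v = tau_v, h_u = h_u, h_v = h_v, beta = beta,
            w_uu_amp = w_uu_amp, w_uu_width = w_uu_width,
            w_uv_amp = w_uv_amp, w_uv_width = w_uv_width,
            w_vu_amp = w_vu_amp, w_vu_width = w_vu_width,
            trace_build_tau = trace_build_tau, trace_decay_tau = trace_decay_tau,
            trace_gain = trace_gain, trace_spread = trace_spread,
            trace_sat = trace_sat,
            adapt_tau = adapt_tau, adapt_decay_tau = adapt_decay_tau,
            adapt_gain = adapt_gain, adapt_spread = adapt_spread,
            noise_slow_tau = noise_slow_tau, noise_slow_amp = noise_slow_amp,
            noise_fast_amp = noise_fast_amp,
            input_width = input_width, dt = dt,
            n_points = as.integer(n_points), spacing = spacing)
  validate_field_params(p)
  structure(p, class = "field_params")
}

validate_field_params <- function(p) {
  taus <- c("tau_u", "tau_v", "trace_build_tau", "trace_decay_tau",
            "adapt_tau", "adapt_decay_tau", "noise_slow_tau")
  for (nm in taus)
    if (!is.numeric(p[[nm]]) || p[[nm]] <= 0)
      stop("invalid parameter: '", nm, "' must be a positive time constant", call. = FALSE)
  if (p$dt <= 0 || p$dt > min(p$tau_u, p$tau_v) / 5)
    stop("invalid parameter: dt must satisfy 0 < dt <= min(tau_u, tau_v)/5", call. = FALSE)
  for (nm in c("w_uu_width", "w_uv_width", "w_vu_width", "trace_spread",
               "adapt_spread", "input_width"))
    if (p[[nm]] <= 0)
      stop("invalid parameter: '", nm, "' must be a positive width", call. = FALSE)
  if (p$h_u >= 0 || p$h_v >= 0)
    stop("invalid parameter: resting levels h_u and h_v must be below the zero threshold",
         call. = FALSE)
  if (p$trace_sat <= 0)
    stop("invalid parameter: trace_sat must be > 0", call. = FALSE)
  if (p$noise_slow_amp < 0 || p$noise_fast_amp < 0)
    stop("invalid parameter: noise amplitudes must be >= 0", call. = FALSE)
  if (p$beta <= 0) stop("invalid parameter: beta must be > 0", call. = FALSE)
  if (p$spacing <= 0) stop("invalid parameter: spacing must be > 0", call. = FALSE)
  widest <- max(p$w_uu_width, p$w_uv_width, p$w_vu_width)
  if (p$n_points < 3 * widest / p$spacing)
    stop("invalid parameter: n_points must span at least 3x the widest kernel",
         call. = FALSE)
  invisible(p)
}

#' The calibrated default parameter set
#'
#' Reads the frozen default configuration shipped with the package. This is
#' the single parameter set used for all ten experiment simulations.
#'
#' @return A `field_params` object.
#' @export
default_params <- function() {
  path <- system.file("extdata", "default_params.yaml", package = "visfield")
  load_config(path)
}

#' Remove a model component
#'
#' Returns the parameter set with one mechanism switched off, leaving
#' everything else untouched. Used for the ablation analyses (e.g., showing
#' that start-of-trial repetition effects require adaptation while
#' end-of-trial invisible-to-visible switches survive without it).
#'
#' @param params A `field_params` object.
#' @param component One of `"no_adaptation"`, `"no_trace"`, `"no_noise"`,
#'   `"no_self_excitation"`.
#' @return A modified `field_params` object. Idempotent.
#' @export
ablate <- function(params, component) {
  component <- match.arg(component,
                         c("no_adaptation", "no_trace", "no_noise", "no_self_excitation"))
  p <- unclass(params)
  switch(component,
         no_adaptation = { p$adapt_gain <- 0 },
         no_trace = { p$trace_gain <- 0 },
         no_noise = { p$noise_slow_amp <- 0; p$noise_fast_amp <- 0 },
         no_self_excitation = { p$w_uu_amp <- 0 })
  validate_field_params(p)
  structure(p, class = "field_params")
}

#' Hash of a canonical parameter serialization
#'
#' Identifies a parameter set across runs; identical across all experiments of
#' a release under the single-parameter-set contract.
#'
#' @param params A `field_params` object.
#' @return A character scalar.
#' @export
params_hash <- function(params) {
  p <- unclass(params)
  p <- p[order(names(p))]
  txt <- paste(names(p), vapply(p, function(x) format(x, digits = 17), ""),
               sep = "=", collapse = ";")
  # polynomial rolling hash mod 2^31-1; stable across platforms
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' @export
print.field_params <- function(x, ...) {
  cat("<field_params> hash", params_hash(x), "\n")
  utils::str(unclass(x), give.attr = FALSE)
  invisible(x)
}

#' Spatial grid of the field
#'
#' @param params A `field_params` object.
#' @return A list with `n_points`, `spacing`, `extent`, and the vector of
#'   `positions` (field units, centred on zero, strictly increasing).
#' @export
field_grid <- function(params) {
  n <- params$n_points
  sp <- params$spacing
  pos <- (seq_len(n) - (n + 1) / 2) * sp
  list(n_points = n, spacing = sp, extent = (n - 1) * sp, positions = pos)
}

#' Sigmoidal rate function
#'
#' Maps activation to a firing-rate fraction in (0, 1), with value 0.5 at the
#' visibility threshold (activation zero).
#'
#' @param activation Numeric vector of activation values.
#' @param beta Steepness (> 0).
#' @return Values in (0, 1), strictly increasing in `activation`.
#' @export
sigmoid <- function(activation, beta) {
  stopifnot(beta > 0)
  1 / (1 + exp(-beta * activation))
}

#' Interaction kernel over grid offsets
#'
#' Truncated Gaussian coupling kernel, symmetric about zero offset and
#' integral-normalized so that `sum(kernel) * spacing == amp` regardless of
#' the discretization.
#'
#' @param amp Kernel amplitude (total coupling).
#' @param width Gaussian width (field units, > 0).
#' @param grid A grid as returned by [field_grid()] (only `spacing` is used).
#' @return A named list with `offsets` and `weights`.
#' @export
gaussian_kernel <- function(amp, width, grid) {
  if (width <= 0) stop("invalid parameter: kernel width must be > 0", call. = FALSE)
  sp <- grid$spacing
  half <- max(1L, as.integer(ceiling(3 * width / sp)))
  offs <- (-half:half) * sp
  w <- exp(-0.5 * offs^2 / width^2)
  w <- w * amp / (sum(w) * sp)
  list(offsets = offs, weights = w)
}

#' Adaptation-weakened stimulus input
#'
#' @param raw_input Input amplitude field.
#' @param a Adaptation field (same length), values in `[0, 1]`.
#' @param adapt_gain Input-weakening strength.
#' @return `raw_input * (1 - adapt_gain * a)`, clipped below at zero.
#' @export
effective_input <- function(raw_input, a, adapt_gain) {
  stopifnot(length(raw_input) == length(a))
  pmax(0, raw_input * (1 - adapt_gain * a))
}
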