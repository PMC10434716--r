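# Shared fixtures: the calibrated default set plus cheap deterministic variants.
test_params <- function(...) {
  p <- default_params()
  over <- list(...)
  if (length(over)) {
    q <- unclass(p)
    q[names(over)] <- over
    p <- do.call(field_params, q)
  }
  p
}

# deterministic: both noise sources off
det_params <- function(...) test_params(noise_slow_amp = 0, noise_fast_amp = 0, ...)

# one-frame protocol with a single centred input, judged at the centre
single_frame_protocol <- function(amp, duration = 614, center = 0) {
  visfield:::new_protocol(
    visfield:::frame_row(duration, "object", judge_center = center),
    list(data.frame(center = center, amplitude = amp)),
    4L, "object", NA_real_)
}
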