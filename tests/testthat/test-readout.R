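test_that("score_trial enumerates switches and directions correctly", {
  prot <- visfield:::new_protocol(
    do.call(rbind, lapply(1:4, function(i)
      visfield:::frame_row(100, "object", judge_center = 0))),
    rep(list(data.frame(center = 0, amplitude = 4.7)), 4),
    4L, "object", 0.041)
  fake <- function(fracs) {
    structure(list(frac_supra = fracs, protocol = prot),
              class = "activation_record")
  }
  r <- score_trial(fake(c(1, 1, 0, 0)), prot)
  expect_true(r$initial_visible)
  expect_equal(r$n_switches, 1)
  expect_equal(r$first_switch_direction, "vis_to_invis")
  expect_true(r$any_switch)

  r2 <- score_trial(fake(c(0, 1, 0, 0)), prot)
  expect_false(r2$initial_visible)
  expect_equal(r2$n_switches, 2)
  expect_equal(r2$first_switch_direction, "invis_to_vis")

  r3 <- score_trial(fake(c(1, 1, 1, 1)), prot)
  expect_false(r3$any_switch)
  expect_equal(r3$first_switch_direction, "none")
  # any_switch iff the judged sequence is non-constant
  expect_equal(r3$any_switch, length(unique(r3$per_frame_visible)) > 1)
})

test_that("frame_visible applies the sustained window criterion to the record", {
  p <- det_params()
  # clamped at rest: never visible
  sub <- single_frame_protocol(3.0, duration = 200)
  rec <- simulate_frames(sub, p, seed = 1, record_stride = 2)
  expect_false(frame_visible(rec, 1, 0))
  # sustained peak: visible, and matches the step-resolution readout
  supra <- single_frame_protocol(5.3, duration = 400)
  rec2 <- simulate_frames(supra, p, seed = 1, record_stride = 1)
  expect_true(frame_visible(rec2, 1, 0))
  expect_equal(frame_visible(rec2, 1, 0), rec2$frac_supra[1] >= 0.25)
  # querying a frame without stimulus input errors
  blank <- visfield:::new_protocol(
    rbind(visfield:::frame_row(100, "object", judge_center = 0),
          visfield:::frame_row(100, "blank")),
    list(data.frame(center = 0, amplitude = 5), visfield:::no_input()),
    1L, "object", NA_real_)
  rec3 <- simulate_frames(blank, p, seed = 1, record_stride = 2)
  expect_error(frame_visible(rec3, 2, 0), "no stimulus")
})

test_that("with noise ablated, single-frame visibility is monotone in amplitude", {
  p <- det_params()
  amps <- seq(3.8, 5.4, by = 0.2)
  vis <- vapply(amps, function(a) {
    rec <- simulate_frames(single_frame_protocol(a, duration = 360), p,
                           seed = 1, record_stride = 0)
    rec$frac_supra[1] >= 0.25
  }, logical(1))
  expect_true(all(diff(as.integer(vis)) >= 0))
})

test_that("staircase returns a ceiling flag when the probe starts invisible", {
  # without self-excitation no probe contrast on the ladder is detectable
  p <- ablate(det_params(), "no_self_excitation")
  st <- staircase_threshold(3.3, "baseline", p, seed = 1,
                            start_contrast = 0.041)
  expect_true(st$ceiling)
  expect_equal(st$threshold, 0.041)
})
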