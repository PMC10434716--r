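test_that("contrast calibration reproduces printed anchors and the linear ladder", {
  expect_equal(contrast_to_amplitude(0.008), 3.8)
  expect_equal(contrast_to_amplitude(0.073), 5.4)
  expect_equal(contrast_to_amplitude(0.0405), 4.6)   # ladder midpoint
  # printed overrides take precedence over the linear map
  expect_equal(contrast_to_amplitude(0.071, role = "object_low"), 5.0)
  expect_equal(contrast_to_amplitude(0.24, role = "object_high"), 10.0)
  expect_equal(contrast_to_amplitude(0.008, role = "probe_exp2"), 4.5)
  expect_equal(contrast_to_amplitude(0.041, role = "object_exp4"), 4.7)
  # monotone non-decreasing over the ladder
  amps <- contrast_to_amplitude(visfield:::LADDER_MAIN)
  expect_true(all(diff(amps) > 0))
  expect_error(contrast_to_amplitude(-0.01), "negative")
})

test_that("arcmin conversion uses the 6.6 arcmin = 8 units anchor", {
  expect_equal(arcmin_to_units(6.6), 8)
  expect_equal(arcmin_to_units(0), 0)
  expect_equal(arcmin_to_units(14.3), 14.3 * 8 / 6.6, tolerance = 1e-12)
  expect_equal(arcmin_to_units(14.3), 17.33, tolerance = 1e-3)
})

test_that("relocation distances match the uniform-square closed form and scale with the window", {
  # closed form for the mean distance between two independent uniform points
  # in a square of side L: L * (2 + sqrt(2) + 5 * asinh(1)) / 15
  cmean <- function(L) L * (2 + sqrt(2) + 5 * asinh(1)) / 15
  set.seed(42)
  d1 <- abs(replicate(20000, sample_relocation(12.8))) * 6.6 / 8  # back to arcmin
  expect_equal(mean(d1), cmean(25.6), tolerance = 0.02)
  set.seed(42)
  d2 <- abs(replicate(20000, sample_relocation(25.6))) * 6.6 / 8
  expect_equal(mean(d2) / mean(d1), 2, tolerance = 0.02)
  expect_equal(sample_relocation(0), 0)
  # signs are symmetric
  set.seed(1)
  s <- sign(replicate(4000, sample_relocation(12.8)))
  expect_lt(abs(mean(s)), 0.05)
})

test_that("pair-trial protocols follow the printed frame schedules", {
  t1 <- build_pair_trial(1, "baseline", probe_contrast = 0.008)
  expect_equal(nrow(t1$frames), 1)
  expect_equal(t1$frames$duration, 360)
  expect_equal(t1$inputs[[1]]$amplitude, 3.8)

  t1o <- build_pair_trial(1, "object_high", probe_contrast = 0.041)
  expect_equal(sort(t1o$inputs[[1]]$center), c(-8, 0))
  expect_equal(max(t1o$inputs[[1]]$amplitude), 10.0)

  t2 <- build_pair_trial(2, "object", isi_ms = 800)
  expect_equal(t2$frames$duration, c(360, 800, 107))
  expect_equal(t2$inputs[[1]]$amplitude, 5.0)
  expect_equal(t2$inputs[[3]]$amplitude, 4.5)
  expect_equal(nrow(t2$inputs[[2]]), 0)

  t3 <- build_pair_trial(3, "object", probe_contrast = 0.025)
  expect_equal(t3$frames$duration, c(360, 612, 106))
  expect_equal(t3$inputs[[3]]$center - t3$inputs[[1]]$center, 8)

  expect_error(build_pair_trial(1, "nonsense"), "invalid")
  expect_error(build_pair_trial(2, "object", isi_ms = 123), "invalid")
})

test_that("stability protocol has the printed durations and constant amplitude", {
  set.seed(5)
  t2 <- build_stability_trial(2)
  expect_equal(t2$frames$duration, c(614, 360))
  t9 <- build_stability_trial(9)
  expect_equal(sum(t9$frames$duration), 614 + 8 * 360)
  expect_true(all(vapply(t9$inputs, function(d) d$amplitude, 0) == 4.7))
  # relocations are fresh draws
  expect_gt(length(unique(vapply(t9$inputs, function(d) d$center, 0))), 1)
  expect_error(build_stability_trial(1), "invalid")
  expect_error(build_stability_trial(10), "invalid")
})

test_that("ladder protocols walk the printed contrast sequences", {
  set.seed(6)
  d17 <- build_ladder_trial("descending", 0.017)
  expect_equal(d17$meta$contrasts,
               c(0.073, 0.065, 0.057, 0.049, 0.041, 0.033, 0.025, 0.017))
  expect_equal(d17$frames$duration, c(614, rep(360, 7)))
  a25 <- build_ladder_trial("ascending", 0.025)
  expect_equal(a25$meta$contrasts, c(0.008, 0.017, 0.025))
  # palindromic: full descending reversed equals full ascending
  df <- build_ladder_trial("descending", 0.008)
  af <- build_ladder_trial("ascending", 0.073)
  expect_equal(rev(df$meta$contrasts), af$meta$contrasts)

  s4 <- build_ladder_trial("descending", 0.033, start_reps = 4)
  expect_equal(s4$meta$contrasts[1:4], rep(0.073, 4))
  expect_equal(length(unique(s4$meta$centers[1:4])), 4) # distinct locations
  e4 <- build_ladder_trial("ascending", 0.033, end_reps = 4)
  expect_equal(tail(e4$meta$contrasts, 4), rep(0.033, 4))

  b <- build_ladder_trial("ascending", 0.025, blank_ms = 614)
  expect_equal(b$frames$label, c("object", "blank", "object", "blank", "object"))
  expect_equal(b$frames$duration[b$frames$label == "blank"], rep(614, 2))

  f9 <- build_ladder_trial("descending", 0.016, frame_ms = 116)
  expect_true(all(f9$frames$duration == 116))
  expect_equal(f9$meta$contrasts[1], 0.071)

  expect_error(build_ladder_trial("ascending", 0.02), "ladder")
})

test_that("threshold presentations encode the gap geometry", {
  base <- build_threshold_presentation(3.3, NA, 0.041)
  expect_equal(nrow(base$inputs[[1]]), 1)
  hi <- build_threshold_presentation(3.3, 0.24, 0.041)
  expect_equal(max(hi$inputs[[1]]$amplitude), 10.0)
  # gap 3.3 arcmin -> center-to-center 6.6 arcmin -> 8 field units
  expect_equal(diff(sort(hi$inputs[[1]]$center)), 8)
  expect_error(build_threshold_presentation(-1), "invalid")
})
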