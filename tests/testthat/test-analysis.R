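test_that("constant-switch-probability fit inverts the closed form exactly", {
  N <- 2:9
  for (p_true in c(0, 0.04, 0.1, 0.5, 1)) {
    curve <- data.frame(N = N, prop_switch = 1 - (1 - p_true)^(N - 1))
    fit <- fit_constant_switch_probability(curve)
    expect_equal(fit$p, p_true, tolerance = 1e-6)
    expect_equal(fit$predicted$prop_switch, curve$prop_switch, tolerance = 1e-6)
  }
})

test_that("aggregate_proportions computes proportions and block SEMs", {
  d <- data.frame(g = rep(c("a", "b"), each = 16),
                  ok = c(rep(TRUE, 16), rep(c(TRUE, FALSE), 8)))
  agg <- aggregate_proportions(d, "g", outcome = "ok")
  expect_equal(agg$proportion[agg$g == "a"], 1)
  expect_equal(agg$sem[agg$g == "a"], 0)
  expect_equal(agg$proportion[agg$g == "b"], 0.5)
  expect_true(all(agg$sem >= 0))
  expect_error(aggregate_proportions(d[0, ], "g"), "missing cell")
})

test_that("hysteresis table uses the asymmetric conventions on the common range", {
  mkrows <- function(dir, ends, init_vis, seqs) {
    do.call(rbind, Map(function(e, s) data.frame(
      direction = dir, end_contrast = e, initial_visible = init_vis,
      visible_seq = s, stringsAsFactors = FALSE), ends, seqs))
  }
  # descending trials that all stayed visible vs ascending that never switched
  res <- rbind(
    mkrows("descending", rep(c(0.017, 0.033), each = 8), TRUE, rep("VVV", 16)),
    mkrows("ascending", rep(c(0.017, 0.033), each = 8), FALSE, rep("III", 16)))
  h <- hysteresis_gap(res)
  expect_equal(h$gap, c(1, 1))
  # identical outcome distributions in both directions give zero gap
  res2 <- rbind(
    mkrows("descending", rep(0.033, 8), TRUE, rep(c("VVV", "VVI"), 4)),
    mkrows("ascending", rep(0.033, 8), FALSE, rep(c("IIV", "III"), 4)))
  h2 <- hysteresis_gap(res2)
  expect_equal(h2$gap, 0)   # 0.5 stayed visible vs 0.5 became visible
  # contrasts outside the common range are excluded
  res3 <- rbind(res,
                mkrows("descending", rep(0.008, 8), TRUE, rep("VVV", 8)),
                mkrows("ascending", rep(0.073, 8), FALSE, rep("IIV", 8)))
  h3 <- hysteresis_gap(res3)
  expect_true(all(h3$end_contrast >= 0.017 & h3$end_contrast <= 0.065))
  expect_error(hysteresis_gap(res[res$direction == "ascending", ]), "direction")
})

test_that("psychometric table pairs conditions with the baseline", {
  d <- expand.grid(condition = c("baseline", "object_low"),
                   contrast = c(0.01, 0.02), rep = 1:8,
                   stringsAsFactors = FALSE)
  d$initial_visible <- d$condition == "object_low" | d$contrast > 0.015
  pt <- psychometric_table(d)
  expect_true(all(is.na(pt$delta_vs_baseline[pt$condition == "baseline"])))
  expect_equal(pt$delta_vs_baseline[pt$condition == "object_low" & pt$contrast == 0.01], 1)
  expect_equal(pt$delta_vs_baseline[pt$condition == "object_low" & pt$contrast == 0.02], 0)
})
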