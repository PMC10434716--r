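# Heavier Monte-Carlo runs shared between test blocks, computed once per
# session.
.run_cache <- new.env(parent = emptyenv())

cached_run <- function(key, fn) {
  if (!exists(key, envir = .run_cache)) assign(key, fn(), envir = .run_cache)
  get(key, envir = .run_cache)
}

# z-interval for a difference of two proportions from Bernoulli trial vectors
prop_diff_ci <- function(x, y, level = 0.95) {
  px <- mean(x); py <- mean(y)
  se <- sqrt(px * (1 - px) / length(x) + py * (1 - py) / length(y))
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(est = px - py, lo = px - py - z * se, hi = px - py + z * se)
}

# per-trial hysteresis outcomes on the common end-contrast range
ladder_outcomes <- function(results, common = c(0.017, 0.065)) {
  keep <- results$end_contrast >= common[1] - 1e-9 &
    results$end_contrast <= common[2] + 1e-9
  r <- results[keep, ]
  desc <- r[r$direction == "descending" & r$initial_visible, ]
  asc <- r[r$direction == "ascending" & !r$initial_visible, ]
  list(desc_stayed = !grepl("I", desc$visible_seq),
       asc_became = grepl("V", asc$visible_seq),
       desc = desc, asc = asc)
}
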