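#' Proportions with pseudo-subject SEM
#'
#' Aggregates a logical outcome column into per-cell proportions. The SEM
#' mirrors the human experiments' between-subject error bars: trials within a
#' cell are partitioned into 8 pseudo-subject blocks and the SEM is the SD of
#' the block means divided by sqrt(number of blocks). This is a presentation
#' choice, not inference.
#'
#' @param results A results data.frame (e.g., `run$results`).
#' @param grouping Character vector of grouping column names.
#' @param outcome Name of the logical outcome column.
#' @param n_blocks Number of pseudo-subject blocks.
#' @return A data.frame with the grouping columns, `n`, `proportion`, `sem`.
#' @export
aggregate_proportions <- function(results, grouping,
                                  outcome = "initial_visible", n_blocks = 8) {
  if (nrow(results) == 0) stop("missing cell: no trials to aggregate", call. = FALSE)
  key <- interaction(results[grouping], drop = TRUE, lex.order = TRUE)
  out <- lapply(split(results, key), function(d) {
    x <- as.logical(d[[outcome]])
    blocks <- (seq_along(x) - 1L) %% n_blocks
    bm <- tapply(x, blocks, mean)
    cbind(d[1, grouping, drop = FALSE],
          data.frame(n = length(x), proportion = mean(x),
                     sem = if (length(bm) > 1) stats::sd(bm) / sqrt(length(bm)) else 0))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Switch-proportion curve for the stability experiment
#'
#' Proportion of trials with at least one visibility switch as a function of
#' the number of presentations, split by the initial visibility state.
#'
#' @param results Results of the constant-contrast relocation experiment.
#' @return A `switch_curve` data.frame with columns `N`, `initial_state`,
#'   `prop_switch`, `n`, `sem`.
#' @export
switch_curve <- function(results) {
  results$initial_state <- ifelse(results$initial_visible, "visible", "invisible")
  agg <- aggregate_proportions(results, c("n_presentations", "initial_state"),
                               outcome = "any_switch")
  names(agg)[names(agg) == "n_presentations"] <- "N"
  names(agg)[names(agg) == "proportion"] <- "prop_switch"
  structure(agg, class = c("switch_curve", "data.frame"))
}

#' Fit a constant per-presentation switch probability
#'
#' Least-squares fit of `1 - (1 - p)^(N - 1)` to the proportion of trials
#' with at least one switch over the presentation counts N, with p
#' constrained to `[0, 1]`. The fit is an exact inverse on noiseless
#' closed-form curves.
#'
#' @param curve A data.frame with columns `N` and `prop_switch` (one switch
#'   direction at a time, or pooled).
#' @return A list with `p` (fitted probability), `predicted` (data.frame of N
#'   and predicted proportion), and `sse`.
#' @export
fit_constant_switch_probability <- function(curve) {
  stopifnot(all(c("N", "prop_switch") %in% names(curve)), nrow(curve) >= 2)
  N <- curve$N
  y <- curve$prop_switch
  sse <- function(p) sum((1 - (1 - p)^(N - 1) - y)^2)
  opt <- stats::optimize(sse, c(0, 1), tol = 1e-12)
  # the interior optimizer cannot land exactly on the boundary; check it too
  cand <- c(opt$minimum, 0, 1)
  p <- cand[which.min(vapply(cand, sse, 0))]
  list(p = p,
       predicted = data.frame(N = N, prop_switch = 1 - (1 - p)^(N - 1)),
       sse = sse(p))
}

#' Hysteresis table: descending versus ascending visibility
#'
#' Follows the plotting conventions of the ladder experiments: ascending
#' trials (filtered to those starting invisible) contribute the proportion
#' with at least one invisible-to-visible switch; descending trials (filtered
#' to those starting visible) contribute the proportion that remained visible
#' throughout. The gap (descending minus ascending) is computed on the end
#' contrasts common to both directions.
#'
#' @param results Results of a ladder experiment (needs columns `direction`,
#'   `end_contrast`, `initial_visible`, `visible_seq`).
#' @param common_range Contrast bounds of the comparison range.
#' @return A `hysteresis_table` data.frame with per-contrast
#'   `visible_prop_descending`, `visible_prop_ascending`, `gap`, and SEMs.
#' @export
hysteresis_gap <- function(results, common_range = c(0.017, 0.065)) {
  if (!all(c("ascending", "descending") %in% results$direction))
    stop("invalid input: results must contain both ladder directions", call. = FALSE)
  asc <- results[results$direction == "ascending" & !results$initial_visible, ]
  desc <- results[results$direction == "descending" & results$initial_visible, ]
  asc$became_visible <- grepl("V", asc$visible_seq)
  desc$stayed_visible <- !grepl("I", desc$visible_seq)
  a <- aggregate_proportions(asc, "end_contrast", outcome = "became_visible")
  d <- aggregate_proportions(desc, "end_contrast", outcome = "stayed_visible")
  common <- intersect(a$end_contrast, d$end_contrast)
  common <- common[common >= common_range[1] - 1e-9 &
                   common <= common_range[2] + 1e-9]
  a <- a[match(common, a$end_contrast), ]
  d <- d[match(common, d$end_contrast), ]
  structure(data.frame(
    end_contrast = common,
    visible_prop_descending = d$proportion,
    visible_prop_ascending = a$proportion,
    gap = d$proportion - a$proportion,
    sem_descending = d$sem,
    sem_ascending = a$sem), class = c("hysteresis_table", "data.frame"))
}

#' Psychometric table: visibility versus contrast per condition
#'
#' Per-contrast, per-condition visible proportions for the object-probe
#' designs, with the baseline condition paired to each object condition to
#' give facilitation/suppression deltas.
#'
#' @param results Results with columns `contrast`, `condition`,
#'   `initial_visible` (the probe judgment).
#' @return A data.frame with one row per (condition, contrast): `proportion`,
#'   `sem`, and `delta_vs_baseline` (NA for the baseline itself).
#' @export
psychometric_table <- function(results) {
  agg <- aggregate_proportions(results, c("condition", "contrast"))
  base <- agg[agg$condition == "baseline", ]
  agg$delta_vs_baseline <- ifelse(
    agg$condition == "baseline", NA_real_,
    agg$proportion - base$proportion[match(agg$contrast, base$contrast)])
  agg
}
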