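# Half-life estimation for non-dividing cells.
#
# In a pulse-labelling design the heavy/light ratio of a protein follows
# r(t) = exp(k * t) - 1, so log(r + 1) is linear through the origin in time
# and the decay-rate constant is the through-origin least-squares slope.

#' First-order decay-rate constant from a fold-change time course
#'
#' `k = sum(log(r_i + 1) * t_i) / sum(t_i^2)` over time points with a defined
#' fold change — the through-origin least-squares slope of `log(r + 1)`
#' against time. Undefined fold changes are skipped; a zero-hour time point
#' contributes nothing and is excluded.
#'
#' @param time_h Time points in hours (> 0).
#' @param ratio Heavy/light fold changes (`NA` = undetermined).
#' @return Rate constant in 1/hours, or `NA` when no point is usable.
#' @examples
#' decay_rate(10, 1)           # log(2) / 10
#' decay_rate(c(7, 11, 24, 34), exp(0.01 * c(7, 11, 24, 34)) - 1)
#' @export
decay_rate <- function(time_h, ratio) {
  keep <- !is.na(ratio) & !is.na(time_h) & time_h > 0
  if (!any(keep)) return(NA_real_)
  t <- time_h[keep]
  r <- ratio[keep]
  sum(log(r + 1) * t) / sum(t^2)
}

#' Half-life from a decay-rate constant
#'
#' `T_half = log(2) / k` for positive rates. Non-positive rates mean the
#' protein did not measurably degrade within the observation window and the
#' half-life is reported as undetermined rather than clipped to a cap.
#'
#' @param k_dp Decay-rate constant (1/hours).
#' @return Half-life in hours, or `NA`.
#' @export
half_life <- function(k_dp) {
  ifelse(!is.na(k_dp) & k_dp > 0, log(2) / k_dp, NA_real_)
}

#' Fit quality of a fold-change time course
#'
#' Squared Pearson correlation between time and `log(r + 1)`, the quantity
#' used to select the high-quality half-life subset (default cutoff 0.85).
#'
#' @inheritParams decay_rate
#' @return R-squared in `[0, 1]`, or `NA` for fewer than two usable points or
#'   zero variance.
#' @export
fit_r_squared <- function(time_h, ratio) {
  keep <- !is.na(ratio) & !is.na(time_h) & time_h > 0
  t <- time_h[keep]
  y <- log(ratio[keep] + 1)
  if (length(t) < 2 || sd(t) == 0 || sd(y) == 0) return(NA_real_)
  cor(t, y)^2
}

#' Data-quality label of a time course
#'
#' With a four-time-point design: `"weak"` when a fold change could be
#' determined at three or more of the four time points, `"good"` when three
#' or more of those fold changes are each based on at least three quantified
#' peptides, `"poor"` otherwise.
#'
#' @inheritParams decay_rate
#' @param n_peptides Peptides behind each fold change.
#' @param n_design Time points in the design (default 4).
#' @return One of `"good"`, `"weak"`, `"poor"`.
#' @export
qc_label <- function(time_h, ratio, n_peptides = rep(1L, length(ratio)), n_design = 4L) {
  defined <- !is.na(ratio)
  need <- n_design - 1L
  if (sum(defined & n_peptides >= 3) >= need) return("good")
  if (sum(defined) >= need) return("weak")
  "poor"
}

#' Fit the turnover model to one protein's time course
#'
#' @inheritParams qc_label
#' @return Object of class `turnover_fit` with the rate constant, half-life,
#'   R-squared, QC label and the underlying points. Use [tidy()] / [glance()]
#'   for tibble output and [autoplot()] for the fitted course.
#' @export
turnover_fit <- function(time_h, ratio, n_peptides = rep(1L, length(ratio)), n_design = 4L) {
  k <- decay_rate(time_h, ratio)
  structure(
    list(
      k_dp = k,
      t_half = half_life(k),
      r_squared = fit_r_squared(time_h, ratio),
      qc = qc_label(time_h, ratio, n_peptides, n_design),
      n_points = sum(!is.na(ratio)),
      data = tibble(time_h = time_h, ratio = ratio, n_peptides = n_peptides)
    ),
    class = "turnover_fit"
  )
}

#' @export
print.turnover_fit <- function(x, ...) {
  cat("<turnover_fit> k_dp =", signif(x$k_dp, 4), "1/h, T1/2 =",
      signif(x$t_half, 5), "h, R2 =", signif(x$r_squared, 3),
      ", QC =", x$qc, "\n")
  invisible(x)
}

#' @export
tidy.turnover_fit <- function(x, ...) {
  tibble(k_dp = x$k_dp, t_half = x$t_half, r_squared = x$r_squared,
         qc = x$qc, n_points = x$n_points)
}

#' @export
glance.turnover_fit <- function(x, ...) tidy(x)

#' Fit turnover models to many proteins at once
#'
#' @param fold_changes Tibble with columns `protein`, `time_h`, `ratio` and
#'   optionally `n_peptides` (defaults to 1) and `replicate` (carried into
#'   the grouping when present).
#' @param n_design Time points in the design.
#' @return Tibble with one row per protein (and replicate, if given):
#'   `k_dp`, `t_half`, `r_squared`, `qc`, `n_points`.
#' @export
fit_turnover <- function(fold_changes, n_design = 4L) {
  if (!"n_peptides" %in% names(fold_changes)) fold_changes$n_peptides <- 1L
  keys <- intersect(c("protein", "replicate"), names(fold_changes))
  fold_changes |>
    group_by(across(all_of(keys))) |>
    group_modify(function(df, key) {
      tidy(turnover_fit(df$time_h, df$ratio, df$n_peptides, n_design))
    }) |>
    ungroup()
}

#' Merge replicate half-lives into per-protein summaries
#'
#' Restricts to fits with R-squared above `min_r2` and a determined
#' half-life, keeps proteins measured in at least two biological replicates,
#' and reports the arithmetic-mean half-life on the hour scale together with
#' its log10, with the per-replicate values retained.
#'
#' @param fits Tibble with columns `protein`, `replicate`, `t_half`,
#'   `r_squared`.
#' @param min_r2 High-quality cutoff (exclusive; default 0.85).
#' @return Tibble (`protein`, `n_replicates`, `t_half_mean`,
#'   `log10_t_half`, `t_half_by_replicate` list-column).
#' @export
merge_replicates <- function(fits, min_r2 = 0.85) {
  fits |>
    filter(!is.na(.data$t_half), !is.na(.data$r_squared), .data$r_squared > min_r2) |>
    group_by(.data$protein) |>
    filter(n_distinct(.data$replicate) >= 2) |>
    summarise(
      n_replicates = n_distinct(.data$replicate),
      t_half_mean = mean(.data$t_half),
      log10_t_half = log10(mean(.data$t_half)),
      t_half_by_replicate = list(setNames(.data$t_half, .data$replicate)),
      .groups = "drop"
    )
}

#' Convert hours to days
#'
#' @param hours Duration in hours.
#' @return Duration in days.
#' @export
hours_to_days <- function(hours) hours / 24
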