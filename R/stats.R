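#' Group summary (mean, SD, n)
#'
#' @param mean Group mean.
#' @param sd Group standard deviation (>= 0).
#' @param n Group size (>= 2).
#' @return A `group_summary` object.
#' @export
group_summary <- function(mean, sd, n) {
  stopifnot(is.finite(mean), sd >= 0, n >= 2)
  structure(list(mean = mean, sd = sd, n = as.integer(n)),
            class = "group_summary")
}

#' Pooled-variance two-sample t-test from summary statistics
#'
#' The classic independent two-sample t-test computed directly from
#' `(mean, sd, n)` triplets: pooled variance
#' `sp2 = ((n1-1)*s1^2 + (n2-1)*s2^2) / (n1+n2-2)`,
#' `t = (m1-m2) / (sp*sqrt(1/n1 + 1/n2))`, two-sided p from the t
#' distribution with `n1+n2-2` degrees of freedom. This is the variant that
#' reproduces published screening tables reported as mean (SD) per stratum.
#'
#' @param g1,g2 `group_summary` objects (or lists with `mean`, `sd`, `n`).
#' @param alpha Significance level for the `significant` flag.
#' @return A `ttest_result` object: `t_stat`, `df`, `p_two_sided`,
#'   `mean_difference` (= `g1$mean - g2$mean`), `significant`, `degenerate`
#'   (TRUE when the pooled SD is zero).
#' @export
#' @examples
#' # a high P5/P4 harmonic ratio in the low-flow stratum
#' ttest_from_summary(group_summary(1.075, 0.601, 11),
#'                    group_summary(0.711, 0.273, 34))$p_two_sided
ttest_from_summary <- function(g1, g2, alpha = 0.05) {
  stopifnot(g1$n >= 2, g2$n >= 2, g1$sd >= 0, g2$sd >= 0)
  df <- g1$n + g2$n - 2
  sp2 <- ((g1$n - 1) * g1$sd^2 + (g2$n - 1) * g2$sd^2) / df
  diff <- g1$mean - g2$mean
  degenerate <- sp2 == 0
  if (degenerate) {
    if (diff == 0) { t_stat <- 0; p <- 1 } else { t_stat <- Inf * sign(diff); p <- 0 }
  } else {
    t_stat <- diff / sqrt(sp2 * (1 / g1$n + 1 / g2$n))
    p <- 2 * stats::pt(-abs(t_stat), df)
  }
  structure(list(t_stat = t_stat, df = df, p_two_sided = p,
                 mean_difference = diff, significant = p < alpha,
                 alpha = alpha, degenerate = degenerate),
            class = "ttest_result")
}

#' Pooled-variance two-sample t-test from raw samples
#'
#' Computes each group's mean and SD and delegates to
#' [ttest_from_summary()], so the two paths agree exactly.
#'
#' @param x1,x2 Numeric sample vectors (each of length >= 2).
#' @param alpha Significance level.
#' @return A `ttest_result`.
#' @export
ttest_from_samples <- function(x1, x2, alpha = 0.05) {
  if (length(x1) < 2 || length(x2) < 2)
    stop("each group needs at least 2 observations")
  stopifnot(all(is.finite(x1)), all(is.finite(x2)))
  ttest_from_summary(group_summary(mean(x1), stats::sd(x1), length(x1)),
                     group_summary(mean(x2), stats::sd(x2), length(x2)),
                     alpha = alpha)
}

#' Screen harmonic-ratio features at a flow cutoff
#'
#' Splits the cohort into a low-flow stratum (`flow <= cutoff`, the
#' dysfunction candidates) and a high-flow stratum, and t-tests each of the
#' five harmonic ratios between strata. Five features are screened at raw
#' `alpha` with no multiple-testing correction, matching the screening
#' convention the feature set was validated under; the returned table
#' carries a `note` attribute recording this.
#'
#' @param features Feature table from [feature_table()] (needs the `hr*`
#'   columns).
#' @param flows Access flows (mL/min), defaults to `features$flow_mL_min`.
#' @param cutoff Flow cutoff in mL/min.
#' @param alpha Significance level (default 0.05).
#' @return Data.frame with one row per harmonic ratio: `harmonic_ratio`,
#'   `mean_low`, `sd_low`, `n_low`, `mean_high`, `sd_high`, `n_high`,
#'   `difference` (low minus high), `t_stat`, `p_value`, `significant`.
#' @export
screen_features <- function(features, flows = features$flow_mL_min,
                            cutoff, alpha = 0.05) {
  stopifnot(nrow(features) == length(flows), all(flows > 0))
  if (cutoff < min(flows) || cutoff > max(flows))
    stop("cutoff ", cutoff, " mL/min outside the observed flow range")
  low <- flows <= cutoff
  if (sum(low) < 2) stop("low-flow stratum (<= ", cutoff, ") has n < 2")
  if (sum(!low) < 2) stop("high-flow stratum (> ", cutoff, ") has n < 2")
  rows <- lapply(hr_feature_names(), function(hr) {
    x1 <- features[[hr]][low]; x2 <- features[[hr]][!low]
    tt <- ttest_from_samples(x1, x2, alpha = alpha)
    data.frame(harmonic_ratio = hr,
               mean_low = mean(x1), sd_low = stats::sd(x1), n_low = length(x1),
               mean_high = mean(x2), sd_high = stats::sd(x2),
               n_high = length(x2),
               difference = tt$mean_difference, t_stat = tt$t_stat,
               p_value = tt$p_two_sided, significant = tt$significant,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "note") <- "five features screened at raw alpha; no multiplicity correction"
  out
}
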