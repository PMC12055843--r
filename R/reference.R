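#' Reference summary statistics of the calibrating NPH study
#'
#' Published participant-level summary statistics from the clinical
#' eye-tracking study of picture naming in normal pressure hydrocephalus
#' (NPH, n = 14) versus healthy elderly (HE, n = 12) that this package's
#' presets and power analyses are calibrated against. These are the inputs
#' to post-hoc power computations; the raw gaze recordings behind them are
#' not public.
#'
#' @return A list of tibbles:
#' \describe{
#'   \item{lrt}{lexical-retrieval score means/SDs per group;}
#'   \item{metrics}{the six metric means/SDs per group with the reported
#'     Mann-Whitney U;}
#'   \item{by_response}{the six metric means/SDs per group x response
#'     type;}
#'   \item{correlations}{score-vs-metric Pearson r with its n;}
#'   \item{anova_f}{reported mixed-ANOVA F values (df 1, 24) per metric
#'     and effect.}
#' }
#' @export
reference_study <- function() {
  list(
    lrt = tibble::tibble(
      group = c("NPH", "HE"), n = c(14L, 12L),
      mean = c(52.14, 84.17), sd = c(16.88, 7.26)),
    metrics = tibble::tibble(
      metric = c("FC", "FD", "SC", "SD", "SST", "SAT"),
      mean_nph = c(22.63, 6139.76, 21.65, 4143.48, 6064.02, 666.74),
      sd_nph = c(8.31, 2239.67, 8.30, 1489.44, 3075.49, 278.87),
      mean_he = c(12.31, 3263.67, 11.31, 2018.58, 2617.30, 311.28),
      sd_he = c(3.06, 889.09, 3.06, 612.86, 1067.94, 101.26),
      n_nph = 14L, n_he = 12L,
      U = c(2, 19, 20, 10, 13, 15)),
    by_response = tibble::tibble(
      metric = rep(c("FC", "FD", "SC", "SD", "SST", "SAT"), each = 4),
      group = rep(rep(c("NPH", "HE"), each = 2), 6),
      response_type = rep(c("correct", "incorrect"), 12),
      mean = c(14.05, 34.23, 9.94, 22.26,
               3925.58, 9216.46, 2634.16, 5663.05,
               13.08, 33.44, 8.94, 21.26,
               2249.65, 6425.71, 1658.81, 4152.57,
               3599.13, 9484.76, 2076.57, 5236.22,
               415.81, 978.90, 241.02, 713.40),
      sd = c(4.18, 14.84, 2.08, 8.90,
             1352.17, 4324.67, 640.07, 2401.56,
             4.14, 14.62, 2.08, 8.90,
             634.63, 2080.53, 490.01, 1324.87,
             1695.89, 5620.43, 753.80, 3013.62,
             135.81, 395.64, 76.47, 418.35)),
    correlations = tibble::tibble(
      metric = c("FC", "FD", "SC", "SD", "SST", "SAT"),
      r = c(-0.569, -0.566, -0.569, -0.554, -0.488, -0.462),
      n = 26L),
    anova_f = tibble::tibble(
      metric = rep(c("FC", "FD", "SC", "SD", "SST", "SAT"), 2),
      effect = rep(c("group", "response_type"), each = 6),
      F = c(7.534, 8.281, 7.956, 13.600, 6.576, 6.109,
            60.922, 46.643, 62.539, 94.014, 39.284, 46.093),
      df1 = 1L, df2 = 24L)
  )
}

#' Post-hoc power report for the reference study
#'
#' Recomputes every power claim derivable from the published summary
#' statistics: the rank-test (ARE-corrected) power of the lexical-score
#' and six metric group comparisons from pooled-SD effect sizes, the
#' Fisher-z power of the score-metric correlations, and the observed power
#' of the reported within-subject F effects.
#'
#' @param alpha Significance level (default 0.05).
#' @return A list of tibbles: `$lrt`, `$metrics`, `$correlations`,
#'   `$anova`.
#' @export
reference_power_report <- function(alpha = 0.05) {
  ref <- reference_study()
  lrt_d <- cohens_d(ref$lrt$mean[1], ref$lrt$sd[1], ref$lrt$n[1],
                    ref$lrt$mean[2], ref$lrt$sd[2], ref$lrt$n[2])
  lrt <- power_two_sample(lrt_d, ref$lrt$n[1], ref$lrt$n[2], alpha,
                          are_correction = TRUE)

  mt <- ref$metrics
  metrics <- dplyr::bind_rows(lapply(seq_len(nrow(mt)), function(i) {
    d <- cohens_d(mt$mean_nph[i], mt$sd_nph[i], mt$n_nph[i],
                  mt$mean_he[i], mt$sd_he[i], mt$n_he[i])
    out <- power_two_sample(d, mt$n_nph[i], mt$n_he[i], alpha,
                            are_correction = TRUE)
    dplyr::bind_cols(tibble::tibble(metric = mt$metric[i]), out)
  }))

  co <- ref$correlations
  correlations <- dplyr::bind_rows(lapply(seq_len(nrow(co)), function(i) {
    out <- power_correlation(abs(co$r[i]), co$n[i], alpha)
    dplyr::bind_cols(tibble::tibble(metric = co$metric[i]), out)
  }))

  av <- ref$anova_f
  anova <- dplyr::bind_rows(lapply(seq_len(nrow(av)), function(i) {
    out <- observed_power_f(av$F[i], av$df1[i], av$df2[i], alpha)
    dplyr::bind_cols(av[i, c("metric", "effect")], out)
  }))

  list(lrt = lrt, metrics = metrics, correlations = correlations,
       anova = anova)
}
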