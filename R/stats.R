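#' Mann-Whitney U comparison of two groups
#'
#' Rank-sum test in the reporting convention of clinical software: mid-ranks
#' for ties, `U = min(U1, U2)`, a Z value from the normal approximation with
#' the tie-corrected variance, and a two-sided p from that Z. The sign of Z
#' follows the direction of group 1's mean-rank deficit (negative when group
#' 1 ranks lower). No continuity correction is applied.
#'
#' @param x,y Numeric values for groups 1 and 2.
#' @param metric Optional label carried into the result.
#' @return A one-row tibble: `metric`, group means/sds, `n1`, `n2`, `U`,
#'   `Z`, `p`.
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))$U  # complete separation: 0
mann_whitney <- function(x, y, metric = NA_character_) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 1L, n2 >= 1L)
  r <- rank(c(x, y))
  r1 <- sum(r[seq_len(n1)])
  u1 <- r1 - n1 * (n1 + 1) / 2
  u2 <- n1 * n2 - u1
  n <- n1 + n2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  z <- if (sigma2 <= 0) 0 else (u1 - n1 * n2 / 2) / sqrt(sigma2)
  p <- if (sigma2 <= 0) 1 else 2 * stats::pnorm(-abs(z))
  tibble::tibble(metric = metric,
                 mean1 = mean(x), sd1 = stats::sd(x),
                 mean2 = mean(y), sd2 = stats::sd(y),
                 n1 = n1, n2 = n2,
                 U = min(u1, u2), Z = z, p = min(p, 1))
}

#' Pearson correlation with t-based p value
#'
#' Product-moment correlation via [stats::cor.test()]; zero-variance input
#' yields a missing result rather than an error.
#'
#' @param a,b Numeric vectors of equal length (>= 3).
#' @param metric Optional label carried into the result.
#' @return A one-row tibble: `metric`, `r`, `p`, `n`.
#' @export
pearson_correlation <- function(a, b, metric = NA_character_) {
  stopifnot(length(a) == length(b), length(a) >= 3L)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    return(tibble::tibble(metric = metric, r = NA_real_, p = NA_real_,
                          n = length(a)))
  ct <- stats::cor.test(a, b, method = "pearson")
  tibble::tibble(metric = metric, r = unname(ct$estimate),
                 p = ct$p.value, n = length(a))
}

#' Two-way mixed ANOVA (group x response type)
#'
#' One between-subjects factor (group, 2 levels) crossed with one
#' within-subjects factor (response type: correct vs incorrect), fitted as
#' a univariate ANOVA with an `Error(participant)` stratum — the classical
#' sums-of-squares decomposition for this design, giving each effect
#' `df = (1, N - 2)`. Participants lacking either response-type cell are
#' excluded with a warning. Bonferroni-corrected post-hoc paired
#' comparisons of the correct vs incorrect cell means are run within each
#' group (family size 2).
#'
#' @param summaries Participant summary tibble from
#'   [aggregate_participants()] (rows with `response_type` in
#'   `correct`/`incorrect`).
#' @param metric Name of the metric column to analyse.
#' @return A list of class `mixed_anova_result`: `$effects` (tibble with
#'   `effect`, `F`, `df1`, `df2`, `p`), `$cell_means`, `$posthoc`,
#'   `$n_participants`.
#' @export
mixed_anova <- function(summaries, metric) {
  d <- summaries[summaries$response_type %in% c("correct", "incorrect"),
                 c("participant_id", "group", "response_type", metric)]
  names(d)[4] <- "value"
  complete <- names(which(table(d$participant_id) == 2L))
  dropped <- setdiff(unique(d$participant_id), complete)
  if (length(dropped))
    warning("mixed_anova: excluding participant(s) without both response ",
            "types: ", paste(dropped, collapse = ", "), call. = FALSE)
  d <- d[d$participant_id %in% complete, ]
  if (length(unique(d$participant_id[d$group == "NPH"])) < 2L ||
      length(unique(d$participant_id[d$group == "HE"])) < 2L)
    stop("analysis error: need >= 2 complete participants per group",
         call. = FALSE)

  d$participant_id <- factor(d$participant_id)
  d$group <- factor(d$group)
  d$response_type <- factor(d$response_type)
  fit <- stats::aov(value ~ group * response_type + Error(participant_id),
                    data = d)
  sm <- summary(fit)
  between <- as.data.frame(sm[["Error: participant_id"]][[1]])
  within <- as.data.frame(sm[["Error: Within"]][[1]])
  row_of <- function(tab, name) {
    i <- match(name, trimws(rownames(tab)))
    tab[i, , drop = FALSE]
  }
  eff <- function(tab, name, label) {
    rw <- row_of(tab, name)
    resid <- row_of(tab, "Residuals")
    tibble::tibble(effect = label, F = rw[["F value"]],
                   df1 = rw[["Df"]], df2 = resid[["Df"]],
                   p = rw[["Pr(>F)"]])
  }
  effects <- dplyr::bind_rows(
    eff(between, "group", "group"),
    eff(within, "response_type", "response_type"),
    eff(within, "group:response_type", "interaction"))
  # degenerate zero-variance data: a zero effect over a zero residual is
  # reported as F = 0, not NaN
  deg <- !is.finite(effects$F)
  effects$F[deg] <- 0
  effects$p[deg] <- 1

  cell_means <- dplyr::summarise(
    dplyr::group_by(d, .data$group, .data$response_type),
    mean = mean(.data$value), sd = stats::sd(.data$value),
    n = dplyr::n(), .groups = "drop")

  posthoc <- dplyr::bind_rows(lapply(levels(d$group), function(g) {
    sub <- d[d$group == g, ]
    sub <- sub[order(sub$participant_id, sub$response_type), ]
    co <- sub$value[sub$response_type == "correct"]
    inc <- sub$value[sub$response_type == "incorrect"]
    tt <- tryCatch(stats::t.test(inc, co, paired = TRUE),
                   error = function(e) NULL)  # constant differences
    if (is.null(tt))
      return(tibble::tibble(group = g, contrast = "incorrect - correct",
                            estimate = mean(inc - co), t = NA_real_,
                            df = NA_real_, p_bonferroni = NA_real_))
    tibble::tibble(group = g, contrast = "incorrect - correct",
                   estimate = unname(tt$estimate), t = unname(tt$statistic),
                   df = unname(tt$parameter),
                   p_bonferroni = min(1, tt$p.value * 2))
  }))

  structure(list(metric = metric, effects = effects, cell_means = cell_means,
                 posthoc = posthoc,
                 n_participants = length(complete)),
            class = "mixed_anova_result")
}

#' @export
print.mixed_anova_result <- function(x, ...) {
  cat("Two-way mixed ANOVA for", x$metric, "(n =", x$n_participants, ")\n")
  print(as.data.frame(x$effects), row.names = FALSE)
  invisible(x)
}

#' Post-hoc power of a two-sample comparison
#'
#' Power of the two-sided two-sample t test at standardized difference `d`,
#' via the noncentral t distribution with
#' `ncp = d * sqrt(n1 * n2 / (n1 + n2))`. With `are_correction = TRUE` the
#' sample sizes are first multiplied by the Wilcoxon-Mann-Whitney
#' asymptotic relative efficiency 3/pi, the standard device for post-hoc
#' power of a rank-based two-group comparison.
#'
#' @param d Standardized mean difference (Cohen's d, >= 0).
#' @param n1,n2 Group sizes (>= 2).
#' @param alpha Two-sided significance level.
#' @param are_correction Apply the 3/pi Mann-Whitney efficiency correction.
#' @return A one-row tibble: `kind`, `d`, `n1`, `n2`, `alpha`, `power`.
#' @export
power_two_sample <- function(d, n1, n2, alpha = 0.05, are_correction = FALSE) {
  stopifnot(d >= 0, n1 >= 2, n2 >= 2)
  e1 <- n1; e2 <- n2
  if (are_correction) { e1 <- n1 * 3 / pi; e2 <- n2 * 3 / pi }
  df <- e1 + e2 - 2
  ncp <- d * sqrt(e1 * e2 / (e1 + e2))
  tcrit <- stats::qt(1 - alpha / 2, df)
  power <- stats::pt(tcrit, df, ncp, lower.tail = FALSE) +
    stats::pt(-tcrit, df, ncp)
  tibble::tibble(kind = if (are_correction) "two_sample_are" else "two_sample",
                 d = d, n1 = n1, n2 = n2, alpha = alpha, power = power)
}

#' Post-hoc power of a correlation test (Fisher z)
#'
#' Two-sided power of the test that a population correlation is zero, via
#' the Fisher z approximation:
#' `power = Phi(atanh(r) * sqrt(n - 3) - z_{1 - alpha/2}) +
#'          Phi(-atanh(r) * sqrt(n - 3) - z_{1 - alpha/2})`.
#'
#' @param r Effect size, `0 <= r < 1`.
#' @param n Sample size (>= 4).
#' @param alpha Two-sided significance level.
#' @return A one-row tibble: `kind`, `r`, `n`, `alpha`, `power`.
#' @export
power_correlation <- function(r, n, alpha = 0.05) {
  stopifnot(r >= 0, r < 1, n >= 4)
  za <- stats::qnorm(1 - alpha / 2)
  fz <- atanh(r) * sqrt(n - 3)
  power <- stats::pnorm(fz - za) + stats::pnorm(-fz - za)
  tibble::tibble(kind = "correlation", r = r, n = n, alpha = alpha,
                 power = power)
}

#' Observed power of an F effect
#'
#' G*Power-style observed power: the noncentrality is taken from the
#' observed statistic, `lambda = F * df1`, and power is the probability
#' that a noncentral F(df1, df2, lambda) exceeds the critical value at
#' `alpha`.
#'
#' @param f Observed F statistic (>= 0).
#' @param df1,df2 Numerator and denominator degrees of freedom.
#' @param alpha Significance level.
#' @return A one-row tibble: `kind`, `F`, `df1`, `df2`, `alpha`, `power`.
#' @export
observed_power_f <- function(f, df1, df2, alpha = 0.05) {
  stopifnot(f >= 0, df1 >= 1, df2 >= 1)
  fcrit <- stats::qf(1 - alpha, df1, df2)
  power <- stats::pf(fcrit, df1, df2, ncp = f * df1, lower.tail = FALSE)
  tibble::tibble(kind = "f_effect", F = f, df1 = df1, df2 = df2,
                 alpha = alpha, power = power)
}

#' Pooled-SD standardized difference from summary statistics
#'
#' Cohen's d computed from group means, SDs and sizes, pooling variances
#' with `n - 1` weights. Useful for post-hoc power from published summary
#' tables.
#'
#' @param mean1,sd1,n1 Group 1 summary.
#' @param mean2,sd2,n2 Group 2 summary.
#' @return Absolute standardized difference.
#' @export
cohens_d <- function(mean1, sd1, n1, mean2, sd2, n2) {
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  abs(mean1 - mean2) / sp
}

#' Group comparison report across metrics
#'
#' Runs [mann_whitney()] for every metric column of a participant summary
#' (one value per participant, `response_type == "all"`), NPH vs HE.
#'
#' @param summaries Tibble from [aggregate_participants()].
#' @param metrics Metric column names (default the six core metrics).
#' @return Tibble with one row per metric.
#' @export
compare_groups <- function(summaries,
                           metrics = c("FC", "FD", "SC", "SD", "SST", "SAT")) {
  s <- summaries[summaries$response_type == "all", ]
  dplyr::bind_rows(lapply(metrics, function(m) {
    mann_whitney(s[[m]][s$group == "NPH"], s[[m]][s$group == "HE"], metric = m)
  }))
}
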