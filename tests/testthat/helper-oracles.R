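# Independent reference implementations used as oracles. These are written
# as literal per-sample / per-pair loops, deliberately sharing no code with
# the package internals.

# Brute-force velocity-threshold classifier: label every inter-sample
# segment, split runs at saccadic segments, keep runs spanning at least
# min_fixation_ms, snap to the first sample, rebuild saccades as the
# inter-fixation gaps.
oracle_classify <- function(t, x, y, config) {
  g <- config$geometry
  n <- length(t)
  fix <- data.frame(t_start_ms = numeric(), t_end_ms = numeric(),
                    x_px = numeric(), y_px = numeric())
  if (n >= 2) {
    lab <- logical(n - 1)
    for (i in seq_len(n - 1)) {
      d_mm <- sqrt((x[i + 1] - x[i])^2 + (y[i + 1] - y[i])^2) *
        g$pixel_pitch_mm
      ang <- 2 * atan(d_mm / (2 * g$viewing_distance_mm)) * 180 / pi
      lab[i] <- ang / ((t[i + 1] - t[i]) / 1000) >
        config$velocity_threshold_deg_s
    }
    start <- 1L
    ends <- c(which(lab), n)  # a saccadic segment i ends the run at sample i
    for (e in ends) {
      if (t[e] - t[start] >= config$min_fixation_ms) {
        fix <- rbind(fix, data.frame(t_start_ms = t[start], t_end_ms = t[e],
                                     x_px = x[start], y_px = y[start]))
      }
      start <- e + 1L
    }
  }
  sac <- data.frame(s_start_ms = numeric(), s_end_ms = numeric(),
                    x_start_px = numeric(), y_start_px = numeric(),
                    x_end_px = numeric(), y_end_px = numeric())
  if (nrow(fix) >= 2) {
    for (i in seq_len(nrow(fix) - 1)) {
      sac <- rbind(sac, data.frame(
        s_start_ms = fix$t_end_ms[i], s_end_ms = fix$t_start_ms[i + 1],
        x_start_px = fix$x_px[i], y_start_px = fix$y_px[i],
        x_end_px = fix$x_px[i + 1], y_end_px = fix$y_px[i + 1]))
    }
  }
  list(fixations = fix, saccades = sac)
}

# Exhaustive pairwise-win count for the Mann-Whitney U (min of the two).
oracle_u <- function(x, y) {
  u1 <- 0
  for (xi in x) for (yj in y) u1 <- u1 + (xi > yj) + 0.5 * (xi == yj)
  min(u1, length(x) * length(y) - u1)
}

# Textbook sums-of-squares decomposition of the 2 (between) x 2 (within)
# mixed design, balanced groups. `d` has participant_id, group,
# response_type, value.
oracle_mixed_anova <- function(d) {
  grand <- mean(d$value)
  subj <- tapply(d$value, d$participant_id, mean)
  subj_group <- tapply(d$group, d$participant_id, function(g) g[1])
  m_g <- tapply(d$value, d$group, mean)
  m_r <- tapply(d$value, d$response_type, mean)
  m_gr <- tapply(d$value, list(d$group, d$response_type), mean)
  groups <- names(m_g); resps <- names(m_r)
  n_per_group <- table(subj_group)[groups]
  N <- length(subj)

  ss_group <- sum(2 * n_per_group * (m_g - grand)^2)
  ss_subjw <- 2 * sum((subj - m_g[subj_group])^2)
  ss_resp <- sum(N * (m_r - grand)^2)
  ss_cells <- 0
  for (g in groups) for (r in resps)
    ss_cells <- ss_cells + n_per_group[[g]] * (m_gr[g, r] - grand)^2
  ss_int <- ss_cells - ss_group - ss_resp
  ss_err <- 0
  for (i in seq_len(nrow(d))) {
    g <- d$group[i]; r <- d$response_type[i]; s <- as.character(d$participant_id[i])
    ss_err <- ss_err + (d$value[i] - subj[[s]] - m_gr[g, r] + m_g[[g]])^2
  }
  df2 <- N - 2
  list(F_group = (ss_group / 1) / (ss_subjw / df2),
       F_resp = (ss_resp / 1) / (ss_err / df2),
       F_int = (ss_int / 1) / (ss_err / df2),
       df2 = df2)
}

# Random gaze stream with velocities scattered around the classification
# threshold so run boundaries are exercised.
random_stream <- function(n = 200, seed = 1) {
  set.seed(seed)
  dt <- runif(n - 1, 25, 45)
  t <- cumsum(c(0, dt))
  # steps: mixture of sub-threshold drift, near-threshold and clear jumps
  kind <- sample(1:3, n - 1, replace = TRUE, prob = c(0.6, 0.2, 0.2))
  step <- c(runif(sum(kind == 1), 0, 25),
            runif(sum(kind == 2), 25, 55),
            runif(sum(kind == 3), 100, 600))[order(order(kind))]
  th <- runif(n - 1, 0, 2 * pi)
  x <- cumsum(c(960, step * cos(th)))
  y <- cumsum(c(540, step * sin(th)))
  tibble::tibble(t_ms = t, x_px = x, y_px = y)
}

# The default synthetic study and its pipeline products, generated once
# and shared across test files.
.study_cache <- new.env(parent = emptyenv())
default_study_fixture <- function() {
  if (is.null(.study_cache$study)) {
    .study_cache$study <- simulate_study(seed = 20240901)
    .study_cache$pipeline <- run_pipeline(.study_cache$study)
  }
  list(study = .study_cache$study, pipeline = .study_cache$pipeline)
}

# An event stream built directly from fixation bounds/coordinates, with
# saccades as the inter-fixation gaps.
make_stream <- function(t_start, t_end, x, y) {
  tab <- tibble::tibble(trial_id = "t", kind = "fixation",
                        t_start_ms = t_start, t_end_ms = t_end,
                        x_px = x, y_px = y,
                        x_end_px = NA_real_, y_end_px = NA_real_,
                        inside_aoi = TRUE)
  table_to_events(tab)
}
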