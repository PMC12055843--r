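#' Cohort parameters for the synthetic gaze generator
#'
#' Describes one cohort's per-trial gaze behaviour: how many fixations a
#' trial contains, how long each lasts, how far and how fast the gaze jumps
#' between them, how often it strays outside the AOI, and how much every
#' parameter inflates on incorrectly answered trials.
#'
#' @param name Cohort label (`"NPH"` or `"HE"` in the default study).
#' @param n_participants Number of participants.
#' @param fixation_count_mean,fixation_count_sd Per-trial fixation count
#'   distribution (rounded truncated normal, minimum 1).
#' @param fixation_dur_mean_ms,fixation_dur_sd_ms Per-fixation duration
#'   distribution (lognormal truncated below at the minimum fixation
#'   duration).
#' @param saccade_gap_mean_ms Mean inter-fixation gap in ms.
#' @param step_px_mean,step_px_sd Inter-fixation displacement magnitude in
#'   pixels (truncated normal).
#' @param outside_aoi_prob Probability that a fixation centre is ejected
#'   outside the AOI.
#' @param incorrect_multiplier Factor (>= 1) applied to the fixation count
#'   and duration parameters on incorrect trials.
#' @param jitter_px Radius of the uniform within-fixation jitter disc; the
#'   default keeps sample-to-sample velocity well below half the 30 deg/s
#'   classification threshold. Set to 0 for noiseless plateaus.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(name, n_participants,
                        fixation_count_mean, fixation_count_sd,
                        fixation_dur_mean_ms, fixation_dur_sd_ms,
                        saccade_gap_mean_ms,
                        step_px_mean, step_px_sd,
                        outside_aoi_prob = 0.1,
                        incorrect_multiplier = 1.5,
                        jitter_px = 9) {
  s <- list(name = name, n_participants = as.integer(n_participants),
            fixation_count_mean = fixation_count_mean,
            fixation_count_sd = fixation_count_sd,
            fixation_dur_mean_ms = fixation_dur_mean_ms,
            fixation_dur_sd_ms = fixation_dur_sd_ms,
            saccade_gap_mean_ms = saccade_gap_mean_ms,
            step_px_mean = step_px_mean, step_px_sd = step_px_sd,
            outside_aoi_prob = outside_aoi_prob,
            incorrect_multiplier = incorrect_multiplier,
            jitter_px = jitter_px)
  means <- c("fixation_count_mean", "fixation_dur_mean_ms",
             "saccade_gap_mean_ms", "step_px_mean")
  for (k in means) if (s[[k]] <= 0)
    stop("cohort_spec: `", k, "` must be > 0", call. = FALSE)
  if (outside_aoi_prob < 0 || outside_aoi_prob > 1)
    stop("cohort_spec: `outside_aoi_prob` must be in [0, 1]", call. = FALSE)
  if (incorrect_multiplier < 1)
    stop("cohort_spec: `incorrect_multiplier` must be >= 1", call. = FALSE)
  if (n_participants < 0)
    stop("cohort_spec: `n_participants` must be >= 0", call. = FALSE)
  structure(s, class = "cohort_spec")
}

#' Default clinical-cohort preset (NPH-like)
#'
#' Calibrated so that a 14-participant, 30-trial study lands near the
#' published magnitudes for a normal-pressure-hydrocephalus cohort:
#' ~14 inside-AOI fixations of ~279 ms on correct trials, ~172 ms
#' inter-fixation gaps, ~275 px steps, with counts and durations inflating
#' on incorrect trials. The count parameter covers all plateaus including
#' the `outside_aoi_prob` fraction later removed by the AOI filter, so it
#' sits above the inside-count target by `1 / (1 - outside_aoi_prob)`.
#'
#' @param n_participants Number of participants (default 14).
#' @return A `cohort_spec`.
#' @export
cohort_nph <- function(n_participants = 14L) {
  cohort_spec("NPH", n_participants,
              fixation_count_mean = 14.05 / 0.85, fixation_count_sd = 4.18,
              fixation_dur_mean_ms = 279, fixation_dur_sd_ms = 140,
              saccade_gap_mean_ms = 172,
              step_px_mean = 275, step_px_sd = 140,
              outside_aoi_prob = 0.15,
              incorrect_multiplier = 1.68)
}

#' Default healthy-elderly preset (HE-like)
#'
#' Counterpart of [cohort_nph()]: fewer (~10), slightly shorter fixations,
#' shorter steps and a smaller incorrect-trial inflation.
#'
#' @param n_participants Number of participants (default 12).
#' @return A `cohort_spec`.
#' @export
cohort_he <- function(n_participants = 12L) {
  cohort_spec("HE", n_participants,
              fixation_count_mean = 9.94 / 0.90, fixation_count_sd = 2.08,
              fixation_dur_mean_ms = 265, fixation_dur_sd_ms = 130,
              saccade_gap_mean_ms = 186,
              step_px_mean = 232, step_px_sd = 120,
              outside_aoi_prob = 0.10,
              incorrect_multiplier = 1.60)
}

# mean/sd-parameterised lognormal draws truncated below at `lower`.
rlnorm_trunc <- function(n, mean, sd, lower) {
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  meanlog <- log(mean) - sdlog^2 / 2
  p0 <- stats::plnorm(lower, meanlog, sdlog)
  u <- stats::runif(n, p0, 1)
  stats::qlnorm(u, meanlog, sdlog)
}

# Normal draws truncated to [lower, upper] by inverse CDF.
rnorm_trunc <- function(n, mean, sd, lower, upper = Inf) {
  if (sd <= 0) return(pmin(pmax(rep(mean, n), lower), upper))
  p0 <- stats::pnorm(lower, mean, sd); p1 <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, p0, p1), mean, sd)
}

# Uniform draw in a disc of radius r.
runif_disc <- function(n, r) {
  th <- stats::runif(n, 0, 2 * pi)
  rr <- r * sqrt(stats::runif(n))
  cbind(rr * cos(th), rr * sin(th))
}

# Next walk position: step of fixed length from `from`, direction
# resampled until the target lies in [x0,x1]x[y0,y1]; clamped as a last
# resort (step lengths are capped well below the box diagonal, so the
# fallback is rare).
walk_step <- function(from, step, x0, x1, y0, y1) {
  for (i in 1:50) {
    th <- stats::runif(1, 0, 2 * pi)
    to <- from + step * c(cos(th), sin(th))
    if (to[1] >= x0 && to[1] <= x1 && to[2] >= y0 && to[2] <= y1) return(to)
  }
  c(min(max(from[1], x0), x1), min(max(from[2], y0), y1))
}

#' Simulate one trial's gaze-sample stream
#'
#' A renewal process of alternating fixation plateaus and saccadic gaps,
#' sampled on the regular grid implied by `geometry$sample_rate_hz`:
#' \itemize{
#'   \item plateau durations are lognormal (`fixation_dur_mean_ms` /
#'     `fixation_dur_sd_ms`), truncated below at `min_fixation_ms` and
#'     rounded to whole sample intervals, so classified spans are unbiased
#'     for the drawn durations;
#'   \item plateau centres follow a fixed-step-length random walk
#'     (truncated normal `step_px_mean` / `step_px_sd`) bounded inside the
#'     AOI, each centre being ejected outside the AOI with probability
#'     `outside_aoi_prob`;
#'   \item within a plateau every sample gets independent uniform-disc
#'     jitter of radius `jitter_px`, small enough that within-plateau
#'     velocities stay below half the classification threshold;
#'   \item gaps last `saccade_gap_mean_ms` on average; interior gap samples
#'     sweep far off the fixation axis so that every gap segment exceeds
#'     the velocity threshold and the generated event log is an exact
#'     classification oracle.
#' }
#' On incorrect trials the fixation count and duration parameters (means
#' and sds) are multiplied by `incorrect_multiplier`.
#'
#' The generated ground truth (one row per plateau: bounds, first-sample
#' coordinate, drawn duration and step, AOI flag) is attached as
#' `attr(result, "truth")`.
#'
#' @param spec A [cohort_spec()].
#' @param correct Logical: was the trial answered correctly?
#' @param geometry A [screen_geometry()].
#' @param aoi An [aoi_spec()].
#' @param min_fixation_ms,velocity_threshold_deg_s Classification
#'   parameters the stream is generated to respect.
#' @param n_fixations Optional fixed fixation count overriding the drawn
#'   one.
#' @return Tibble of samples `t_ms`, `x_px`, `y_px` with a `truth`
#'   attribute. Uses (and advances) the current RNG state; seed control
#'   belongs to the caller or to [simulate_study()].
#' @export
simulate_trial <- function(spec, correct, geometry = screen_geometry(),
                           aoi = aoi_spec(geometry = geometry),
                           min_fixation_ms = 70,
                           velocity_threshold_deg_s = 30,
                           n_fixations = NULL) {
  mult <- if (correct) 1 else spec$incorrect_multiplier
  dur_mean <- spec$fixation_dur_mean_ms * mult
  dur_sd <- spec$fixation_dur_sd_ms * mult
  if (dur_mean <= min_fixation_ms)
    stop("config error: fixation_dur_mean_ms (after any multiplier) must ",
         "exceed min_fixation_ms = ", min_fixation_ms, call. = FALSE)

  dt <- 1000 / geometry$sample_rate_hz
  r <- spec$jitter_px
  if (is.null(n_fixations)) {
    n_fix <- max(1L, as.integer(round(stats::rnorm(
      1, spec$fixation_count_mean * mult, spec$fixation_count_sd * mult))))
  } else n_fix <- as.integer(n_fixations)

  # walk box: AOI shrunk by the jitter radius so inside intent is realised
  m <- r + 1
  x0 <- aoi$x_min + m; x1 <- aoi$x_max - 1 - m
  y0 <- aoi$y_min + m; y1 <- aoi$y_max - 1 - m

  durs <- rlnorm_trunc(n_fix, dur_mean, dur_sd, min_fixation_ms)
  k_fix <- pmax(2L, as.integer(round(durs / dt)))
  step_cap <- min(600, (y1 - y0))
  steps <- if (n_fix > 1)
    rnorm_trunc(n_fix - 1L, spec$step_px_mean, spec$step_px_sd, 1, step_cap)
  else numeric()
  gaps <- if (n_fix > 1)
    rlnorm_trunc(n_fix - 1L, spec$saccade_gap_mean_ms,
                 0.3 * spec$saccade_gap_mean_ms, dt)
  else numeric()
  outside <- stats::runif(n_fix) < spec$outside_aoi_prob

  centers <- matrix(0, n_fix, 2)
  pos <- c(stats::runif(1, x0, x1), stats::runif(1, y0, y1))
  for (i in seq_len(n_fix)) {
    if (i > 1L) pos <- walk_step(pos, steps[i - 1L], x0, x1, y0, y1)
    if (outside[i]) {
      # excursion outside the AOI (on screen); walk resumes from it
      repeat {
        cand <- c(stats::runif(1, m, geometry$width_px - 1 - m),
                  stats::runif(1, m, geometry$height_px - 1 - m))
        if (!in_aoi(cand[1], cand[2], aoi) &&
            !(cand[1] >= aoi$x_min - m && cand[1] < aoi$x_max + m &&
              cand[2] >= aoi$y_min - m && cand[2] < aoi$y_max + m)) break
      }
      pos <- cand
    }
    centers[i, ] <- pos
  }

  ts <- xs <- ys <- vector("list", 2L * n_fix - 1L)
  truth_first <- matrix(0, n_fix, 2)
  t_cursor <- 0
  t_start <- t_end <- numeric(n_fix)
  for (i in seq_len(n_fix)) {
    npts <- k_fix[i] + 1L
    jit <- runif_disc(npts, r)
    tt <- t_cursor + dt * (0:(npts - 1L))
    ts[[2L * i - 1L]] <- tt
    xs[[2L * i - 1L]] <- centers[i, 1] + jit[, 1]
    ys[[2L * i - 1L]] <- centers[i, 2] + jit[, 2]
    truth_first[i, ] <- c(centers[i, 1] + jit[1, 1], centers[i, 2] + jit[1, 2])
    t_start[i] <- tt[1]; t_end[i] <- tt[npts]
    if (i < n_fix) {
      k_gap <- max(1L, as.integer(round(gaps[i] / dt)))
      a <- c(xs[[2L * i - 1L]][npts], ys[[2L * i - 1L]][npts])
      b <- centers[i + 1L, ]
      if (k_gap == 1L && sqrt(sum((b - a)^2)) < 120) k_gap <- 2L
      if (k_gap > 1L) {
        # interior gap samples detour far off the A-B axis so every
        # segment exceeds the velocity threshold
        mid <- (a + b) / 2
        u <- b - a; nu <- sqrt(sum(u^2))
        perp <- if (nu < 1e-9) c(0, 1) else c(-u[2], u[1]) / nu
        L <- 200 + nu / 2
        sgn <- rep_len(c(1, -1), k_gap - 1L)
        gx <- mid[1] + sgn * L * perp[1]
        gy <- mid[2] + sgn * L * perp[2]
        ts[[2L * i]] <- t_end[i] + dt * seq_len(k_gap - 1L)
        xs[[2L * i]] <- gx; ys[[2L * i]] <- gy
      } else {
        ts[[2L * i]] <- numeric(); xs[[2L * i]] <- numeric()
        ys[[2L * i]] <- numeric()
      }
      t_cursor <- t_end[i] + dt * k_gap
    }
  }

  samples <- tibble::tibble(t_ms = unlist(ts), x_px = unlist(xs),
                            y_px = unlist(ys))
  truth <- tibble::tibble(
    fix_index = seq_len(n_fix),
    t_start_ms = t_start, t_end_ms = t_end,
    x_px = truth_first[, 1], y_px = truth_first[, 2],
    center_x = centers[, 1], center_y = centers[, 2],
    drawn_dur_ms = durs,
    drawn_step_px = c(NA_real_, steps),
    inside_aoi = in_aoi(truth_first[, 1], truth_first[, 2], aoi)
  )
  attr(samples, "truth") <- truth
  samples
}

#' Simulate a full two-cohort naming study
#'
#' Generates every participant's trials for both cohorts with a single
#' seed, producing a gaze-sample table, a trial table, and the generator's
#' ground-truth event log. Participant heterogeneity follows a half/half
#' variance split: half of each cohort's count/duration variance is
#' between-participant (a lognormal multiplier on the participant's means)
#' and half within (the trial-level sd scaled by `1/sqrt(2)`).
#'
#' @param nph,he [cohort_spec()]s for the two cohorts.
#' @param n_trials_per_participant Trials per participant (default 30).
#' @param p_incorrect_by_group Named probabilities of an incorrect response
#'   per group; defaults solved from the published overall vs per-response
#'   fixation-count means.
#' @param seed Integer seed; the full study is reproducible from it.
#' @param geometry A [screen_geometry()].
#' @param aoi An [aoi_spec()].
#' @param items Item labels recycled across participants (default: the
#'   four canonical naming items plus generic fillers).
#' @return An object of class `simulated_study`: `$samples`, `$trials`,
#'   `$truth` (with `trial_id`), `$specs`, `$seed`.
#' @export
simulate_study <- function(nph = cohort_nph(), he = cohort_he(),
                           n_trials_per_participant = 30L,
                           p_incorrect_by_group = c(NPH = 0.425, HE = 0.192),
                           seed = 1L,
                           geometry = screen_geometry(),
                           aoi = aoi_spec(geometry = geometry),
                           items = default_items(n_trials_per_participant)) {
  stopifnot(n_trials_per_participant >= 1L,
            length(items) == n_trials_per_participant)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  all_samples <- list(); all_trials <- list(); all_truth <- list()
  for (spec in list(nph, he)) {
    p_inc <- p_incorrect_by_group[[spec$name]]
    for (p in seq_len(spec$n_participants)) {
      pid <- sprintf("%s%02d", spec$name, p)
      pspec <- participant_spec(spec)
      for (tr in seq_len(n_trials_per_participant)) {
        trial_id <- paste(pid, items[tr], sep = "_")
        correct <- stats::runif(1) >= p_inc
        s <- simulate_trial(pspec, correct, geometry, aoi)
        truth <- attr(s, "truth")
        s <- dplyr::mutate(s, trial_id = trial_id, .before = 1L)
        truth <- dplyr::mutate(truth, trial_id = trial_id, .before = 1L)
        all_samples[[trial_id]] <- s
        all_truth[[trial_id]] <- truth
        all_trials[[trial_id]] <- tibble::tibble(
          trial_id = trial_id, participant_id = pid, group = spec$name,
          item = items[tr], response_correct = as.integer(correct),
          error_type = NA_character_)
      }
    }
  }
  structure(list(samples = dplyr::bind_rows(all_samples),
                 trials = dplyr::bind_rows(all_trials),
                 truth = dplyr::bind_rows(all_truth),
                 specs = list(nph = nph, he = he),
                 p_incorrect_by_group = p_incorrect_by_group,
                 seed = as.integer(seed)),
            class = "simulated_study")
}

# Draw a participant-level spec: lognormal multipliers on the count and
# duration means carrying half the cohort variance; within-trial sds carry
# the other half.
participant_spec <- function(spec) {
  cv_c <- (spec$fixation_count_sd / sqrt(2)) / spec$fixation_count_mean
  cv_d <- (spec$fixation_dur_sd_ms / sqrt(2)) / spec$fixation_dur_mean_ms
  f_c <- stats::rlnorm(1, -cv_c^2 / 2, cv_c)
  f_d <- stats::rlnorm(1, -cv_d^2 / 2, cv_d)
  out <- spec
  out$fixation_count_mean <- spec$fixation_count_mean * f_c
  out$fixation_count_sd <- spec$fixation_count_sd / sqrt(2)
  out$fixation_dur_mean_ms <- spec$fixation_dur_mean_ms * f_d
  out$fixation_dur_sd_ms <- spec$fixation_dur_sd_ms / sqrt(2)
  out
}

#' Default item labels for the synthetic study
#'
#' The four canonical naming items first, then generic fillers; shared by
#' every participant so per-item pooling is meaningful.
#'
#' @param n Number of items.
#' @return Character vector of length `n`.
#' @export
default_items <- function(n) {
  base <- c("motorcycle", "eggplant", "xylophone", "escalator")
  if (n <= 4L) return(base[seq_len(n)])
  c(base, sprintf("item%02d", 5:n))
}

#' @export
print.simulated_study <- function(x, ...) {
  cat("<simulated_study> seed ", x$seed, ": ",
      length(unique(x$trials$participant_id)), " participants, ",
      nrow(x$trials), " trials, ", nrow(x$samples), " samples\n", sep = "")
  invisible(x)
}
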