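#' Typist profile for the synthetic keystroke generator
#'
#' Describes one synthetic typist. Hold times are log-normal around a
#' location (median) that wanders slowly within a session; key presses
#' follow a renewal process with occasional exponential pauses. Two
#' test-retest jitter terms model day-to-day variability of a subject's
#' median hold time and typing speed between sessions.
#'
#' @param base_median_ht Target median hold time in ms (default 100, the
#'   canonical magnitude for natural typing).
#' @param ht_dispersion Log-scale standard deviation of hold times
#'   (default 0.25).
#' @param typing_speed Target typing speed in keys/minute; must lie within
#'   `speed_band` (default band 100--300, bracketing observed natural-typing
#'   speeds of 126--281 characters/minute).
#' @param pause_rate Expected pauses per minute (default 2).
#' @param pause_scale Mean pause length in ms (default 2000).
#' @param drift_sd Standard deviation in ms of the per-minute step of the
#'   bounded random walk followed by the hold-time location within a session
#'   (default 5).
#' @param session_ht_jitter Log-scale sd of the per-session multiplicative
#'   jitter on the hold-time location (test-retest variability; default
#'   0.08).
#' @param session_speed_jitter Log-scale sd of the per-session jitter on
#'   typing speed (default 0.04).
#' @param seed Integer seed making the typist's sessions reproducible.
#' @param speed_band Permitted range for `typing_speed`.
#' @return Object of class `"typist_profile"`.
#' @export
typist_profile <- function(base_median_ht = 100, ht_dispersion = 0.25,
                           typing_speed = 200, pause_rate = 2,
                           pause_scale = 2000, drift_sd = 5,
                           session_ht_jitter = 0.08,
                           session_speed_jitter = 0.04,
                           seed = 1L, speed_band = c(100, 300)) {
  check_scalar(base_median_ht, "base_median_ht", positive = TRUE)
  check_scalar(ht_dispersion, "ht_dispersion", positive = TRUE)
  check_scalar(typing_speed, "typing_speed", positive = TRUE)
  check_scalar(pause_rate, "pause_rate", positive = TRUE)
  check_scalar(pause_scale, "pause_scale", positive = TRUE)
  check_scalar(drift_sd, "drift_sd", positive = TRUE)
  check_scalar(session_ht_jitter, "session_ht_jitter", nonneg = TRUE)
  check_scalar(session_speed_jitter, "session_speed_jitter", nonneg = TRUE)
  check_scalar(seed, "seed")
  if (typing_speed < speed_band[1L] || typing_speed > speed_band[2L])
    stop(sprintf("typing_speed %g outside the plausible band [%g, %g]",
                 typing_speed, speed_band[1L], speed_band[2L]), call. = FALSE)
  structure(
    list(base_median_ht = base_median_ht, ht_dispersion = ht_dispersion,
         typing_speed = typing_speed, pause_rate = pause_rate,
         pause_scale = pause_scale, drift_sd = drift_sd,
         session_ht_jitter = session_ht_jitter,
         session_speed_jitter = session_speed_jitter,
         seed = as.integer(seed)),
    class = "typist_profile"
  )
}

#' Impairment effect applied to a typist profile
#'
#' Parameterizes what psychomotor impairment does to typing: hold times get
#' longer (`ht_shift` multiplies the hold-time location), the hold-time
#' distribution becomes temporally unstable (`instability_gain` multiplies
#' the within-session drift), and typing slows down (`speed_factor`
#' multiplies the typing speed).
#'
#' @param ht_shift Multiplicative factor `>= 1` on the hold-time location
#'   (default 1.22).
#' @param instability_gain Factor `>= 1` on the within-session drift sd
#'   (default 2.5).
#' @param speed_factor Factor `<= 1` on typing speed (default 0.93).
#' @return Object of class `"impairment_effect"`.
#' @export
impairment_effect <- function(ht_shift = 1.22, instability_gain = 2.5,
                              speed_factor = 0.93) {
  check_scalar(ht_shift, "ht_shift", positive = TRUE)
  check_scalar(instability_gain, "instability_gain", positive = TRUE)
  check_scalar(speed_factor, "speed_factor", positive = TRUE)
  if (ht_shift < 1) stop("'ht_shift' must be >= 1", call. = FALSE)
  if (instability_gain < 1) stop("'instability_gain' must be >= 1",
                                 call. = FALSE)
  if (speed_factor > 1) stop("'speed_factor' must be <= 1", call. = FALSE)
  structure(list(ht_shift = ht_shift, instability_gain = instability_gain,
                 speed_factor = speed_factor),
            class = "impairment_effect")
}

# resample any immediate key repeats so a key is never pressed again while
# its previous hold could still be open
sample_keys <- function(n) {
  key <- sample(letters, n, replace = TRUE)
  repeat {
    bad <- which(key[-1L] == key[-n]) + 1L
    if (!length(bad)) break
    key[bad] <- sample(letters, length(bad), replace = TRUE)
  }
  key
}

#' Generate one synthetic typing session
#'
#' Emits a matched down/up event stream for one session. Inter-press gaps
#' follow a gamma renewal process calibrated so the realized typing speed
#' matches the profile target after accounting for occasional exponential
#' pauses. Hold times are log-normal around a location that follows a
#' bounded, mean-reverting random walk updated once per minute (the
#' within-session instability channel); under impairment the location is
#' multiplied by `ht_shift` and the walk step by `instability_gain`.
#' Rollover (a key released after the next key is pressed) arises naturally
#' because holds are attached to presses. Identical seeds give
#' byte-identical logs.
#'
#' @param profile A [typist_profile()].
#' @param effect An [impairment_effect()] or `NULL` for the rested state.
#' @param duration_ms Session length in ms (default 900000, a 15-minute
#'   session).
#' @param subject_id,repetition Session metadata.
#' @param state Session label; defaults to `"sleep_inertia"` when an effect
#'   is applied and `"rested"` otherwise.
#' @param seed Seed for this session (defaults to the profile seed).
#' @return A [keystroke_log()].
#' @export
generate_session <- function(profile, effect = NULL, duration_ms = 900000,
                             subject_id = "sim", repetition = 1L,
                             state = NULL, seed = profile$seed) {
  stopifnot(inherits(profile, "typist_profile"))
  if (!is.null(effect)) stopifnot(inherits(effect, "impairment_effect"))
  check_scalar(duration_ms, "duration_ms", positive = TRUE)
  if (is.null(state)) state <- if (is.null(effect)) "rested" else "sleep_inertia"

  hs <- if (is.null(effect)) 1 else effect$ht_shift
  gain <- if (is.null(effect)) 1 else effect$instability_gain
  sf <- if (is.null(effect)) 1 else effect$speed_factor

  ev <- withr::with_seed(as.integer(seed), {
    speed <- profile$typing_speed * sf *
      exp(stats::rnorm(1, 0, profile$session_speed_jitter))
    loc <- profile$base_median_ht * hs *
      exp(stats::rnorm(1, 0, profile$session_ht_jitter))
    step_sd <- profile$drift_sd * gain

    budget <- 60000 / speed                      # ms per key, pauses included
    p_pause <- min(profile$pause_rate / speed, 0.5)
    gap_mean <- budget - p_pause * profile$pause_scale
    if (gap_mean <= 0)
      stop("pause load incompatible with the requested typing speed",
           call. = FALSE)

    n_gen <- ceiling(duration_ms / budget * 1.3) + 50
    gaps <- stats::rgamma(n_gen, shape = 4, scale = gap_mean / 4)
    pauses <- stats::rbinom(n_gen, 1L, p_pause) *
      stats::rexp(n_gen, rate = 1 / profile$pause_scale)
    press <- cumsum(gaps + pauses)

    # per-minute bounded mean-reverting walk of the hold-time location
    phi <- 0.8
    stat_sd <- step_sd / sqrt(1 - phi^2)
    n_blocks <- ceiling(duration_ms / 60000)
    m <- numeric(n_blocks)
    m[1L] <- loc + stats::rnorm(1, 0, stat_sd)
    if (n_blocks > 1L)
      for (b in 2:n_blocks)
        m[b] <- loc + phi * (m[b - 1L] - loc) + stats::rnorm(1, 0, step_sd)
    m <- pmin(pmax(m, 0.5 * loc), 1.5 * loc)

    block <- pmin(floor(press / 60000) + 1L, n_blocks)
    ht <- m[block] * exp(stats::rnorm(n_gen, 0, profile$ht_dispersion))

    down <- round(press, 1)
    up <- round(press + ht, 1)
    keep <- up <= duration_ms & down > 0
    down <- down[keep]; up <- up[keep]
    n <- length(down)
    key <- sample_keys(n)
    data.frame(
      timestamp_ms = c(down, up),
      key_id = c(key, key),
      event_type = rep(c("down", "up"), each = n),
      stringsAsFactors = FALSE
    )
  })

  keystroke_log(ev, subject_id = subject_id, state = state,
                repetition = repetition, duration_ms = duration_ms)
}

#' Population ranges for a synthetic cohort
#'
#' Uniform sampling ranges from which per-subject [typist_profile()]s are
#' drawn. Defaults bracket natural-typing observations: speeds 126--281
#' keys/minute, median hold times near 100 ms.
#'
#' @param base_median_ht,ht_dispersion,typing_speed,pause_rate,pause_scale,drift_sd,session_ht_jitter,session_speed_jitter
#'   Length-2 numeric ranges (min, max).
#' @return A named list of ranges.
#' @export
cohort_population <- function(base_median_ht = c(90, 110),
                              ht_dispersion = c(0.20, 0.30),
                              typing_speed = c(126, 281),
                              pause_rate = c(1, 4),
                              pause_scale = c(1000, 4000),
                              drift_sd = c(3, 8),
                              session_ht_jitter = c(0.06, 0.10),
                              session_speed_jitter = c(0.03, 0.05)) {
  ranges <- list(base_median_ht = base_median_ht,
                 ht_dispersion = ht_dispersion,
                 typing_speed = typing_speed, pause_rate = pause_rate,
                 pause_scale = pause_scale, drift_sd = drift_sd,
                 session_ht_jitter = session_ht_jitter,
                 session_speed_jitter = session_speed_jitter)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (!is.numeric(r) || length(r) != 2L || r[1L] > r[2L])
      stop(sprintf("'%s' must be a (min, max) range", nm), call. = FALSE)
  }
  ranges
}

#' Generate a synthetic cohort
#'
#' Emulates the study design: `n_subjects` typists, each measured in two
#' states (rested and impaired) in each of two repetitions — four sessions
#' per subject. Each subject keeps one profile across sessions; repetitions
#' redraw the session-level jitters and noise (test-retest variability), and
#' impaired sessions apply the effect. All randomness derives from
#' `master_seed`.
#'
#' @param n_subjects Number of subjects (default 14).
#' @param effect An [impairment_effect()] applied in impaired sessions
#'   (pass `impairment_effect(1, 1, 1)` for a null effect).
#' @param master_seed Integer master seed.
#' @param population Sampling ranges from [cohort_population()].
#' @param duration_ms Session length in ms (default 900000).
#' @return Object of class `"khte_cohort"`: list with `logs` (list of
#'   [keystroke_log()]s, 4 per subject) and `manifest` (true profiles,
#'   effect, seeds — the ground truth for recovery tests).
#' @export
generate_cohort <- function(n_subjects = 14L, effect = impairment_effect(),
                            master_seed = 1L,
                            population = cohort_population(),
                            duration_ms = 900000) {
  check_scalar(n_subjects, "n_subjects", positive = TRUE)
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 2L) stop("'n_subjects' must be at least 2", call. = FALSE)
  stopifnot(inherits(effect, "impairment_effect"))

  setup <- withr::with_seed(as.integer(master_seed), {
    draw <- function(nm) stats::runif(n_subjects, population[[nm]][1L],
                                      population[[nm]][2L])
    profiles <- data.frame(
      subject = sprintf("S%02d", seq_len(n_subjects)),
      base_median_ht = draw("base_median_ht"),
      ht_dispersion = draw("ht_dispersion"),
      typing_speed = draw("typing_speed"),
      pause_rate = draw("pause_rate"),
      pause_scale = draw("pause_scale"),
      drift_sd = draw("drift_sd"),
      session_ht_jitter = draw("session_ht_jitter"),
      session_speed_jitter = draw("session_speed_jitter"),
      stringsAsFactors = FALSE
    )
    seeds <- sample.int(.Machine$integer.max, 4L * n_subjects)
    list(profiles = profiles, seeds = seeds)
  })

  logs <- vector("list", 4L * n_subjects)
  nm <- character(4L * n_subjects)
  i <- 0L
  for (s in seq_len(n_subjects)) {
    p <- setup$profiles[s, ]
    prof <- typist_profile(p$base_median_ht, p$ht_dispersion, p$typing_speed,
                           p$pause_rate, p$pause_scale, p$drift_sd,
                           p$session_ht_jitter, p$session_speed_jitter,
                           seed = 1L)
    for (rep_idx in 1:2) for (st in c("rested", "sleep_inertia")) {
      i <- i + 1L
      eff <- if (st == "sleep_inertia") effect else NULL
      logs[[i]] <- generate_session(prof, eff, duration_ms = duration_ms,
                                    subject_id = p$subject,
                                    repetition = rep_idx, state = st,
                                    seed = setup$seeds[i])
      nm[i] <- sprintf("%s_%s_r%d", p$subject, st, rep_idx)
    }
  }
  names(logs) <- nm
  structure(
    list(logs = logs,
         manifest = list(profiles = setup$profiles, effect = unclass(effect),
                         master_seed = as.integer(master_seed),
                         duration_ms = duration_ms)),
    class = "khte_cohort"
  )
}

#' @export
print.khte_cohort <- function(x, ...) {
  n <- nrow(x$manifest$profiles)
  cat(sprintf("Synthetic cohort: %d subjects, %d sessions (%.0f min each)\n",
              n, length(x$logs), x$manifest$duration_ms / 60000))
  e <- x$manifest$effect
  cat(sprintf("  impairment effect: ht_shift %.2f, instability_gain %.2f, speed_factor %.2f\n",
              e$ht_shift, e$instability_gain, e$speed_factor))
  invisible(x)
}

#' Write a cohort to a directory of log files
#'
#' One log file per session plus `manifest.json` holding the true profiles
#' and effect (the generator's ground truth).
#'
#' @param cohort A `"khte_cohort"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "khte_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(cohort$logs))
    write_keystroke_log(cohort$logs[[nm]], file.path(dir, paste0(nm, ".csv")))
  jsonlite::write_json(cohort$manifest, file.path(dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, dataframe = "rows")
  invisible(dir)
}
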