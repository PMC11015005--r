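#' Activity specification for the synthetic cohort generator
#'
#' Each activity is a narrow-band oscillation of a given base frequency and
#' amplitude under an amplitude envelope, expressed in a body frame whose
#' gravity direction is the activity's orientation, plus white Gaussian
#' noise. Envelopes: `constant` (steady oscillation), `sawtooth`
#' (time-asymmetric ramp-up/sharp-drop cycles, which makes time reversal
#' detectable), `burst` (on/off gating).
#'
#' @param name activity name.
#' @param base_frequency oscillation frequency in Hz (0 for postures;
#'   must stay below the 15 Hz Nyquist limit at 30 Hz).
#' @param amplitude oscillation amplitude in g (>= 0).
#' @param envelope one of `"constant"`, `"sawtooth"`, `"burst"`.
#' @param orientation unit 3-vector: gravity direction in the body frame.
#' @param noise_sd white-noise standard deviation in g.
#' @param mean_bout_length mean bout duration in seconds.
#' @return A list of class `harssl_activity_spec`.
#' @export
activity_spec <- function(name, base_frequency, amplitude,
                          envelope = c("constant", "sawtooth", "burst"),
                          orientation = c(0, 0, 1), noise_sd = 0.02,
                          mean_bout_length = 60) {
  if (base_frequency < 0 || base_frequency >= 15)
    stop_param("base_frequency must be in [0, 15) Hz (Nyquist at 30 Hz)")
  if (amplitude < 0) stop_param("amplitude must be >= 0")
  if (abs(sqrt(sum(orientation^2)) - 1) > 1e-6)
    stop_param("orientation must be a unit vector")
  if (noise_sd < 0) stop_param("noise_sd must be >= 0")
  if (mean_bout_length <= 0) stop_param("mean_bout_length must be > 0")
  structure(list(name = as.character(name),
                 base_frequency = base_frequency,
                 amplitude = amplitude,
                 envelope = match.arg(envelope),
                 orientation = orientation / sqrt(sum(orientation^2)),
                 noise_sd = noise_sd,
                 mean_bout_length = mean_bout_length),
            class = "harssl_activity_spec")
}

#' Default synthetic activity catalogue
#'
#' Four activities spanning intensity, spectral content and posture:
#' a walk-like 1 Hz bout under a sawtooth envelope (time-asymmetric, so the
#' arrow-of-time task is learnable), a run-like 3 Hz steady bout (narrow-band,
#' so time warping is learnable; the envelope contrast also makes bouts
#' non-stationary for the permutation task), and two near-still postures
#' (sit, stand) distinguished from each other and from between-bout
#' stillness by orientation. The two periodic activities differ in base
#' frequency by 2 Hz, keeping the downstream 4-class problem separable.
#'
#' @return List of `harssl_activity_spec`.
#' @export
default_catalogue <- function() {
  list(
    activity_spec("walk", base_frequency = 1, amplitude = 0.35,
                  envelope = "sawtooth", orientation = c(0, 0, 1),
                  noise_sd = 0.03, mean_bout_length = 90),
    activity_spec("run", base_frequency = 3, amplitude = 0.8,
                  envelope = "constant", orientation = c(0, 0, 1),
                  noise_sd = 0.05, mean_bout_length = 60),
    activity_spec("sit", base_frequency = 0, amplitude = 0,
                  envelope = "constant", orientation = c(1, 0, 0),
                  noise_sd = 0.03, mean_bout_length = 120),
    activity_spec("stand", base_frequency = 0, amplitude = 0,
                  envelope = "constant",
                  orientation = c(1, 1, 1) / sqrt(3),
                  noise_sd = 0.04, mean_bout_length = 90))
}

# Envelope value over bout time (seconds); sawtooth ramps up over each
# 2-second cycle and drops sharply (time-asymmetric), burst gates 1 s on/off.
#' @noRd
envelope_value <- function(kind, t) {
  switch(kind,
         constant = rep(1, length(t)),
         sawtooth = (t %% 2) / 2,
         burst = as.numeric((t %% 2) < 1))
}

# Unit vector orthogonal to v.
#' @noRd
orthogonal_unit <- function(v) {
  ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * v) * v
  u / sqrt(sum(u^2))
}

#' Generate one pure activity bout
#'
#' `amplitude * envelope(t) * sin(2 pi f t + phase)` along a movement
#' direction with a fixed vertical (gravity-parallel) component — as in gait,
#' where impact acceleration is dominantly vertical — and a horizontal
#' component rotated about the orientation axis by `rotation`; plus the 1 g
#' gravity offset along the orientation, plus white noise. The vertical
#' component puts the oscillation's fundamental frequency (not only its
#' second harmonic) into the magnitude spectrum.
#'
#' @param spec a `harssl_activity_spec`.
#' @param duration bout duration in seconds.
#' @param rate sampling rate in Hz (default 30).
#' @param phase oscillation phase (default random).
#' @param rotation body-frame rotation angle about the orientation axis
#'   (default random).
#' @return Numeric `duration * rate` x 3 matrix (g).
#' @export
activity_bout_signal <- function(spec, duration, rate = 30,
                                 phase = stats::runif(1, 0, 2 * pi),
                                 rotation = stats::runif(1, 0, 2 * pi)) {
  n <- max(1L, as.integer(round(duration * rate)))
  t <- (seq_len(n) - 1L) / rate
  osc <- spec$amplitude * envelope_value(spec$envelope, t) *
    sin(2 * pi * spec$base_frequency * t + phase)
  horiz <- rotation_matrix(spec$orientation, rotation) %*%
    orthogonal_unit(spec$orientation)
  dir <- 0.6 * spec$orientation + 0.8 * as.vector(horiz)
  sig <- outer(osc, as.vector(dir)) +
    matrix(spec$orientation, n, 3, byrow = TRUE)
  sig + matrix(stats::rnorm(n * 3L, 0, spec$noise_sd), n, 3L)
}

#' Simulation configuration
#'
#' The generator emulates the free-living structure the sampler and pretext
#' tasks exist for: multi-day per-subject recordings in which long
#' near-stationary periods (gravity plus small noise) alternate with activity
#' bouts under a semi-Markov model with exponential durations. Stationary
#' segment mean duration is set from `stationary_fraction` so that the
#' expected fraction of recording time that is stationary equals it.
#' Synthetic "days" default to one hour: free-living statistical structure at
#' a tractable desk scale.
#'
#' @param n_subjects number of subjects.
#' @param days_per_subject days per subject (default 1).
#' @param rate sampling rate in Hz (default 30).
#' @param catalogue list of `harssl_activity_spec`
#'   (default [default_catalogue()]).
#' @param stationary_fraction expected fraction of time stationary, in
#'   `[0, 1)` (default 0.7).
#' @param day_seconds seconds per synthetic day (default 3600).
#' @param stationary_noise_sd noise during stationary segments in g
#'   (default 0.002: a still wrist shows the gravity offset plus sensor
#'   noise).
#' @param seed RNG seed.
#' @return A list of class `harssl_sim_config`.
#' @export
sim_config <- function(n_subjects, days_per_subject = 1L, rate = 30,
                       catalogue = default_catalogue(),
                       stationary_fraction = 0.7, day_seconds = 3600,
                       stationary_noise_sd = 0.002, seed = 1L) {
  if (!is_count(n_subjects)) stop_param("n_subjects must be >= 1")
  if (length(catalogue) == 0L) stop_param("catalogue must be non-empty")
  if (stationary_fraction < 0 || stationary_fraction >= 1)
    stop_param("stationary_fraction must be in [0, 1)")
  structure(list(n_subjects = as.integer(n_subjects),
                 days_per_subject = as.integer(days_per_subject),
                 rate = rate, catalogue = catalogue,
                 stationary_fraction = stationary_fraction,
                 day_seconds = day_seconds,
                 stationary_noise_sd = stationary_noise_sd,
                 seed = as.integer(seed)),
            class = "harssl_sim_config")
}

#' @noRd
simulate_day <- function(cfg) {
  n <- as.integer(round(cfg$day_seconds * cfg$rate))
  acc <- matrix(0, n, 3L)
  labels <- character(n)
  mean_bout <- mean(vapply(cfg$catalogue,
                           function(s) s$mean_bout_length, numeric(1)))
  f <- cfg$stationary_fraction
  mean_still <- if (f > 0) mean_bout * f / (1 - f) else 0
  grav <- c(0, 0, 1)
  at <- 1L
  stationary <- TRUE
  while (at <= n) {
    if (stationary && mean_still > 0) {
      len <- min(n - at + 1L,
                 max(1L, as.integer(round(stats::rexp(1, 1 / mean_still) *
                                          cfg$rate))))
      seg <- matrix(grav, len, 3L, byrow = TRUE) +
        matrix(stats::rnorm(len * 3L, 0, cfg$stationary_noise_sd), len, 3L)
      acc[at:(at + len - 1L), ] <- seg
      labels[at:(at + len - 1L)] <- "stationary"
      at <- at + len
    }
    stationary <- FALSE
    if (at > n) break
    spec <- cfg$catalogue[[sample.int(length(cfg$catalogue), 1L)]]
    dur <- max(10, stats::rexp(1, 1 / spec$mean_bout_length))
    len <- min(n - at + 1L, as.integer(round(dur * cfg$rate)))
    if (len >= 1L) {
      bout <- activity_bout_signal(spec, len / cfg$rate, cfg$rate)
      acc[at:(at + len - 1L), ] <- bout[seq_len(len), , drop = FALSE]
      labels[at:(at + len - 1L)] <- spec$name
      at <- at + len
    }
    stationary <- TRUE
    if (mean_still == 0) stationary <- FALSE
  }
  list(acc = acc, labels = labels)
}

#' Simulate a free-living cohort
#'
#' Per subject and day, alternates stationary segments (gravity orientation
#' plus small noise) with activity bouts drawn uniformly from the catalogue,
#' with exponential segment durations (semi-Markov). The label stream tracks
#' the active activity name or `"stationary"`. Fully reproducible under the
#' configured seed.
#'
#' @param cfg a `harssl_sim_config`.
#' @return List of labelled `harssl_recording`, one per subject (days are
#'   concatenated; [windows_by_day()] with `day_seconds = cfg$day_seconds`
#'   recovers the day structure).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "harssl_sim_config"))
  set.seed(cfg$seed)
  lapply(seq_len(cfg$n_subjects), function(s) {
    days <- lapply(seq_len(cfg$days_per_subject),
                   function(d) simulate_day(cfg))
    acc <- do.call(rbind, lapply(days, `[[`, "acc"))
    labels <- unlist(lapply(days, `[[`, "labels"))
    new_recording(acc, cfg$rate, sprintf("subj%03d", s),
                  label_stream = labels)
  })
}

#' All labelled windows of a cohort as one batch
#'
#' Non-overlapping windows of every subject, concatenated; the standard way
#' to build a labelled downstream benchmark from a simulated cohort.
#'
#' @param cohort list of labelled `harssl_recording`.
#' @param duration window duration in seconds (default 10).
#' @return A labelled `harssl_window_batch`.
#' @export
cohort_windows <- function(cohort, duration = 10) {
  bind_batches(lapply(cohort, make_windows, duration = duration))
}

#' Write a cohort to per-subject CSV files with a manifest
#'
#' @param cohort list of `harssl_recording`.
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- vapply(cohort, function(rec) {
    path <- file.path(dir, paste0(rec$subject_id, ".csv"))
    df <- data.frame(time = (seq_len(nrow(rec$acc)) - 1L) / rec$rate,
                     x = rec$acc[, 1], y = rec$acc[, 2], z = rec$acc[, 3])
    if (!is.null(rec$label_stream)) df$label <- rec$label_stream
    utils::write.csv(df, path, row.names = FALSE)
    path
  }, character(1))
  manifest <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(list(
    n_subjects = length(cohort),
    rate = cohort[[1]]$rate,
    files = as.list(basename(files))), manifest)
  invisible(manifest)
}
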