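#' Sampler configuration for pre-training batch assembly
#'
#' One pre-training batch loads up to `subjects_per_batch` subjects, draws one
#' day per subject, and samples `windows_per_subject` windows within that day
#' in proportion to their movement weight (defaults give the 4 x 1500 = 6000
#' window batch). When every weight in a day falls at or below `weight_floor`
#' the sampler falls back to uniform draws.
#'
#' @param subjects_per_batch subjects per batch (default 4).
#' @param windows_per_subject windows sampled per subject (default 1500).
#' @param weight_floor weights at or below this (in g) count as zero movement
#'   (default 1e-4).
#' @param weight_mode `"axis_mean"` (mean of per-axis standard deviations,
#'   default) or `"magnitude_std"` (standard deviation of the vector
#'   magnitude).
#' @return A list of class `harssl_sampler_config`.
#' @export
sampler_config <- function(subjects_per_batch = 4L,
                           windows_per_subject = 1500L,
                           weight_floor = 1e-4,
                           weight_mode = c("axis_mean", "magnitude_std")) {
  if (!is_count(subjects_per_batch)) stop_param("subjects_per_batch must be >= 1")
  if (!is_count(windows_per_subject)) stop_param("windows_per_subject must be >= 1")
  if (weight_floor < 0) stop_param("weight_floor must be >= 0")
  structure(list(subjects_per_batch = as.integer(subjects_per_batch),
                 windows_per_subject = as.integer(windows_per_subject),
                 weight_floor = weight_floor,
                 weight_mode = match.arg(weight_mode)),
            class = "harssl_sampler_config")
}

#' Movement weight of a window
#'
#' Free-living data is dominated by low-movement periods that are nearly
#' unchanged by the pretext transformations, so training windows are sampled
#' in proportion to their standard deviation. The default weight is the mean
#' of the three per-axis sample standard deviations (invariant to axis
#' permutation, matching the orientation augmentations); the alternative is
#' the standard deviation of the vector magnitude.
#'
#' @param w numeric L x 3 window (g).
#' @param mode `"axis_mean"` or `"magnitude_std"`.
#' @return Non-negative scalar weight (g).
#' @export
window_weight <- function(w, mode = c("axis_mean", "magnitude_std")) {
  mode <- match.arg(mode)
  if (mode == "axis_mean") {
    mean(apply(w, 2, stats::sd))
  } else {
    stats::sd(sqrt(rowSums(w^2)))
  }
}

#' Movement weights for every window of a batch
#' @param batch a `harssl_window_batch`.
#' @param mode see [window_weight()].
#' @return Numeric vector of length `n_windows(batch)`.
#' @export
batch_weights <- function(batch, mode = c("axis_mean", "magnitude_std")) {
  mode <- match.arg(mode)
  win <- batch$windows
  B <- dim(win)[1L]
  L <- dim(win)[2L]
  if (B == 0L) return(numeric(0))
  if (mode == "axis_mean") {
    # vectorised mean of per-axis sample standard deviations
    w <- numeric(B)
    for (a in 1:3) {
      Wa <- win[, , a, drop = FALSE]
      dim(Wa) <- c(B, L)
      m <- rowMeans(Wa)
      ss <- rowSums(Wa * Wa) - L * m * m
      w <- w + sqrt(pmax(ss, 0) / (L - 1))
    }
    w / 3
  } else {
    vm <- sqrt(win[, , 1]^2 + win[, , 2]^2 + win[, , 3]^2)
    dim(vm) <- c(B, L)
    m <- rowMeans(vm)
    ss <- rowSums(vm * vm) - L * m * m
    sqrt(pmax(ss, 0) / (L - 1))
  }
}

#' Draw window indices with probability proportional to weight
#'
#' Indices are drawn proportionally to `max(weight, 0)`; when every weight is
#' at or below `weight_floor` the draw falls back to uniform (with a
#' `harssl_uniform_fallback` condition signalled so callers can log it).
#'
#' @param weights non-negative numeric vector.
#' @param n number of draws.
#' @param replace sample with replacement (default TRUE).
#' @param weight_floor fallback threshold (default 1e-4).
#' @return Integer vector of `n` indices into `weights`.
#' @export
weighted_sample <- function(weights, n, replace = TRUE, weight_floor = 1e-4) {
  if (any(weights < 0)) stop_param("weights must be non-negative")
  if (!is_count(n)) stop_param("n must be a positive integer")
  if (all(weights <= weight_floor)) {
    signalCondition(structure(
      class = c("harssl_uniform_fallback", "condition"),
      list(message = "all weights at or below floor; uniform fallback",
           call = NULL)))
    return(sample.int(length(weights), n, replace = replace))
  }
  w <- pmax(weights, 0)
  if (!replace && n > sum(w > weight_floor)) {
    signalCondition(structure(
      class = c("harssl_uniform_fallback", "condition"),
      list(message = "too few positive-weight windows; uniform fallback",
           call = NULL)))
    return(sample.int(length(weights), n, replace = FALSE))
  }
  sample.int(length(weights), n, replace = replace, prob = w)
}

#' Assemble one movement-weighted pre-training batch
#'
#' Draws up to `subjects_per_batch` subjects without replacement, one calendar
#' day uniformly per subject, then `windows_per_subject` windows within that
#' day by weighted sampling with replacement, and concatenates the result.
#' Windows are never mixed across days within one subject's contribution.
#'
#' @param pool a named list: per subject, a list of `harssl_window_batch`
#'   objects, one per calendar day (as produced by [windows_by_day()] or
#'   [cohort_to_pool()]).
#' @param cfg a `harssl_sampler_config`.
#' @return A `harssl_window_batch` with
#'   `subjects_per_batch * windows_per_subject` windows (fewer subjects if
#'   the pool is smaller).
#' @export
assemble_batch <- function(pool, cfg = sampler_config()) {
  if (length(pool) == 0L) stop_data("empty subject pool")
  k <- min(cfg$subjects_per_batch, length(pool))
  subjects <- sample(names(pool), k)
  parts <- lapply(subjects, function(sid) {
    days <- pool[[sid]]
    day <- days[[sample.int(length(days), 1L)]]
    w <- attr(day, paste0("weights_", cfg$weight_mode)) %||%
      batch_weights(day, cfg$weight_mode)
    idx <- weighted_sample(w, cfg$windows_per_subject, replace = TRUE,
                           weight_floor = cfg$weight_floor)
    subset_batch(day, idx)
  })
  bind_batches(parts)
}

#' Partition a labelled Recording into per-day window batches
#'
#' Splits a recording into consecutive 24-hour segments (by sample count at
#' the recording's rate) and windows each day separately, so the batch
#' sampler can draw one day at a time.
#'
#' @param rec a `harssl_recording`.
#' @param duration window duration in seconds (default 10).
#' @param day_seconds length of a "day" in seconds (default 86400; tests and
#'   toy cohorts may use shorter synthetic days).
#' @return A list of `harssl_window_batch`, one per (possibly partial) day.
#' @export
windows_by_day <- function(rec, duration = 10, day_seconds = 86400) {
  n <- nrow(rec$acc)
  per_day <- as.integer(round(day_seconds * rec$rate))
  starts <- seq(1L, n, by = per_day)
  out <- list()
  for (s in starts) {
    e <- min(s + per_day - 1L, n)
    sub <- new_recording(rec$acc[s:e, , drop = FALSE], rec$rate,
                         rec$subject_id,
                         label_stream = if (is.null(rec$label_stream)) NULL
                                        else rec$label_stream[s:e])
    wb <- make_windows(sub, duration = duration)
    if (n_windows(wb) > 0L) {
      # cache sampling weights so repeated batch assembly is cheap
      attr(wb, "weights_axis_mean") <- batch_weights(wb, "axis_mean")
      out[[length(out) + 1L]] <- wb
    }
  }
  out
}

#' Convert a cohort of Recordings into a sampler pool
#' @param cohort list of `harssl_recording`.
#' @param duration window duration in seconds (default 10).
#' @param day_seconds synthetic day length in seconds (default 86400).
#' @return Named list (by subject id) of per-day window batch lists.
#' @export
cohort_to_pool <- function(cohort, duration = 10, day_seconds = 86400) {
  pool <- lapply(cohort, windows_by_day, duration = duration,
                 day_seconds = day_seconds)
  names(pool) <- vapply(cohort, function(r) r$subject_id, character(1))
  pool
}
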