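#' Recording: one subject's continuous tri-axial acceleration trace
#'
#' A `Recording` holds a uniformly sampled tri-axial acceleration signal in
#' gravitational units (g), the sampling rate, and an optional per-sample
#' activity label stream. Gravity is not removed: a device lying still shows a
#' constant ~1 g offset along one axis, so stationary periods have small
#' standard deviation, not small mean.
#'
#' @param acc numeric N x 3 matrix of acceleration (g), columns x, y, z.
#' @param rate sampling rate in samples/second (> 0).
#' @param subject_id subject identifier string.
#' @param start_time optional timestamp of the first sample.
#' @param label_stream optional character vector of per-sample activity
#'   labels, length N.
#' @return An object of class `harssl_recording`.
#' @export
new_recording <- function(acc, rate, subject_id, start_time = NULL,
                          label_stream = NULL) {
  acc <- as.matrix(acc)
  if (ncol(acc) != 3L) stop_format("acc must have exactly 3 channels")
  if (anyNA(acc)) stop_format("acc must not contain missing values")
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop_param("rate must be a single positive number")
  if (!is.null(label_stream) && length(label_stream) != nrow(acc))
    stop_format(sprintf("label_stream has %d entries but acc has %d samples",
                        length(label_stream), nrow(acc)))
  structure(list(subject_id = as.character(subject_id),
                 start_time = start_time,
                 rate = as.numeric(rate),
                 acc = unname(acc),
                 label_stream = label_stream),
            class = "harssl_recording")
}

#' @export
print.harssl_recording <- function(x, ...) {
  cat(sprintf("<Recording> subject %s: %d samples @ %g Hz (%.1f s)%s\n",
              x$subject_id, nrow(x$acc), x$rate, nrow(x$acc) / x$rate,
              if (is.null(x$label_stream)) "" else ", labelled"))
  invisible(x)
}

#' Read a tri-axial accelerometer CSV into a Recording
#'
#' Expects header columns `time,x,y,z` (optionally `label`); acceleration in
#' g; time either seconds-as-float or ISO-8601. The sampling rate is inferred
#' as the reciprocal of the median inter-sample interval. Rows with any
#' non-numeric acceleration value are dropped and counted in the attached
#' load report (`attr(rec, "load_report")`).
#'
#' @param path CSV file path.
#' @param subject_id subject identifier to attach.
#' @return A `harssl_recording` with attribute `load_report`
#'   (list with `n_read`, `dropped`).
#' @export
read_csv_recording <- function(path, subject_id) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop_format(paste0("missing required columns: ", paste(miss, collapse = ", ")))
  tm <- df$time
  if (is.character(tm)) {
    tnum <- suppressWarnings(as.numeric(tm))
    if (anyNA(tnum)) {
      tp <- as.POSIXct(tm, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
      if (anyNA(tp)) tp <- as.POSIXct(tm, tz = "UTC")
      if (anyNA(tp)) stop_format("time column is neither numeric nor ISO-8601")
      tnum <- as.numeric(tp)
    }
    tm <- tnum
  }
  if (length(tm) < 2L) stop_insufficient("need at least 2 rows")
  dt <- diff(tm)
  if (any(dt < 0)) {
    stop_format(sprintf("time column is non-monotone at row %d",
                        which(dt < 0)[1L] + 1L))
  }
  acc <- suppressWarnings(cbind(as.numeric(df$x), as.numeric(df$y),
                                as.numeric(df$z)))
  keep <- stats::complete.cases(acc)
  dropped <- sum(!keep)
  acc <- acc[keep, , drop = FALSE]
  tm_kept <- tm[keep]
  if (nrow(acc) < 2L) stop_insufficient("fewer than 2 usable rows after dropping")
  rate <- 1 / stats::median(diff(tm_kept))
  labels <- if ("label" %in% names(df)) as.character(df$label)[keep] else NULL
  rec <- new_recording(acc, rate, subject_id,
                       start_time = tm_kept[1L], label_stream = labels)
  attr(rec, "load_report") <- list(n_read = length(keep), dropped = dropped)
  rec
}

#' Linearly resample a Recording onto a uniform grid
#'
#' Per-axis linear interpolation onto a uniform grid at `target_rate`,
#' spanning the closed interval from the first to the last sample time of the
#' source (grid points `t0 + i/target_rate`, `i = 0, 1, ...`, while they do
#' not exceed the last sample time). Label streams are resampled by nearest
#' neighbour. The pipeline default of 30 Hz sits above the ~20 Hz Nyquist
#' rate of human movement.
#'
#' @param rec a `harssl_recording`.
#' @param target_rate target sampling rate (samples/second).
#' @return A resampled `harssl_recording` with `rate = target_rate`.
#' @export
resample_linear <- function(rec, target_rate = 30) {
  stopifnot(inherits(rec, "harssl_recording"))
  if (!is.numeric(target_rate) || target_rate <= 0)
    stop_param("target_rate must be positive")
  n <- nrow(rec$acc)
  if (n < 2L) stop_insufficient("need at least 2 samples to resample")
  t_src <- (seq_len(n) - 1L) / rec$rate
  span <- t_src[n]
  t_new <- seq(0, by = 1 / target_rate,
               length.out = floor(span * target_rate + 1e-9) + 1L)
  acc <- vapply(1:3, function(a) {
    stats::approx(t_src, rec$acc[, a], xout = t_new)$y
  }, numeric(length(t_new)))
  labels <- NULL
  if (!is.null(rec$label_stream)) {
    idx <- pmin(pmax(round(t_new * rec$rate) + 1L, 1L), n)
    labels <- rec$label_stream[idx]
  }
  new_recording(acc, target_rate, rec$subject_id,
                start_time = rec$start_time, label_stream = labels)
}

#' WindowBatch: a fixed-shape stack of signal windows
#'
#' @param windows numeric B x L x 3 array (g units).
#' @param subject_ids character vector of length B.
#' @param rate sampling rate of the windows (Hz).
#' @param duration window duration (seconds); `L = round(rate * duration)`.
#' @param labels optional character vector of length B.
#' @return An object of class `harssl_window_batch`.
#' @export
new_window_batch <- function(windows, subject_ids, rate, duration,
                             labels = NULL) {
  d <- dim(windows)
  if (length(d) != 3L || d[3L] != 3L)
    stop_shape("windows must be a B x L x 3 array")
  L <- round(rate * duration)
  if (d[2L] != L)
    stop_shape(sprintf("window length %d != round(rate * duration) = %d",
                       d[2L], L))
  if (length(subject_ids) != d[1L])
    stop_shape("one subject id per window required")
  if (!is.null(labels) && length(labels) != d[1L])
    stop_shape("one label per window required")
  structure(list(windows = windows,
                 subject_ids = as.character(subject_ids),
                 labels = if (is.null(labels)) NULL else as.character(labels),
                 rate = as.numeric(rate),
                 duration = as.numeric(duration)),
            class = "harssl_window_batch")
}

#' @export
print.harssl_window_batch <- function(x, ...) {
  cat(sprintf("<WindowBatch> %d windows of %g s @ %g Hz (%d samples), %d subject(s)%s\n",
              dim(x$windows)[1L], x$duration, x$rate, dim(x$windows)[2L],
              length(unique(x$subject_ids)),
              if (is.null(x$labels)) "" else
                sprintf(", %d classes", length(unique(x$labels)))))
  invisible(x)
}

#' Number of windows in a WindowBatch
#' @param batch a `harssl_window_batch`.
#' @return integer count.
#' @export
n_windows <- function(batch) dim(batch$windows)[1L]

#' Split a Recording into fixed-duration windows
#'
#' Consecutive windows of `L = round(rate * duration)` samples with hop
#' `L * (1 - overlap_fraction)`; the trailing partial window is discarded.
#' If the recording is labelled, each window receives its modal per-sample
#' label (ties broken by first-seen order within the window). Windows are
#' non-overlapping by default, treating each as an independent input.
#'
#' @param rec a `harssl_recording` (already at the pipeline rate).
#' @param duration window duration in seconds (default 10).
#' @param overlap_fraction fraction of overlap between consecutive windows,
#'   in `[0, 1)` (default 0).
#' @return A `harssl_window_batch` (possibly with 0 windows).
#' @export
make_windows <- function(rec, duration = 10, overlap_fraction = 0) {
  stopifnot(inherits(rec, "harssl_recording"))
  if (!is.numeric(duration) || duration <= 0)
    stop_param("duration must be positive")
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop_param("overlap_fraction must be in [0, 1)")
  L <- round(rec$rate * duration)
  hop <- max(1L, as.integer(round(L * (1 - overlap_fraction))))
  n <- nrow(rec$acc)
  nb <- if (n >= L) 1L + (n - L) %/% hop else 0L
  win <- array(0, dim = c(nb, L, 3L))
  labels <- if (!is.null(rec$label_stream) && nb > 0L) character(nb) else NULL
  for (b in seq_len(nb)) {
    i0 <- (b - 1L) * hop + 1L
    win[b, , ] <- rec$acc[i0:(i0 + L - 1L), ]
    if (!is.null(labels)) {
      lw <- rec$label_stream[i0:(i0 + L - 1L)]
      # modal label, first-seen order breaks ties
      cnt <- table(factor(lw, levels = unique(lw)))
      labels[b] <- names(cnt)[which.max(cnt)]
    }
  }
  new_window_batch(win, rep(rec$subject_id, nb), rec$rate, duration,
                   labels = labels)
}

#' Combine several WindowBatch objects
#' @param ... `harssl_window_batch` objects sharing rate and duration.
#' @return A single concatenated `harssl_window_batch`.
#' @export
bind_batches <- function(...) {
  bs <- list(...)
  if (length(bs) == 1L && is.list(bs[[1L]]) &&
      !inherits(bs[[1L]], "harssl_window_batch")) bs <- bs[[1L]]
  stopifnot(all(vapply(bs, inherits, TRUE, "harssl_window_batch")))
  rate <- bs[[1L]]$rate; dur <- bs[[1L]]$duration
  if (!all(vapply(bs, function(b) b$rate == rate && b$duration == dur, TRUE)))
    stop_param("batches differ in rate or duration")
  L <- dim(bs[[1L]]$windows)[2L]
  ntot <- sum(vapply(bs, n_windows, 1L))
  win <- array(0, dim = c(ntot, L, 3L))
  sid <- character(ntot)
  has_lab <- all(vapply(bs, function(b) !is.null(b$labels), TRUE))
  lab <- if (has_lab) character(ntot) else NULL
  at <- 0L
  for (b in bs) {
    nb <- n_windows(b)
    if (nb > 0L) {
      win[at + seq_len(nb), , ] <- b$windows
      sid[at + seq_len(nb)] <- b$subject_ids
      if (has_lab) lab[at + seq_len(nb)] <- b$labels
    }
    at <- at + nb
  }
  new_window_batch(win, sid, rate, dur, labels = lab)
}

#' Subset a WindowBatch by window index
#' @param batch a `harssl_window_batch`.
#' @param idx integer indices of windows to keep (may repeat).
#' @return A `harssl_window_batch` with the selected windows.
#' @export
subset_batch <- function(batch, idx) {
  new_window_batch(batch$windows[idx, , , drop = FALSE],
                   batch$subject_ids[idx], batch$rate, batch$duration,
                   labels = if (is.null(batch$labels)) NULL else batch$labels[idx])
}

BUNDLE_SCHEMA_VERSION <- 1L

#' Write / read a window bundle
#'
#' Lossless round-trip of a `harssl_window_batch` as a single compressed
#' container (`path`) with a JSON metadata sidecar (`<path>.meta.json`,
#' schema version, counts, class names, index/grid conventions).
#'
#' @param batch a `harssl_window_batch`.
#' @param path output file path (the sidecar is written next to it).
#' @return `write_window_bundle`: the path, invisibly.
#' @export
write_window_bundle <- function(batch, path) {
  stopifnot(inherits(batch, "harssl_window_batch"))
  meta <- list(schema_version = BUNDLE_SCHEMA_VERSION,
               n_windows = n_windows(batch),
               window_len = dim(batch$windows)[2L],
               rate = batch$rate,
               duration = batch$duration,
               n_subjects = length(unique(batch$subject_ids)),
               class_names = if (is.null(batch$labels)) list() else
                 as.list(sort(unique(batch$labels))),
               conventions = list(index_base = 0L,
                                  window_boundaries = "half-open",
                                  units = "g"))
  con <- gzfile(path, "wb")
  on.exit(close(con), add = TRUE)
  saveRDS(list(schema_version = BUNDLE_SCHEMA_VERSION,
               windows = batch$windows,
               subjects = batch$subject_ids,
               labels = batch$labels,
               rate = batch$rate,
               duration = batch$duration), con)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_window_bundle
#' @return `read_window_bundle`: the restored `harssl_window_batch`.
#' @export
read_window_bundle <- function(path) {
  con <- gzfile(path, "rb")
  on.exit(close(con), add = TRUE)
  obj <- readRDS(con)
  if (is.null(obj$schema_version) || obj$schema_version != BUNDLE_SCHEMA_VERSION)
    stop_version(sprintf("bundle schema version %s; this build reads version %d",
                         as.character(obj$schema_version %||% "missing"),
                         BUNDLE_SCHEMA_VERSION))
  side <- paste0(path, ".meta.json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side)
    if (!identical(as.integer(meta$schema_version), BUNDLE_SCHEMA_VERSION))
      stop_version(sprintf("sidecar schema version %s; this build reads version %d",
                           as.character(meta$schema_version), BUNDLE_SCHEMA_VERSION))
  }
  new_window_batch(obj$windows, obj$subjects, obj$rate, obj$duration,
                   labels = obj$labels)
}
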