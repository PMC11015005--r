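#' Pretext transformation configuration
#'
#' Parameters of the three self-supervised transformations. The permutation
#' task cuts each window into `n_chunks` chunks of at least `min_chunk_len`
#' samples and shuffles them; time warping draws log-normal local speeds at
#' `tw_n_knots + 2` equally spaced knots with log-speed standard deviation
#' `tw_sigma`. Each enabled task is applied independently with probability
#' `apply_prob`, in the fixed order arrow-of-time, permutation, time-warp.
#'
#' @param n_chunks number of permutation chunks (default 4).
#' @param min_chunk_len minimum chunk length in samples (default 10).
#' @param tw_n_knots number of interior warp knots (default 4).
#' @param tw_sigma standard deviation of log local speed (default 0.2;
#'   0 gives the identity warp).
#' @param apply_prob per-task application probability (default 0.5).
#' @param tasks character subset of `c("aot", "permutation", "timewarp")`.
#' @return A list of class `harssl_transform_config`.
#' @export
transform_config <- function(n_chunks = 4L, min_chunk_len = 10L,
                             tw_n_knots = 4L, tw_sigma = 0.2,
                             apply_prob = 0.5,
                             tasks = c("aot", "permutation", "timewarp")) {
  if (!is_count(n_chunks, 2L)) stop_param("n_chunks must be an integer >= 2")
  if (!is_count(min_chunk_len, 1L)) stop_param("min_chunk_len must be >= 1")
  if (!is_count(tw_n_knots, 1L)) stop_param("tw_n_knots must be >= 1")
  if (tw_sigma < 0) stop_param("tw_sigma must be >= 0")
  if (apply_prob < 0 || apply_prob > 1)
    stop_param("apply_prob must be in [0, 1]")
  tasks <- match.arg(tasks, c("aot", "permutation", "timewarp"),
                     several.ok = TRUE)
  if (length(tasks) == 0L) stop_param("at least one task must be enabled")
  # fixed composition order, independent of the order given
  tasks <- intersect(c("aot", "permutation", "timewarp"), tasks)
  structure(list(n_chunks = as.integer(n_chunks),
                 min_chunk_len = as.integer(min_chunk_len),
                 tw_n_knots = as.integer(tw_n_knots),
                 tw_sigma = tw_sigma,
                 apply_prob = apply_prob,
                 tasks = tasks),
            class = "harssl_transform_config")
}

#' Arrow-of-time transformation: reverse a window in time
#'
#' Flips the signal along the time axis (plays it in reverse), all three axes
#' simultaneously. An involution: applying it twice restores the input.
#'
#' @param w numeric L x 3 window.
#' @return The time-reversed L x 3 window.
#' @export
arrow_of_time <- function(w) {
  w[rev(seq_len(nrow(w))), , drop = FALSE]
}

# Uniform draw from the compositions of L into n parts each >= mlen,
# via the spacings construction: compose L - n*mlen into n non-negative
# parts uniformly (stars and bars), then add mlen to each part.
#' @noRd
draw_chunk_lengths <- function(L, n_chunks, min_chunk_len) {
  slack <- L - n_chunks * min_chunk_len
  if (slack < 0)
    stop_param(sprintf("window of %d samples cannot hold %d chunks of >= %d",
                       L, n_chunks, min_chunk_len))
  if (slack == 0) return(rep(min_chunk_len, n_chunks))
  # uniform composition of `slack` into n_chunks non-negative parts:
  # choose n_chunks-1 distinct bar positions among slack + n_chunks - 1 slots
  bars <- sort(sample.int(slack + n_chunks - 1L, n_chunks - 1L))
  parts <- diff(c(0L, bars, slack + n_chunks)) - 1L
  parts + min_chunk_len
}

#' Permutation transformation: cut a window into chunks and shuffle them
#'
#' Cut points are drawn uniformly among all compositions of the window length
#' into `n_chunks` parts of at least `min_chunk_len` samples; the chunk order
#' is drawn uniformly among the non-identity permutations, so the output is
#' always genuinely shuffled. All three axes share the same cuts and order.
#'
#' @param w numeric L x 3 window.
#' @param cfg a `harssl_transform_config`.
#' @return The chunk-shuffled L x 3 window.
#' @export
permute <- function(w, cfg = transform_config()) {
  L <- nrow(w)
  lens <- draw_chunk_lengths(L, cfg$n_chunks, cfg$min_chunk_len)
  ends <- cumsum(lens)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  repeat {
    ord <- sample.int(cfg$n_chunks)
    if (!all(ord == seq_len(cfg$n_chunks))) break
  }
  idx <- unlist(lapply(ord, function(i) starts[i]:ends[i]), use.names = FALSE)
  w[idx, , drop = FALSE]
}

# Monotone warp map on [0, 1]: cubic-spline interpolation of log-normal
# local speeds at equally spaced knots, integrated (trapezoid) and
# normalised so that endpoints map to endpoints.
#' @noRd
draw_warp_map <- function(L, n_knots, sigma) {
  kx <- seq(0, 1, length.out = n_knots + 2L)
  speeds <- exp(stats::rnorm(n_knots + 2L, 0, sigma))
  tgrid <- seq(0, 1, length.out = L)
  s <- stats::spline(kx, speeds, xout = tgrid, method = "natural")$y
  s <- pmax(s, 1e-6)  # splines can overshoot below zero; speeds stay positive
  cum <- cumsum(c(0, (s[-1L] + s[-L]) / 2)) # trapezoid integral
  cum / cum[L]
}

#' Time-warping transformation: random monotone time reparameterisation
#'
#' Stretches and compresses segments of the signal (locally slowing it down
#' and speeding it up) by resampling it at warped times via linear
#' interpolation; output length equals input length and the same warp is
#' applied to all three axes. `tw_sigma = 0` yields the identity.
#'
#' @param w numeric L x 3 window.
#' @param cfg a `harssl_transform_config`.
#' @return The time-warped L x 3 window.
#' @export
time_warp <- function(w, cfg = transform_config()) {
  L <- nrow(w)
  if (cfg$tw_sigma == 0) return(w)
  warp <- draw_warp_map(L, cfg$tw_n_knots, cfg$tw_sigma)
  src <- warp * (L - 1) + 1  # warped positions in sample index units
  out <- w
  for (a in 1:3) {
    out[, a] <- stats::approx(seq_len(L), w[, a], xout = src, rule = 2)$y
  }
  out
}

#' @noRd
rotation_matrix <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  c <- cos(angle); s <- sin(angle)
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) * c + s * K + (1 - c) * tcrossprod(u)
}

#' Random axis swap / rotation augmentation
#'
#' Device-orientation invariance augmentation: with probability 1/2 a
#' uniformly chosen signed permutation of the three axes (determinant +1 or
#' -1), otherwise a 3-D rotation by an angle uniform on `[0, 2*pi)` about an
#' axis uniform on the sphere. Label-free: never enters the pretext labels.
#'
#' @param w numeric L x 3 window.
#' @return The transformed L x 3 window.
#' @export
random_axis_transform <- function(w) {
  if (stats::runif(1) < 0.5) {
    perm <- sample(3L)
    signs <- sample(c(-1, 1), 3L, replace = TRUE)
    w[, perm, drop = FALSE] * rep(signs, each = nrow(w))
  } else {
    ax <- stats::rnorm(3)
    while (sum(ax^2) < 1e-12) ax <- stats::rnorm(3)
    R <- rotation_matrix(ax, stats::runif(1, 0, 2 * pi))
    w %*% t(R)
  }
}

#' Build a pretext training batch with binary self-labels
#'
#' Each window first receives the orientation augmentation, then for each
#' enabled task an independent Bernoulli(`apply_prob`) indicator is drawn and
#' the indicated transformations are applied in the fixed order
#' arrow-of-time, permutation, time-warp. The indicators are the training
#' labels: each task is a binary problem predicting whether its
#' transformation was applied.
#'
#' @param batch a `harssl_window_batch`.
#' @param cfg a `harssl_transform_config`.
#' @param augment apply the orientation augmentation first (default TRUE).
#' @return A list with `batch` (transformed `harssl_window_batch`) and
#'   `labels` (B x n_tasks 0/1 matrix, columns named by task).
#' @export
make_pretext_batch <- function(batch, cfg = transform_config(),
                               augment = TRUE) {
  if (length(cfg$tasks) == 0L) stop_param("at least one task must be enabled")
  B <- n_windows(batch)
  labels <- matrix(0L, B, length(cfg$tasks),
                   dimnames = list(NULL, cfg$tasks))
  out <- batch$windows
  for (b in seq_len(B)) {
    w <- out[b, , ]
    if (augment) w <- random_axis_transform(w)
    for (task in cfg$tasks) {
      apply_it <- stats::runif(1) < cfg$apply_prob
      labels[b, task] <- as.integer(apply_it)
      if (apply_it) {
        w <- switch(task,
                    aot = arrow_of_time(w),
                    permutation = permute(w, cfg),
                    timewarp = time_warp(w, cfg))
      }
    }
    out[b, , ] <- w
  }
  list(batch = new_window_batch(out, batch$subject_ids, batch$rate,
                                batch$duration, labels = batch$labels),
       labels = labels)
}
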