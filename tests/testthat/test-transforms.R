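test_that("arrow of time is an involution with the expected fixed points", {
  set.seed(1)
  w <- matrix(rnorm(300 * 3), 300, 3)
  expect_identical(arrow_of_time(arrow_of_time(w)), w)

  # single-axis sequence reverses
  w2 <- cbind(1:5, rep(0, 5), rep(0, 5))
  expect_equal(arrow_of_time(w2)[, 1], 5:1)

  # time-palindromic window is a fixed point
  half <- matrix(rnorm(50 * 3), 50, 3)
  pal <- rbind(half, half[50:1, ])
  expect_identical(arrow_of_time(pal), pal)
})

test_that("permutation preserves multisets and respects chunk constraints", {
  cfg <- transform_config(n_chunks = 4, min_chunk_len = 10)
  set.seed(42)
  w <- matrix(rnorm(60 * 3), 60, 3)
  out <- permute(w, cfg)
  for (a in 1:3) expect_equal(sort(out[, a]), sort(w[, a]))

  # L = 40 with min 10 and 4 chunks admits exactly one composition
  # (10,10,10,10): the output must be one of the 23 non-identity chunk
  # rearrangements, and never the identity
  w40 <- matrix(seq_len(40), 40, 3)
  chunks <- lapply(0:3, function(i) (i * 10 + 1):(i * 10 + 10))
  perms <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ]
  rearr <- apply(perms, 1, function(p) unlist(chunks[p]))
  non_identity <- rearr[, colSums(rearr != seq_len(40)) > 0, drop = FALSE]
  expect_equal(ncol(non_identity), 23)
  for (seed in 1:25) {
    set.seed(seed)
    got <- permute(w40, cfg)[, 1]
    matches <- apply(non_identity, 2, function(e) all(e == got))
    expect_equal(sum(matches), 1)
  }

  # constraint satisfaction over many seeded draws (uniform compositions)
  set.seed(7)
  for (i in 1:2000) {
    lens <- harssl:::draw_chunk_lengths(60L, 4L, 10L)
    expect_true(all(lens >= 10) && sum(lens) == 60)
  }

  expect_error(permute(matrix(0, 20, 3), cfg),
               class = "harssl_parameter_error")
})

test_that("time warping has identity, fixed-point and boundedness properties", {
  set.seed(3)
  w <- matrix(rnorm(300 * 3, 0, 0.5), 300, 3)

  # sigma = 0 is the exact identity
  cfg0 <- transform_config(tw_sigma = 0)
  expect_equal(max(abs(time_warp(w, cfg0) - w)), 0)

  # constant window is a fixed point of any warp
  wc <- matrix(rep(c(0.1, -0.2, 1), each = 300), 300, 3)
  set.seed(11)
  expect_equal(time_warp(wc, transform_config(tw_sigma = 0.4)), wc,
               tolerance = 1e-12)

  # warped values stay inside the per-axis input range (1000 seeded warps)
  cfg <- transform_config(tw_sigma = 0.3)
  set.seed(5)
  lo <- apply(w, 2, min); hi <- apply(w, 2, max)
  for (i in 1:1000) {
    out <- time_warp(w, cfg)
    for (a in 1:3) {
      expect_true(min(out[, a]) >= lo[a] - 1e-12)
      expect_true(max(out[, a]) <= hi[a] + 1e-12)
    }
  }

  # max deviation from identity shrinks monotonically with sigma on a
  # smooth window (deviation on white noise saturates at any warp size)
  t <- (0:299) / 30
  ws <- cbind(sin(2 * pi * 0.5 * t), cos(2 * pi * 0.3 * t), 1 + 0.2 * t / 10)
  devs <- vapply(c(0.4, 0.2, 0.1, 0.05), function(s) {
    set.seed(99)
    max(abs(time_warp(ws, transform_config(tw_sigma = s)) - ws))
  }, numeric(1))
  expect_true(all(diff(devs) < 0))
})

test_that("axis transforms are isometries / signed permutations", {
  set.seed(2)
  w <- matrix(rnorm(300 * 3), 300, 3)
  norms <- sqrt(rowSums(w^2))
  for (i in 1:200) {
    out <- random_axis_transform(w)
    # both branches preserve per-sample Euclidean norm
    expect_equal(sqrt(rowSums(out^2)), norms, tolerance = 1e-9)
  }

  # a 90-degree rotation about z maps (1,0,0) to (0,1,0)
  R <- harssl:::rotation_matrix(c(0, 0, 1), pi / 2)
  expect_equal(as.vector(R %*% c(1, 0, 0)), c(0, 1, 0), tolerance = 1e-12)
})

test_that("pretext batches carry Bernoulli labels and compose transforms", {
  b <- random_batch(B = 12, L = 60, rate = 30)

  # apply_prob 0 -> labels all zero and windows untouched (augment off)
  cfg0 <- transform_config(apply_prob = 0, min_chunk_len = 10)
  set.seed(1)
  pb0 <- make_pretext_batch(b, cfg0, augment = FALSE)
  expect_true(all(pb0$labels == 0))
  expect_identical(pb0$batch$windows, b$windows)

  # AoT-only with indicator 1 equals arrow_of_time exactly
  cfg_aot <- transform_config(apply_prob = 0.5, tasks = "aot")
  set.seed(4)
  pb <- make_pretext_batch(b, cfg_aot, augment = FALSE)
  for (i in seq_len(n_windows(b))) {
    expected <- if (pb$labels[i, "aot"] == 1) arrow_of_time(b$windows[i, , ])
                else b$windows[i, , ]
    expect_identical(pb$batch$windows[i, , ], expected)
  }

  # label fractions inside the 99% binomial interval around 0.5 (n = 10,000)
  big <- random_batch(B = 10000, L = 40, rate = 4)
  cfg3 <- transform_config(min_chunk_len = 10)
  set.seed(9)
  pb3 <- make_pretext_batch(big, cfg3, augment = FALSE)
  ci <- 0.5 + c(-1, 1) * qnorm(0.995) * sqrt(0.25 / 10000)
  for (task in colnames(pb3$labels)) {
    frac <- mean(pb3$labels[, task])
    expect_gt(frac, ci[1])
    expect_lt(frac, ci[2])
  }

  # reproducible under a fixed seed
  set.seed(123)
  a1 <- make_pretext_batch(b, cfg_aot)
  set.seed(123)
  a2 <- make_pretext_batch(b, cfg_aot)
  expect_identical(a1$labels, a2$labels)
  expect_identical(a1$batch$windows, a2$batch$windows)
})
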