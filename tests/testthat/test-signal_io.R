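test_that("CSV loading infers the rate, drops bad rows, rejects bad files", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "rec.csv")

  # 300 rows at 0.1-s spacing -> rate 10, N = 300
  df <- data.frame(time = (0:299) * 0.1, x = 0.1, y = 0.2, z = 1.0)
  write.csv(df, path, row.names = FALSE)
  rec <- read_csv_recording(path, "s1")
  expect_equal(rec$rate, 10)
  expect_equal(nrow(rec$acc), 300)
  expect_equal(attr(rec, "load_report")$dropped, 0)

  # one NaN row among 100 -> N = 99, dropped = 1
  df2 <- data.frame(time = (0:99) * 0.1, x = 1, y = 1, z = 1)
  df2$x[50] <- NA
  write.csv(df2, path, row.names = FALSE)
  rec2 <- read_csv_recording(path, "s1")
  expect_equal(nrow(rec2$acc), 99)
  expect_equal(attr(rec2, "load_report")$dropped, 1)

  # time running backwards -> format error naming the row
  df3 <- data.frame(time = c(0, 1, 0.5, 2), x = 1, y = 1, z = 1)
  write.csv(df3, path, row.names = FALSE)
  expect_error(read_csv_recording(path, "s1"), "non-monotone at row 3",
               class = "harssl_format_error")

  # missing columns
  write.csv(data.frame(time = 1:3, x = 1, y = 1), path, row.names = FALSE)
  expect_error(read_csv_recording(path, "s1"), "missing required columns",
               class = "harssl_format_error")

  # fewer than 2 rows
  write.csv(data.frame(time = 1, x = 1, y = 1, z = 1), path,
            row.names = FALSE)
  expect_error(read_csv_recording(path, "s1"),
               class = "harssl_insufficient_data_error")

  # label column round-trips
  df4 <- data.frame(time = (0:99) * 0.1, x = 0, y = 0, z = 1,
                    label = rep(c("a", "b"), 50))
  write.csv(df4, path, row.names = FALSE)
  rec4 <- read_csv_recording(path, "s1")
  expect_equal(rec4$label_stream, df4$label)
})

test_that("linear resampling preserves constants, spectra, and grid counts", {
  # constant signal at 100 Hz -> identical constant at 30 Hz
  n <- 500
  rec <- new_recording(matrix(rep(c(0, 0, 1), each = n), n, 3), 100, "s1")
  out <- resample_linear(rec, 30)
  expect_equal(out$rate, 30)
  expect_true(all(abs(out$acc[, 3] - 1) < 1e-12))
  expect_true(all(abs(out$acc[, 1:2]) < 1e-12))

  # 1-Hz sinusoid resampled 100 -> 30 Hz keeps its dominant FFT frequency
  t100 <- (0:999) / 100
  rec2 <- new_recording(cbind(sin(2 * pi * 1 * t100), 0, 1), 100, "s1")
  out2 <- resample_linear(rec2, 30)
  x <- out2$acc[, 1]
  spec <- Mod(fft(x - mean(x)))[2:(length(x) %/% 2)]
  dom <- which.max(spec) * 30 / length(x)
  expect_equal(dom, 1, tolerance = 0.05)

  # grid count oracle: independent construction by seq() over the span
  rec3 <- new_recording(matrix(rnorm(900 * 3), 900, 3), 15, "s1")
  out3 <- resample_linear(rec3, 30)
  span <- (900 - 1) / 15
  oracle_n <- length(seq(0, span, by = 1 / 30))
  expect_equal(nrow(out3$acc), oracle_n)
  expect_equal(nrow(out3$acc), 1799)

  # idempotent when source rate equals target and grid already uniform
  rec4 <- make_test_recording(dur = 20, rate = 30)
  out4 <- resample_linear(rec4, 30)
  expect_equal(out4$acc, rec4$acc, tolerance = 1e-12)

  expect_error(resample_linear(new_recording(matrix(1, 1, 3), 30, "s"), 30),
               class = "harssl_insufficient_data_error")
})

test_that("windowing counts, trailing discard, and modal labels", {
  rec <- make_test_recording(dur = 70, rate = 30)
  wb <- make_windows(rec, duration = 10)
  expect_equal(n_windows(wb), 7)
  expect_equal(dim(wb$windows)[2], 300)

  # 9.9-s recording -> 0 windows
  rec2 <- make_test_recording(dur = 9.9, rate = 30)
  expect_equal(n_windows(make_windows(rec2, 10)), 0)

  # 30-s recording with 50% overlap -> 5 windows (hop arithmetic)
  rec3 <- make_test_recording(dur = 30, rate = 30)
  expect_equal(n_windows(make_windows(rec3, 10, overlap_fraction = 0.5)), 5)

  # count formula 1 + floor((N - L)/hop) across parameter grid
  for (dur in c(15, 23, 40)) {
    for (ov in c(0, 0.25, 0.5)) {
      rec_g <- make_test_recording(dur = dur, rate = 30)
      L <- 300
      hop <- round(L * (1 - ov))
      N <- nrow(rec_g$acc)
      expected <- if (N >= L) 1 + (N - L) %/% hop else 0
      expect_equal(n_windows(make_windows(rec_g, 10, ov)), expected)
    }
  }

  # modal label with first-seen tie-break
  labs <- c(rep("walk", 150), rep("rest", 150), rep("walk", 300))
  rec4 <- make_test_recording(dur = 20, rate = 30, labels = labs)
  wb4 <- make_windows(rec4, 10)
  expect_equal(wb4$labels, c("walk", "walk")) # tie in window 1 -> first seen

  expect_error(make_windows(rec, duration = 0),
               class = "harssl_parameter_error")
})

test_that("window bundles round-trip losslessly and reject bad versions", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "batch.bundle")
  b <- random_batch(B = 6, labels = c("a", "b"), subjects = c("s1", "s2"))
  write_window_bundle(b, path)
  expect_true(file.exists(paste0(path, ".meta.json")))
  b2 <- read_window_bundle(path)
  expect_identical(b2$windows, b$windows)
  expect_identical(b2$subject_ids, b$subject_ids)
  expect_identical(b2$labels, b$labels)
  expect_identical(b2$rate, b$rate)
  expect_identical(b2$duration, b$duration)

  # empty batch round-trips with B = 0
  b0 <- new_window_batch(array(0, c(0, 300, 3)), character(0), 30, 10)
  write_window_bundle(b0, path)
  expect_equal(n_windows(read_window_bundle(path)), 0)

  # wrong schema version -> versioned error
  obj <- readRDS(gzfile(path))
  obj$schema_version <- 99L
  con <- gzfile(path, "wb"); saveRDS(obj, con); close(con)
  expect_error(read_window_bundle(path), "99",
               class = "harssl_version_error")
})
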