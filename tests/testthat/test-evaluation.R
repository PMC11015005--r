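test_that("cross-validation folds partition subjects correctly", {
  # 7 subjects -> LOSO: 7 folds, distinct singleton test sets
  set.seed(1)
  folds7 <- make_folds(sprintf("s%d", 1:7))
  expect_length(folds7, 7)
  expect_setequal(vapply(folds7, function(f) f$test_subjects, character(1)),
                  sprintf("s%d", 1:7))

  # 20 subjects -> 5 folds of 4 test, 2 val, 14 train
  set.seed(2)
  folds20 <- make_folds(sprintf("s%d", 1:20))
  expect_length(folds20, 5)
  for (f in folds20) {
    expect_length(f$test_subjects, 4)
    expect_length(f$val_subjects, 2)
    expect_length(f$train_subjects, 14)
  }

  # partition property for 2..30 subjects: pairwise-disjoint sets per fold,
  # every subject tested exactly once across folds
  for (n in 2:30) {
    set.seed(n)
    ids <- sprintf("p%02d", seq_len(n))
    folds <- make_folds(ids)
    tested <- character(0)
    for (f in folds) {
      expect_length(intersect(f$train_subjects, f$val_subjects), 0)
      expect_length(intersect(f$train_subjects, f$test_subjects), 0)
      expect_length(intersect(f$val_subjects, f$test_subjects), 0)
      if (n >= 3) expect_gt(length(f$train_subjects), 0)
      expect_gt(length(f$val_subjects), 0)
      tested <- c(tested, f$test_subjects)
    }
    expect_setequal(tested, ids)
    expect_equal(length(tested), n)
  }

  expect_error(make_folds("only_one"), class = "harssl_data_error")
})

test_that("class filtering keeps the intersection for small datasets", {
  mk <- function(subj, labs) {
    B <- length(labs)
    new_window_batch(array(0, c(B, 30, 3)), rep(subj, B), 3, 10, labels = labs)
  }
  b <- bind_batches(mk("s1", c("A", "B", "C")), mk("s2", c("A", "B")),
                    mk("s3", c("A", "B", "D")))
  out <- filter_classes(b)
  expect_setequal(unique(out$labels), c("A", "B"))
  expect_setequal(attr(out, "filter_report")$removed, c("C", "D"))

  # >= 10 subjects: unchanged even with heterogeneous classes
  parts <- lapply(1:12, function(i)
    mk(sprintf("s%d", i), c("A", sprintf("only%d", i))))
  big <- bind_batches(parts)
  out2 <- filter_classes(big)
  expect_equal(n_windows(out2), n_windows(big))

  # identical class sets: identity
  same <- bind_batches(mk("s1", c("A", "B")), mk("s2", c("B", "A")))
  expect_equal(n_windows(filter_classes(same)), 4)

  # nothing shared: data error
  disj <- bind_batches(mk("s1", "A"), mk("s2", "B"))
  expect_error(filter_classes(disj), class = "harssl_data_error")
})

test_that("subject-wise scores match the confusion-matrix hand computation", {
  # 2x2 confusion {{8,2},{4,6}}: macro-F1 and kappa from first principles
  truth <- c(rep("c1", 10), rep("c2", 10))
  pred <- c(rep("c1", 8), rep("c2", 2), rep("c1", 4), rep("c2", 6))
  # per-class F1: 2*8/(2*8+4+2) = 0.727273, 2*6/(2*6+2+4) = 0.666667
  expect_equal(macro_f1(pred, truth), (8 / 11 + 2 / 3) / 2,
               tolerance = 1e-12)
  expect_equal(cohen_kappa(pred, truth), 0.4, tolerance = 1e-12)

  # perfect predictions
  sc <- score_subjectwise(truth, truth, rep(c("sA", "sB"), 10))
  expect_true(all(sc$scores$macro_f1 == 1))
  expect_true(all(sc$scores$kappa == 1))
  expect_equal(sc$aggregate$sd_f1, 0)

  # constant prediction against balanced 2-class truth: kappa 0
  const <- rep("c1", 20)
  expect_equal(cohen_kappa(const, truth), 0)

  # agreement with an independent oracle over 1,000 random prediction sets
  set.seed(99)
  for (i in 1:1000) {
    k <- sample(2:4, 1)
    n <- sample(5:30, 1)
    classes <- letters[1:k]
    tr <- sample(classes, n, replace = TRUE)
    while (length(unique(tr)) < 2) tr <- sample(classes, n, replace = TRUE)
    pr <- sample(classes, n, replace = TRUE)
    o <- oracle_scores(pr, tr)
    expect_equal(macro_f1(pr, tr), o$macro_f1, tolerance = 1e-12)
    expect_equal(cohen_kappa(pr, tr), o$kappa, tolerance = 1e-12)
  }
})

test_that("relative improvements reproduce the printed table cells", {
  expect_equal(relative_improvement(0.708, 0.726), 2.5)
  expect_equal(relative_improvement(0.327, 0.755), 130.9)
  expect_equal(relative_improvement(0.5, 0.5), 0.0)
  expect_error(relative_improvement(0, 0.5),
               class = "harssl_undefined_improvement_error")

  s <- summarize_improvements(c(2.5, 14.4, 18.4, 130.9, 12.3, 55.4, 30.4,
                                100.0))
  expect_equal(s$min, 2.5)
  expect_equal(s$max, 130.9)
  expect_equal(s$median, 24.4)
  expect_equal(summarize_improvements(5)$median, 5)
  expect_equal(summarize_improvements(c(1, 2, 3))$median, 2)
})

test_that("window features capture the expected signal properties", {
  # constant window: SD features 0, correlations imputed 0
  fc <- window_features(matrix(rep(c(0, 0, 1), each = 300), 300, 3))
  expect_equal(unname(fc[c("sd_x", "sd_y", "sd_z")]), c(0, 0, 0))
  expect_equal(unname(fc[c("cor_xy", "cor_xz", "cor_yz")]), c(0, 0, 0))
  expect_true(all(is.finite(fc)))

  # pure 2-Hz vertical sinusoid at 30 Hz: dominant frequency 2.0 (bin 0.1);
  # the oscillation rides on the 1-g offset so the magnitude spectrum keeps
  # the fundamental
  t <- (0:299) / 30
  w <- cbind(0, 0, 1 + 0.5 * sin(2 * pi * 2 * t))
  expect_equal(unname(window_features(w, 30)["dom_freq"]), 2, tolerance = 0.1)
})

test_that("the random-forest baseline separates separable classes", {
  set.seed(7)
  mk_class <- function(n, f, subj) {
    win <- array(0, c(n, 300, 3))
    for (i in seq_len(n)) {
      t <- (0:299) / 30
      osc <- if (f > 0) 0.5 * sin(2 * pi * f * t + runif(1, 0, 2 * pi))
             else rep(0, 300)
      win[i, , ] <- cbind(osc, rep(0, 300), rep(1, 300)) +
        matrix(rnorm(900, 0, 0.05), 300, 3)
    }
    new_window_batch(win, rep(subj, n), 30, 10,
                     labels = rep(if (f > 0) "osc" else "static", n))
  }
  train <- bind_batches(mk_class(100, 3, "s1"), mk_class(100, 0, "s1"))
  test <- bind_batches(mk_class(100, 3, "s2"), mk_class(100, 0, "s2"))
  pred <- rf_baseline(train, test, n_trees = 50)
  expect_equal(macro_f1(pred, test$labels), 1.0)

  only_one <- mk_class(20, 3, "s1")
  expect_error(rf_baseline(only_one, test), class = "harssl_data_error")
})

test_that("feature projection yields 2-D embeddings with a silhouette", {
  skip_if_not_installed("uwot")
  skip_if_not_installed("cluster")
  set.seed(5)
  X <- rbind(matrix(rnorm(40 * 16, 0), 40, 16),
             matrix(rnorm(40 * 16, 4), 40, 16))
  labs <- rep(c("a", "b"), each = 40)
  p1 <- project_features(X, labs, seed = 3)
  expect_equal(dim(p1$embedding), c(80, 2))
  expect_gt(p1$silhouette, 0.5) # well-separated gaussians
  p2 <- project_features(X, labs, seed = 3)
  expect_identical(p1$embedding, p2$embedding)
  expect_error(project_features(X[1:5, ]), class = "harssl_parameter_error")
})
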