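# Shared fixtures: tiny recordings, window batches and toy encoder configs,
# all generated in code.

toy_encoder_config <- function(input_len = 300L, width = 4L) {
  encoder_config(input_len = input_len, base_width = width,
                 param_budget = NULL)
}

# A deterministic recording: rate Hz, dur seconds, smooth + noise, 3 axes.
make_test_recording <- function(dur = 70, rate = 30, subject = "s1",
                                labels = NULL, seed = 1) {
  set.seed(seed)
  n <- round(dur * rate)
  t <- (seq_len(n) - 1) / rate
  acc <- cbind(0.3 * sin(2 * pi * 1 * t),
               0.2 * cos(2 * pi * 2 * t),
               1 + 0.05 * rnorm(n))
  new_recording(acc, rate, subject, label_stream = labels)
}

random_batch <- function(B = 8, L = 300, rate = 30, subjects = "s1",
                         labels = NULL, seed = 1) {
  set.seed(seed)
  win <- array(rnorm(B * L * 3, 0, 0.3), c(B, L, 3))
  new_window_batch(win, rep_len(subjects, B), rate, L / rate,
                   labels = if (is.null(labels)) NULL else rep_len(labels, B))
}

# Independent confusion-matrix oracle for macro-F1 and kappa (table-based,
# separate code path from the package implementation).
oracle_scores <- function(pred, truth) {
  classes <- unique(truth)
  f1 <- numeric(length(classes))
  for (i in seq_along(classes)) {
    cl <- classes[i]
    tp <- sum(pred == cl & truth == cl)
    prec_den <- sum(pred == cl)
    rec_den <- sum(truth == cl)
    prec <- if (prec_den == 0) 0 else tp / prec_den
    rec <- tp / rec_den
    f1[i] <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }
  lv <- unique(c(pred, truth))
  cm <- table(factor(pred, lv), factor(truth, lv))
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  list(macro_f1 = mean(f1),
       kappa = if (pe == 1) 0 else (po - pe) / (1 - pe))
}
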