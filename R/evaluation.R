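#' Subject-wise cross-validation folds
#'
#' Datasets with fewer than 10 subjects use held-one-subject-out
#' cross-validation (each fold tests one subject; the remaining subjects
#' split ~7:1 train:validation with at least one validation subject).
#' Datasets with 10 or more subjects use five-fold subject-wise
#' cross-validation with a 7:1:2 train/validation/test ratio at subject
#' granularity. Every subject is tested exactly once across folds and the
#' three sets of a fold are pairwise disjoint.
#'
#' @param subject_ids character vector of distinct subject ids (>= 2).
#' @return List of folds, each a list with `fold_id`, `train_subjects`,
#'   `val_subjects`, `test_subjects`.
#' @export
make_folds <- function(subject_ids) {
  subject_ids <- unique(as.character(subject_ids))
  n <- length(subject_ids)
  if (n < 2L) stop_data("need at least 2 subjects")
  if (n < 10L) {
    folds <- lapply(seq_len(n), function(i) {
      rest <- sample(subject_ids[-i])
      n_val <- max(1L, round(length(rest) / 8))
      list(fold_id = i,
           train_subjects = rest[-seq_len(n_val)],
           val_subjects = rest[seq_len(n_val)],
           test_subjects = subject_ids[i])
    })
    return(folds)
  }
  ids <- sample(subject_ids)
  test_sets <- split(ids, cut(seq_len(n), 5L, labels = FALSE))
  lapply(seq_along(test_sets), function(i) {
    rest <- sample(setdiff(ids, test_sets[[i]]))
    n_val <- max(1L, round(n * 0.1))
    list(fold_id = i,
         train_subjects = rest[-seq_len(n_val)],
         val_subjects = rest[seq_len(n_val)],
         test_subjects = test_sets[[i]])
  })
}

#' Remove classes not performed by every subject (small datasets)
#'
#' For datasets with fewer than 10 subjects, keeps only the activity classes
#' present in every subject's data (LOSO folds would otherwise test classes
#' some training subjects never performed); larger datasets pass through
#' unchanged. The removed classes and their window counts are reported in
#' `attr(result, "filter_report")`.
#'
#' @param batch a labelled `harssl_window_batch`.
#' @return The filtered `harssl_window_batch`.
#' @export
filter_classes <- function(batch) {
  if (is.null(batch$labels)) stop_data("labelled batch required")
  subjects <- unique(batch$subject_ids)
  if (length(subjects) >= 10L) {
    attr(batch, "filter_report") <- list(removed = character(0),
                                         windows_removed = 0L)
    return(batch)
  }
  per_subject <- lapply(subjects, function(s)
    unique(batch$labels[batch$subject_ids == s]))
  keep_classes <- Reduce(intersect, per_subject)
  if (length(keep_classes) == 0L)
    stop_data("no class is present in every subject")
  keep <- batch$labels %in% keep_classes
  removed <- setdiff(unique(batch$labels), keep_classes)
  out <- subset_batch(batch, which(keep))
  attr(out, "filter_report") <- list(removed = removed,
                                     windows_removed = sum(!keep))
  out
}

#' Macro-averaged F1 score
#'
#' Unweighted mean of per-class F1 over the classes present in `truth`
#' (classes predicted but absent from the truth contribute via false
#' positives only).
#'
#' @param pred,truth character/factor vectors of equal length.
#' @return Macro-F1 in `[0, 1]`.
#' @export
macro_f1 <- function(pred, truth) {
  classes <- unique(as.character(truth))
  pred <- as.character(pred)
  truth <- as.character(truth)
  f1 <- vapply(classes, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement between predicted and true labels.
#'
#' @param pred,truth character/factor vectors of equal length.
#' @return Kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(pred, truth) {
  lv <- unique(c(as.character(pred), as.character(truth)))
  p <- factor(pred, levels = lv)
  t <- factor(truth, levels = lv)
  n <- length(p)
  cm <- table(p, t)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (pe == 1) return(0)
  (po - pe) / (1 - pe)
}

#' Per-subject scores and their aggregate
#'
#' For each test subject computes macro-F1 (over classes present in that
#' subject's truth) and Cohen's kappa, then aggregates as unweighted mean and
#' standard deviation across subjects (pooled across folds). Subjects with
#' zero windows are excluded with a warning.
#'
#' @param pred predicted labels, one per window.
#' @param truth true labels, one per window.
#' @param subject_ids subject id per window.
#' @return A list with `scores` (data frame: subject_id, macro_f1, kappa,
#'   n_windows) and `aggregate` (mean_f1, sd_f1, mean_kappa, sd_kappa).
#' @export
score_subjectwise <- function(pred, truth, subject_ids) {
  stopifnot(length(pred) == length(truth),
            length(pred) == length(subject_ids))
  if (length(pred) == 0L) stop_data("no predictions to score")
  subjects <- unique(subject_ids)
  rows <- lapply(subjects, function(s) {
    sel <- subject_ids == s
    if (!any(sel)) {
      warning(sprintf("subject %s has zero windows; excluded", s))
      return(NULL)
    }
    data.frame(subject_id = s,
               macro_f1 = macro_f1(pred[sel], truth[sel]),
               kappa = cohen_kappa(pred[sel], truth[sel]),
               n_windows = sum(sel))
  })
  scores <- do.call(rbind, rows)
  list(scores = scores,
       aggregate = list(
         mean_f1 = mean(scores$macro_f1),
         sd_f1 = if (nrow(scores) > 1L) stats::sd(scores$macro_f1) else 0,
         mean_kappa = mean(scores$kappa),
         sd_kappa = if (nrow(scores) > 1L) stats::sd(scores$kappa) else 0))
}

#' Relative improvement in percent
#'
#' `100 * (improved - baseline) / baseline`, reported to one decimal — the
#' convention behind improvement columns such as 0.708 -> 0.726 giving 2.5%.
#'
#' @param baseline baseline score (> 0).
#' @param improved improved score.
#' @return Percent improvement, rounded to one decimal.
#' @export
relative_improvement <- function(baseline, improved) {
  if (any(baseline <= 0))
    abort("relative improvement undefined for baseline <= 0",
          "harssl_undefined_improvement_error")
  round(100 * (improved - baseline) / baseline, 1)
}

#' Range and median of per-dataset improvements
#'
#' @param improvements numeric vector of relative improvements (percent).
#' @return List with `min`, `max`, `median` (mean of the two central order
#'   statistics for even counts).
#' @export
summarize_improvements <- function(improvements) {
  if (length(improvements) == 0L) stop_param("at least one value required")
  list(min = min(improvements), max = max(improvements),
       median = stats::median(improvements))
}

# ---------------------------------------------------------------------------
# Random-forest baseline on classic time-series features.

#' Time-series feature vector of one window
#'
#' Per axis: mean, standard deviation, min, max, lower and upper quartile,
#' mean absolute deviation (21 features); inter-axis Pearson correlations
#' (3; 0 where undefined, e.g. a constant axis); vector-magnitude mean and
#' standard deviation (2); dominant frequency and its power from the
#' mean-removed magnitude spectrum, plus spectral entropy (3); mean roll and
#' pitch angles (2). 31 features total.
#'
#' @param w numeric L x 3 window.
#' @param rate sampling rate in Hz.
#' @return Named numeric feature vector.
#' @export
window_features <- function(w, rate = 30) {
  L <- nrow(w)
  per_axis <- unlist(lapply(1:3, function(a) {
    x <- w[, a]
    q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
    stats::setNames(c(mean(x), stats::sd(x), min(x), max(x), q[1], q[2],
                      mean(abs(x - mean(x)))),
                    paste0(c("mean", "sd", "min", "max", "q25", "q75", "mad"),
                           "_", c("x", "y", "z")[a]))
  }))
  cors <- vapply(list(c(1, 2), c(1, 3), c(2, 3)), function(ax) {
    if (stats::sd(w[, ax[1]]) < 1e-12 || stats::sd(w[, ax[2]]) < 1e-12) 0
    else stats::cor(w[, ax[1]], w[, ax[2]])
  }, numeric(1))
  names(cors) <- c("cor_xy", "cor_xz", "cor_yz")
  vm <- sqrt(rowSums(w^2))
  spec <- Mod(stats::fft(vm - mean(vm)))[2:(L %/% 2 + 1L)]^2
  freqs <- (1:(L %/% 2)) * rate / L
  if (sum(spec) < 1e-24) {
    dom_f <- 0; dom_p <- 0; sent <- 0
  } else {
    i <- which.max(spec)
    dom_f <- freqs[i]; dom_p <- spec[i]
    pr <- spec / sum(spec)
    sent <- -sum(ifelse(pr > 0, pr * log(pr), 0))
  }
  mx <- mean(w[, 1]); my <- mean(w[, 2]); mz <- mean(w[, 3])
  c(per_axis, cors,
    vm_mean = mean(vm), vm_sd = stats::sd(vm),
    dom_freq = dom_f, dom_power = dom_p, spec_entropy = sent,
    roll = atan2(my, mz), pitch = atan2(-mx, sqrt(my^2 + mz^2)))
}

#' @noRd
batch_features <- function(batch) {
  B <- n_windows(batch)
  t(vapply(seq_len(B),
           function(b) window_features(batch$windows[b, , ], batch$rate),
           window_features(batch$windows[1, , ], batch$rate)))
}

#' Random-forest baseline on time-series features
#'
#' The strong classical baseline: tried-and-tested time-series features (see
#' [window_features()]) fed to a random forest.
#'
#' @param train labelled `harssl_window_batch`.
#' @param test `harssl_window_batch` to predict.
#' @param n_trees number of trees (default 100).
#' @param max_depth maximum tree depth (default 12).
#' @return Character vector of predicted labels for `test`.
#' @export
rf_baseline <- function(train, test, n_trees = 100L, max_depth = 12L) {
  if (is.null(train$labels)) stop_data("labelled training batch required")
  classes <- sort(unique(train$labels))
  if (length(classes) < 2L)
    stop_data("single-class training data; the model would be degenerate")
  Xtr <- batch_features(train)
  ytr <- match(train$labels, classes)
  forest <- fit_forest(Xtr, ytr, K = length(classes), n_trees = n_trees,
                       max_depth = max_depth)
  classes[predict_forest(forest, batch_features(test))]
}

#' Project features to 2-D and score class separability
#'
#' UMAP at default parameters (seeded) paired with the mean silhouette width
#' by class, so "better clustering" is a number rather than a picture.
#'
#' @param features numeric B x F matrix (B >= 10).
#' @param labels optional class labels for the silhouette score.
#' @param seed RNG seed for the embedding.
#' @return List with `embedding` (B x 2) and `silhouette` (mean silhouette
#'   width in the embedding space, NA without labels).
#' @export
project_features <- function(features, labels = NULL, seed = 1L) {
  if (nrow(features) < 10L) stop_param("need at least 10 rows")
  set.seed(seed)
  emb <- uwot::umap(features, n_threads = 1, batch = FALSE)
  sil <- NA_real_
  if (!is.null(labels) && length(unique(labels)) > 1L) {
    sil <- silhouette_score(emb, labels)
  }
  list(embedding = emb, silhouette = sil)
}

#' Mean silhouette width by class
#'
#' @param X numeric matrix of points (rows) to score.
#' @param labels class label per row (>= 2 classes).
#' @return Mean silhouette width in `[-1, 1]`.
#' @export
silhouette_score <- function(X, labels) {
  cl <- as.integer(factor(labels))
  sil <- cluster::silhouette(cl, stats::dist(X))
  mean(sil[, "sil_width"])
}
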