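#' Pre-training configuration
#'
#' Multi-task self-supervised pre-training uses Adam at a base learning rate
#' of 1e-3, linearly scaled with batch size (the 4 x 1500 = 6000-window batch
#' trains at 4e-3) with a five-epoch burn-in ramp, an 8:2 subject-wise
#' train/test split, and early stopping with a patience of five epochs on the
#' held-out multi-task loss.
#'
#' @param tasks non-empty subset of `c("aot", "permutation", "timewarp")`.
#' @param base_lr base learning rate (default 1e-3).
#' @param warmup_epochs burn-in epochs for the learning-rate ramp (default 5).
#' @param lr_scale_reference batch size (windows) at which `base_lr` applies
#'   (default 1500, one subject's draw).
#' @param early_stop_patience epochs without held-out improvement before
#'   stopping (default 5).
#' @param train_test_ratio two numbers, subject-wise train:test split
#'   (default `c(8, 2)`).
#' @param max_epochs epoch cap (default 20).
#' @param batches_per_epoch batches assembled per epoch (default 10).
#' @param eval_batches held-out batches used for the per-epoch evaluation
#'   (default 2).
#' @param seed RNG seed for the run.
#' @return A list of class `harssl_pretrain_config`.
#' @export
pretrain_config <- function(tasks = c("aot", "permutation", "timewarp"),
                            base_lr = 1e-3, warmup_epochs = 5L,
                            lr_scale_reference = 1500L,
                            early_stop_patience = 5L,
                            train_test_ratio = c(8, 2),
                            max_epochs = 20L, batches_per_epoch = 10L,
                            eval_batches = 2L, seed = 1L) {
  tasks <- match.arg(tasks, c("aot", "permutation", "timewarp"),
                     several.ok = TRUE)
  if (length(tasks) == 0L) stop_param("tasks must be non-empty")
  if (!is_count(early_stop_patience)) stop_param("patience must be >= 1")
  if (length(train_test_ratio) != 2L || any(train_test_ratio <= 0))
    stop_param("train_test_ratio must be two positive numbers")
  structure(list(tasks = intersect(c("aot", "permutation", "timewarp"), tasks),
                 base_lr = base_lr,
                 warmup_epochs = as.integer(warmup_epochs),
                 lr_scale_reference = as.integer(lr_scale_reference),
                 early_stop_patience = as.integer(early_stop_patience),
                 train_test_ratio = train_test_ratio / sum(train_test_ratio),
                 max_epochs = as.integer(max_epochs),
                 batches_per_epoch = as.integer(batches_per_epoch),
                 eval_batches = as.integer(eval_batches),
                 seed = as.integer(seed)),
            class = "harssl_pretrain_config")
}

#' Fine-tuning configuration
#'
#' Downstream training re-uses the pre-training setup where possible (Adam,
#' base learning rate, patience-5 early stopping — here monitored on
#' validation macro-F1) except for the batch size, which is re-adjusted per
#' dataset. Runs that fail a convergence check (validation macro-F1 at or
#' below 1.1 x chance) are retried with up to three random seeds and the best
#' validation model is kept.
#'
#' @param mode one of `"all_layers"` (load the trunk, train everything),
#'   `"head_only"` (load the trunk, freeze it, train the FC layers only), or
#'   `"scratch"` (random initialisation, ignore any checkpoint).
#' @param batch_size windows per step (dataset-dependent; default 64).
#' @param lr learning rate (default 1e-3, inherited from pre-training).
#' @param early_stop_patience early-stopping patience (default 5).
#' @param max_epochs epoch cap (default 15).
#' @param max_seeds random-seed retries on non-convergence (default 3).
#' @param seed base RNG seed.
#' @return A list of class `harssl_finetune_config`.
#' @export
finetune_config <- function(mode = c("all_layers", "head_only", "scratch"),
                            batch_size = 64L, lr = 1e-3,
                            early_stop_patience = 5L, max_epochs = 15L,
                            max_seeds = 3L, seed = 1L) {
  structure(list(mode = match.arg(mode),
                 batch_size = as.integer(batch_size), lr = lr,
                 early_stop_patience = as.integer(early_stop_patience),
                 max_epochs = as.integer(max_epochs),
                 max_seeds = as.integer(max_seeds),
                 seed = as.integer(seed)),
            class = "harssl_finetune_config")
}

#' Equal-weighted multi-task cross-entropy loss
#'
#' The cross-entropy is computed per task and all tasks are weighed equally:
#' the loss is the unweighted mean over enabled tasks of the per-task mean
#' binary cross-entropy. Uniform (0.5, 0.5) predictions give `log(2)` for any
#' number of tasks.
#'
#' @param logits_list named list (one entry per task) of B x 2 logit
#'   matrices, or B x 2 probability matrices if `probs = TRUE`.
#' @param labels B x n_tasks 0/1 matrix with matching column names.
#' @param probs interpret inputs as probabilities instead of logits.
#' @return Scalar loss.
#' @export
multitask_loss <- function(logits_list, labels, probs = FALSE) {
  tasks <- names(logits_list)
  if (is.null(tasks) || !all(tasks %in% colnames(labels)))
    stop_shape("logits and labels must name the same tasks")
  per_task <- vapply(tasks, function(task) {
    Z <- logits_list[[task]]
    if (nrow(Z) != nrow(labels) || ncol(Z) != 2L)
      stop_shape(sprintf("task %s: expected %d x 2 logits", task, nrow(labels)))
    P <- if (probs) Z else softmax_rows(Z)
    y <- labels[, task] + 1L
    -mean(log(pmax(P[cbind(seq_len(nrow(P)), y)], 1e-12)))
  }, numeric(1))
  mean(per_task)
}

#' Linearly scaled learning rate with burn-in
#'
#' The target rate is `base_lr * batch_windows / lr_scale_reference` (linear
#' scaling for large batches); during the first `warmup_epochs` epochs the
#' rate ramps linearly from `base_lr` at epoch 0 to the target, and is
#' constant at the target thereafter.
#'
#' @param epoch 0-based epoch index.
#' @param batch_windows windows per batch.
#' @param cfg a `harssl_pretrain_config`.
#' @return Learning rate for that epoch.
#' @export
lr_schedule <- function(epoch, batch_windows, cfg = pretrain_config()) {
  if (epoch < 0) stop_param("epoch must be >= 0")
  target <- cfg$base_lr * batch_windows / cfg$lr_scale_reference
  frac <- if (cfg$warmup_epochs > 0) min(epoch / cfg$warmup_epochs, 1) else 1
  cfg$base_lr + (target - cfg$base_lr) * frac
}

# Split subject ids train:test by the configured ratio (at least one test
# subject when 2+ subjects exist).
#' @noRd
split_subjects <- function(subject_ids, ratio) {
  n <- length(subject_ids)
  ids <- sample(subject_ids)
  n_test <- max(1L, round(n * ratio[2L]))
  if (n_test >= n) n_test <- n - 1L
  list(train = ids[seq_len(n - n_test)], test = ids[(n - n_test + 1L):n])
}

# One multi-task forward/backward/update step. Returns updated nets and loss.
#' @noRd
pretext_step <- function(net, batch, labels, opt, lr) {
  X <- batch_to_activation(batch)
  B <- n_windows(batch)
  fwd <- encoder_forward(net$encoder, X, B, training = TRUE)
  net$encoder$state <- fwd$state
  feats <- fwd$features
  n_tasks <- length(net$tasks)
  dfeats <- matrix(0, B, ncol(feats))
  loss <- 0
  head_grads <- list()
  for (task in net$tasks) {
    Wn <- paste0(task, ".W"); bn <- paste0(task, ".b")
    Z <- feats %*% net$heads[[Wn]] + rep(net$heads[[bn]], each = B)
    ce <- softmax_ce(Z, labels[, task] + 1L)
    loss <- loss + ce$loss / n_tasks
    dZ <- ce$dZ / n_tasks
    head_grads[[Wn]] <- crossprod(feats, dZ)
    head_grads[[bn]] <- colSums(dZ)
    dfeats <- dfeats + dZ %*% t(net$heads[[Wn]])
  }
  enc_grads <- encoder_backward(net$encoder, fwd, dfeats)
  upd <- adam_step(c(net$encoder$params, net$heads),
                   c(enc_grads, head_grads), opt, lr)
  np <- upd$params
  net$encoder$params <- np[names(net$encoder$params)]
  net$heads <- np[names(net$heads)]
  list(net = net, opt = upd$opt, loss = loss)
}

# Held-out evaluation: per-task accuracy and multi-task loss on freshly
# transformed batches drawn from the given pool under the given sampler.
#' @noRd
pretext_evaluate <- function(net, pool, tcfg, scfg, n_batches,
                             augment = TRUE) {
  tot_correct <- stats::setNames(numeric(length(net$tasks)), net$tasks)
  tot_n <- 0
  tot_loss <- 0
  for (i in seq_len(n_batches)) {
    raw <- assemble_batch(pool, scfg)
    pb <- make_pretext_batch(raw, tcfg, augment = augment)
    feats <- extract_features(net$encoder, pb$batch)
    logits <- pretext_forward(net, feats)
    tot_loss <- tot_loss + multitask_loss(logits, pb$labels)
    for (task in net$tasks) {
      pred <- max.col(logits[[task]], ties.method = "first") - 1L
      tot_correct[task] <- tot_correct[task] + sum(pred == pb$labels[, task])
    }
    tot_n <- tot_n + n_windows(pb$batch)
  }
  list(accuracy = tot_correct / tot_n, loss = tot_loss / n_batches)
}

#' Multi-task self-supervised pre-training
#'
#' Subjects are split 8:2 into train and held-out sets. Each epoch assembles
#' movement-weighted batches, applies the pretext transformations with binary
#' self-labels, and takes Adam steps at the scheduled learning rate; after
#' each epoch per-task accuracy and mean loss are measured on batches drawn
#' from the held-out subjects under the same sampling policy. Training stops
#' when the held-out loss fails to improve for `early_stop_patience` epochs;
#' the best-held-out checkpoint is returned.
#'
#' @param pool named per-subject list of per-day `harssl_window_batch` lists
#'   (see [cohort_to_pool()]).
#' @param tcfg transform configuration ([transform_config()]); its `tasks`
#'   are overridden by `pcfg$tasks`.
#' @param scfg sampler configuration ([sampler_config()]).
#' @param pcfg pre-training configuration ([pretrain_config()]).
#' @param ecfg encoder configuration ([encoder_config()]).
#' @param weighted use movement-weighted window sampling (default TRUE);
#'   FALSE samples uniformly (the ablation contrast).
#' @param augment apply the random axis swap/rotation augmentation before
#'   the pretext transformations (default TRUE; single-task desk-scale
#'   ablations may disable it).
#' @return A list of class `harssl_checkpoint`: `encoder`, `heads`, `history`
#'   (per-epoch data frame), `best_epoch`, configs and seed.
#' @export
pretrain <- function(pool, tcfg = transform_config(),
                     scfg = sampler_config(), pcfg = pretrain_config(),
                     ecfg = encoder_config(), weighted = TRUE,
                     augment = TRUE) {
  if (length(pool) < 2L) stop_data("need at least 2 subjects to split 8:2")
  set.seed(pcfg$seed)
  tcfg$tasks <- pcfg$tasks
  if (!weighted) scfg$weight_floor <- Inf # every day falls back to uniform
  sp <- split_subjects(names(pool), pcfg$train_test_ratio)
  train_pool <- pool[sp$train]
  test_pool <- pool[sp$test]

  net <- attach_pretext_heads(build_encoder(ecfg), pcfg$tasks)
  opt <- adam_init(c(net$encoder$params, net$heads))
  batch_windows <- min(scfg$subjects_per_batch, length(train_pool)) *
    scfg$windows_per_subject
  history <- list()
  best_loss <- Inf
  best <- list(encoder = net$encoder, heads = net$heads, epoch = 0L)
  stale <- 0L

  for (epoch in seq_len(pcfg$max_epochs) - 1L) {
    lr <- lr_schedule(epoch, batch_windows, pcfg)
    train_loss <- 0
    for (i in seq_len(pcfg$batches_per_epoch)) {
      raw <- assemble_batch(train_pool, scfg)
      pb <- make_pretext_batch(raw, tcfg, augment = augment)
      stp <- pretext_step(net, pb$batch, pb$labels, opt, lr)
      net <- stp$net; opt <- stp$opt
      if (!is.finite(stp$loss))
        stop_data(sprintf(
          "non-finite loss at epoch %d (lr %.3g, batch of %d windows)",
          epoch, lr, n_windows(pb$batch)))
      train_loss <- train_loss + stp$loss
    }
    ev <- pretext_evaluate(net, test_pool, tcfg, scfg, pcfg$eval_batches,
                           augment = augment)
    history[[length(history) + 1L]] <- data.frame(
      epoch = epoch, lr = lr,
      train_loss = train_loss / pcfg$batches_per_epoch,
      heldout_loss = ev$loss,
      t(ev$accuracy))
    if (ev$loss < best_loss - 1e-6) {
      best_loss <- ev$loss
      best <- list(encoder = net$encoder, heads = net$heads, epoch = epoch)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= pcfg$early_stop_patience) break
    }
  }
  history <- do.call(rbind, history)
  names(history) <- sub("^X", "", names(history))
  structure(list(encoder = best$encoder, heads = best$heads,
                 best_epoch = best$epoch, history = history,
                 tasks = pcfg$tasks, weighted = weighted,
                 ecfg = ecfg, pcfg = pcfg, scfg = scfg, tcfg = tcfg,
                 seed = pcfg$seed),
            class = "harssl_checkpoint")
}

# Integer labels (1..K) for a labelled batch against a fixed class list.
#' @noRd
batch_class_ids <- function(batch, class_names) {
  y <- match(batch$labels, class_names)
  if (anyNA(y)) stop_data("batch contains labels outside the class list")
  y
}

# One supervised epoch over shuffled mini-batches; returns updated model.
#' @noRd
supervised_epoch <- function(clf, batch, y, fcfg, opt, freeze_trunk) {
  B <- n_windows(batch)
  ord <- sample.int(B)
  for (start in seq(1L, B, by = fcfg$batch_size)) {
    idx <- ord[start:min(start + fcfg$batch_size - 1L, B)]
    if (length(idx) < 2L) next # batch norm needs 2+ rows
    mb <- subset_batch(batch, idx)
    X <- batch_to_activation(mb)
    nb <- length(idx)
    if (freeze_trunk) {
      feats <- encoder_forward(clf$encoder, X, nb, training = FALSE)$features
      hc <- classifier_head_forward(clf, feats)
      ce <- softmax_ce(hc$logits, y[idx])
      hg <- classifier_head_backward(clf, hc, ce$dZ)
      hg$dfeats <- NULL
      upd <- adam_step(clf$heads, hg, opt, fcfg$lr)
      clf$heads <- upd$params; opt <- upd$opt
    } else {
      fwd <- encoder_forward(clf$encoder, X, nb, training = TRUE)
      clf$encoder$state <- fwd$state
      hc <- classifier_head_forward(clf, fwd$features)
      ce <- softmax_ce(hc$logits, y[idx])
      hg <- classifier_head_backward(clf, hc, ce$dZ)
      eg <- encoder_backward(clf$encoder, fwd, hg$dfeats)
      hg$dfeats <- NULL
      upd <- adam_step(c(clf$encoder$params, clf$heads), c(eg, hg), opt,
                       fcfg$lr)
      np <- upd$params
      clf$encoder$params <- np[names(clf$encoder$params)]
      clf$heads <- np[names(clf$heads)]
      opt <- upd$opt
    }
  }
  list(clf = clf, opt = opt)
}

#' @noRd
finetune_once <- function(checkpoint, splits, fcfg, ecfg, class_names, seed) {
  set.seed(seed)
  encoder <- if (fcfg$mode == "scratch" || is.null(checkpoint)) {
    build_encoder(ecfg)
  } else {
    checkpoint$encoder
  }
  clf <- attach_downstream_head(encoder, length(class_names), class_names)
  freeze <- fcfg$mode == "head_only"
  opt <- adam_init(if (freeze) clf$heads
                   else c(clf$encoder$params, clf$heads))
  y_train <- batch_class_ids(splits$train, class_names)
  best_f1 <- -Inf
  best_clf <- clf
  stale <- 0L
  history <- list()
  for (epoch in seq_len(fcfg$max_epochs) - 1L) {
    se <- supervised_epoch(clf, splits$train, y_train, fcfg, opt, freeze)
    clf <- se$clf; opt <- se$opt
    val_pred <- predict(clf, splits$val)
    vf1 <- macro_f1(val_pred, splits$val$labels)
    history[[length(history) + 1L]] <- data.frame(epoch = epoch,
                                                  val_macro_f1 = vf1)
    if (vf1 > best_f1 + 1e-9) {
      best_f1 <- vf1; best_clf <- clf; stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= fcfg$early_stop_patience) break
    }
  }
  list(clf = best_clf, val_f1 = best_f1, history = do.call(rbind, history),
       seed = seed)
}

#' Fine-tune a classifier on labelled windows
#'
#' Three regimes: `all_layers` loads the pre-trained trunk and trains
#' everything; `head_only` loads the trunk, freezes it and trains only the
#' 1024 -> 512 -> softmax head; `scratch` trains from random initialisation,
#' ignoring any checkpoint. Early stopping monitors validation macro-F1 with
#' the configured patience. If the best validation macro-F1 does not exceed
#' 1.1 x the chance level (majority-class frequency in validation truth), the
#' run is retried with up to `max_seeds` seeds and the best validation model
#' is kept.
#'
#' @param checkpoint a `harssl_checkpoint` from [pretrain()], or NULL
#'   (required NULL-tolerant only for `mode = "scratch"`).
#' @param splits list with `train`, `val`, `test` labelled
#'   `harssl_window_batch` objects; subject-disjoint.
#' @param fcfg a `harssl_finetune_config`.
#' @param ecfg encoder configuration used when no checkpoint is loaded.
#' @return A list of class `harssl_finetuned`: `clf`, `history`,
#'   `val_f1`, `seeds_tried`, `mode`.
#' @export
finetune <- function(checkpoint, splits, fcfg = finetune_config(),
                     ecfg = if (!is.null(checkpoint)) checkpoint$ecfg
                            else encoder_config()) {
  if (is.null(checkpoint) && fcfg$mode != "scratch")
    stop_param(sprintf("mode '%s' requires a checkpoint", fcfg$mode))
  for (part in c("train", "val", "test")) {
    if (is.null(splits[[part]]) || is.null(splits[[part]]$labels))
      stop_data(sprintf("labelled '%s' split required", part))
  }
  tr_sub <- unique(splits$train$subject_ids)
  if (length(intersect(tr_sub, unique(splits$val$subject_ids))) ||
      length(intersect(tr_sub, unique(splits$test$subject_ids))) ||
      length(intersect(unique(splits$val$subject_ids),
                       unique(splits$test$subject_ids))))
    stop_data("train/val/test splits must be subject-disjoint")
  class_names <- sort(unique(splits$train$labels))
  extra <- setdiff(unique(c(splits$val$labels, splits$test$labels)),
                   class_names)
  if (length(extra) > 0L)
    stop_data(paste0("classes absent from training data: ",
                     paste(extra, collapse = ", "),
                     " (bad split or missing class filtering)"))
  chance <- max(table(splits$val$labels)) / n_windows(splits$val)
  runs <- list()
  for (s in seq_len(fcfg$max_seeds)) {
    runs[[s]] <- finetune_once(checkpoint, splits, fcfg, ecfg, class_names,
                               seed = fcfg$seed + (s - 1L))
    if (runs[[s]]$val_f1 > 1.1 * chance) break
  }
  best <- runs[[which.max(vapply(runs, function(r) r$val_f1, numeric(1)))]]
  structure(list(clf = best$clf, history = best$history,
                 val_f1 = best$val_f1, seeds_tried = length(runs),
                 mode = fcfg$mode, class_names = class_names),
            class = "harssl_finetuned")
}
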