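test_that("multi-task loss equals its closed forms", {
  # uniform (0.5, 0.5) predictions -> ln 2, independent of task count
  for (k in 1:3) {
    tasks <- c("aot", "permutation", "timewarp")[1:k]
    n <- 10
    logits <- lapply(setNames(tasks, tasks),
                     function(t) matrix(0, n, 2))
    labels <- matrix(rbinom(n * k, 1, 0.5), n, k,
                     dimnames = list(NULL, tasks))
    expect_equal(multitask_loss(logits, labels), log(2), tolerance = 1e-12)
  }

  # perfect one-hot predictions -> loss ~ 0 under probability clamping
  labels <- matrix(c(1L, 0L, 1L), 3, 1, dimnames = list(NULL, "aot"))
  perfect <- list(aot = cbind(c(0, 1, 0), c(1, 0, 1)))
  expect_lt(multitask_loss(perfect, labels, probs = TRUE), 1e-7)

  # equal weighting: per-task mean CEs 0.2 and 0.6 average to 0.4
  p1 <- exp(-0.2); p2 <- exp(-0.6)
  two <- list(aot = cbind(p1, 1 - p1), permutation = cbind(p2, 1 - p2))
  lab2 <- matrix(0L, 1, 2, dimnames = list(NULL, c("aot", "permutation")))
  expect_equal(multitask_loss(two, lab2, probs = TRUE), 0.4,
               tolerance = 1e-12)

  expect_error(multitask_loss(list(aot = matrix(0, 2, 2)),
                              matrix(0, 2, 1,
                                     dimnames = list(NULL, "permutation"))),
               class = "harssl_shape_error")
})

test_that("learning-rate schedule scales linearly with burn-in", {
  cfg <- pretrain_config()
  # reference batch -> base rate at every epoch
  for (e in c(0, 3, 5, 12)) {
    expect_equal(lr_schedule(e, 1500, cfg), 1e-3)
  }
  # 6000-window batch -> target 4e-3 from epoch 5 onwards
  expect_equal(lr_schedule(5, 6000, cfg), 4e-3)
  expect_equal(lr_schedule(9, 6000, cfg), 4e-3)
  # epoch 0 starts at the base rate; the ramp is linear and continuous
  expect_equal(lr_schedule(0, 6000, cfg), 1e-3)
  expect_equal(lr_schedule(2, 6000, cfg), 1e-3 + (4e-3 - 1e-3) * 2 / 5)
  expect_equal(lr_schedule(5 - 1e-9, 6000, cfg), 4e-3, tolerance = 1e-6)
})

test_that("pretraining early-stops on schedule and is seed-reproducible", {
  set.seed(1)
  cohort <- simulate_cohort(sim_config(4, day_seconds = 400, seed = 5,
                                       stationary_fraction = 0.4))
  pool <- cohort_to_pool(cohort, day_seconds = 400)
  ecfg <- toy_encoder_config(width = 2L)
  scfg <- sampler_config(2L, 8L)
  pcfg <- pretrain_config(tasks = "aot", max_epochs = 12L,
                          batches_per_epoch = 2L, eval_batches = 1L,
                          early_stop_patience = 2L,
                          lr_scale_reference = 16L, seed = 3L)
  ck <- pretrain(pool, transform_config(), scfg, pcfg, ecfg)
  expect_s3_class(ck, "harssl_checkpoint")
  # halts exactly patience epochs after the best held-out epoch (or at cap)
  hist <- ck$history
  if (nrow(hist) < pcfg$max_epochs) {
    expect_equal(nrow(hist) - 1L, ck$best_epoch + pcfg$early_stop_patience)
  }
  expect_true(all(is.finite(hist$train_loss)))
  expect_true(all(is.finite(hist$heldout_loss)))

  ck2 <- pretrain(pool, transform_config(), scfg, pcfg, ecfg)
  expect_identical(ck$history, ck2$history)
})

test_that("fine-tuning honours mode contracts", {
  set.seed(2)
  cohort <- simulate_cohort(sim_config(6, day_seconds = 300,
                                       stationary_fraction = 0.3, seed = 8))
  wb <- cohort_windows(cohort)
  ids <- sort(unique(wb$subject_ids))
  splits <- list(
    train = subset_batch(wb, which(wb$subject_ids %in% ids[1:4])),
    val = subset_batch(wb, which(wb$subject_ids == ids[5])),
    test = subset_batch(wb, which(wb$subject_ids == ids[6])))
  # align class lists across splits for this small fixture
  common <- Reduce(intersect, list(unique(splits$train$labels),
                                   unique(splits$val$labels),
                                   unique(splits$test$labels)))
  for (p in names(splits)) {
    keep <- splits[[p]]$labels %in% common
    splits[[p]] <- subset_batch(splits[[p]], which(keep))
  }
  ecfg <- toy_encoder_config(width = 2L)
  pool <- cohort_to_pool(simulate_cohort(sim_config(4, day_seconds = 300,
                                                    seed = 9)),
                         day_seconds = 300)
  pcfg <- pretrain_config(tasks = "aot", max_epochs = 2L,
                          batches_per_epoch = 2L, eval_batches = 1L,
                          lr_scale_reference = 16L, seed = 4L)
  ck <- pretrain(pool, transform_config(), sampler_config(2L, 8L), pcfg, ecfg)

  # head_only: trunk bitwise identical before and after
  ft <- finetune(ck, splits, finetune_config("head_only", batch_size = 32L,
                                             max_epochs = 2L, max_seeds = 1L),
                 ecfg)
  expect_identical(ft$clf$encoder$params, ck$encoder$params)

  # scratch ignores the checkpoint: initial weights differ
  ft2 <- finetune(ck, splits, finetune_config("scratch", batch_size = 32L,
                                              max_epochs = 1L, max_seeds = 1L),
                  ecfg)
  expect_false(identical(ft2$clf$encoder$params$stem.W, ck$encoder$params$stem.W))

  # predictions have one label per window, from the training classes
  pred <- predict(ft$clf, splits$test)
  expect_length(pred, n_windows(splits$test))
  expect_true(all(pred %in% unique(splits$train$labels)))

  # subject-overlapping splits are rejected
  bad <- splits; bad$val <- splits$train
  expect_error(finetune(ck, bad, finetune_config("head_only")),
               class = "harssl_data_error")

  # classes missing from training are a data error
  bad2 <- splits
  bad2$train <- subset_batch(splits$train,
                             which(splits$train$labels !=
                                     splits$train$labels[1]))
  expect_error(finetune(ck, bad2, finetune_config("head_only")),
               class = "harssl_data_error")

  # scratch is mandatory without a checkpoint
  expect_error(finetune(NULL, splits, finetune_config("all_layers")),
               class = "harssl_parameter_error")
})

test_that("checkpoints, history tables and manifests round-trip", {
  dir <- withr::local_tempdir()
  set.seed(3)
  pool <- cohort_to_pool(simulate_cohort(sim_config(3, day_seconds = 300,
                                                    seed = 11)),
                         day_seconds = 300)
  pcfg <- pretrain_config(tasks = c("aot", "timewarp"), max_epochs = 1L,
                          batches_per_epoch = 1L, eval_batches = 1L,
                          lr_scale_reference = 8L, seed = 2L)
  ck <- pretrain(pool, transform_config(), sampler_config(2L, 4L), pcfg,
                 toy_encoder_config(width = 2L))
  path <- file.path(dir, "run1_best.ckpt")
  save_checkpoint(ck, path)
  expect_true(file.exists(paste0(path, ".model_card.json")))
  card <- jsonlite::read_json(paste0(path, ".model_card.json"))
  expect_equal(card$encoder$layers, 18)
  ck2 <- load_checkpoint(path)
  expect_identical(ck2$encoder$params, ck$encoder$params)

  hist_path <- file.path(dir, "history.tsv")
  write_history_tsv(ck$history, hist_path)
  expect_true(file.exists(hist_path))
  tab <- read.delim(hist_path)
  expect_setequal(unique(tab$metric), setdiff(names(ck$history), "epoch"))

  man <- file.path(dir, "run.yaml")
  write_run_manifest(list(pretrain = pcfg, sampler = sampler_config()), man)
  got <- yaml::read_yaml(man)
  expect_equal(got$pretrain$seed, 2L)
})
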