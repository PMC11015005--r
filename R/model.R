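#' Encoder configuration for the 18-layer 1D ResNet-V2 trunk
#'
#' The trunk is a pre-activation residual network with 1D convolutions: a stem
#' convolution (3 -> w channels, stride 2), four stages of two pre-activation
#' residual blocks with channel widths (w, 2w, 4w, 8w) and stride-2
#' downsampling plus a 1x1 projection shortcut at each stage entry, a final
#' batch-norm/ReLU, global average pooling over time, and a linear projection
#' to the 1024-dimensional feature vector. Counting the stem, the 16 block
#' convolutions and the feature projection gives 18 weighted layers
#' (projection shortcuts and batch-norm parameters are not counted as
#' layers). At the default base width of 78 the trunk holds 9,977,458
#' trainable parameters, which rounds to the 10M budget.
#'
#' @param input_len window length in samples (default 300 = 30 Hz x 10 s).
#' @param n_channels input channels (3 accelerometer axes).
#' @param kernel_size convolution kernel length (default 5).
#' @param base_width stage-1 channel width w; stages use (w, 2w, 4w, 8w)
#'   (default 78).
#' @param blocks_per_stage residual blocks per stage (default 2).
#' @param feature_dim output feature dimension (default 1024).
#' @param param_budget target trainable-parameter count; the build fails if
#'   the realised count falls outside `[0.95, 1.05) x param_budget`. Set to
#'   `NULL` to disable (reduced-width encoders for desk-scale tests).
#' @return A list of class `harssl_encoder_config`.
#' @export
encoder_config <- function(input_len = 300L, n_channels = 3L,
                           kernel_size = 5L, base_width = 78L,
                           blocks_per_stage = 2L, feature_dim = 1024L,
                           param_budget = 1e7) {
  if (!is_count(input_len)) stop_param("input_len must be a positive integer")
  if (!is_count(kernel_size)) stop_param("kernel_size must be a positive integer")
  if (!is_count(base_width)) stop_param("base_width must be a positive integer")
  if (!identical(as.integer(blocks_per_stage), 2L))
    stop_param("this trunk is fixed at 2 blocks per stage (18 layers)")
  structure(list(input_len = as.integer(input_len),
                 n_channels = as.integer(n_channels),
                 kernel_size = as.integer(kernel_size),
                 base_width = as.integer(base_width),
                 stage_widths = as.integer(base_width) * c(1L, 2L, 4L, 8L),
                 blocks_per_stage = 2L,
                 feature_dim = as.integer(feature_dim),
                 param_budget = param_budget),
            class = "harssl_encoder_config")
}

# Stage/block descriptors shared by init, forward/backward and the
# independent layer/parameter accounting.
#' @noRd
encoder_layout <- function(cfg) {
  blocks <- list()
  c_in <- cfg$base_width # after stem
  for (s in 1:4) {
    c_out <- cfg$stage_widths[s]
    for (b in 1:2) {
      blocks[[length(blocks) + 1L]] <- list(
        name = sprintf("s%d.b%d", s, b),
        c_in = if (b == 1L) c_in else c_out,
        c_out = c_out,
        stride = if (b == 1L) 2L else 1L,
        proj = (b == 1L))
    }
    c_in <- c_out
  }
  blocks
}

#' @noRd
init_encoder_params <- function(cfg) {
  k <- cfg$kernel_size
  p <- list()
  p[["stem.W"]] <- he_init(k * cfg$n_channels, cfg$base_width,
                           k * cfg$n_channels)
  for (bl in encoder_layout(cfg)) {
    nm <- bl$name
    p[[paste0(nm, ".bn1.gamma")]] <- rep(1, bl$c_in)
    p[[paste0(nm, ".bn1.beta")]] <- rep(0, bl$c_in)
    p[[paste0(nm, ".conv1.W")]] <- he_init(k * bl$c_in, bl$c_out, k * bl$c_in)
    p[[paste0(nm, ".bn2.gamma")]] <- rep(1, bl$c_out)
    p[[paste0(nm, ".bn2.beta")]] <- rep(0, bl$c_out)
    p[[paste0(nm, ".conv2.W")]] <- he_init(k * bl$c_out, bl$c_out,
                                           k * bl$c_out)
    if (bl$proj)
      p[[paste0(nm, ".proj.W")]] <- he_init(bl$c_in, bl$c_out, bl$c_in)
  }
  w8 <- cfg$stage_widths[4L]
  p[["head.bn.gamma"]] <- rep(1, w8)
  p[["head.bn.beta"]] <- rep(0, w8)
  p[["head.fc.W"]] <- he_init(w8, cfg$feature_dim, w8)
  p[["head.fc.b"]] <- rep(0, cfg$feature_dim)
  p
}

#' @noRd
init_bn_state <- function(params) {
  st <- list()
  for (nm in names(params)) {
    if (grepl("\\.gamma$", nm)) {
      base <- sub("\\.gamma$", "", nm)
      st[[paste0(base, ".mean")]] <- rep(0, length(params[[nm]]))
      st[[paste0(base, ".var")]] <- rep(1, length(params[[nm]]))
    }
  }
  st
}

#' Count trainable parameters of a network
#'
#' Exact count of trainable scalars (weights, biases, batch-norm scales and
#' shifts; running statistics are buffers, not parameters).
#'
#' @param net an encoder (from [build_encoder()]), a classifier or head
#'   structure, or a bare named list of parameter arrays.
#' @return Integer parameter count.
#' @export
count_parameters <- function(net) {
  if (inherits(net, "harssl_classifier") || inherits(net, "harssl_multitask_net"))
    return(count_parameters(net$encoder) +
             sum(vapply(net$heads, length, numeric(1))))
  params <- if (!is.null(net$params)) net$params else net
  sum(vapply(params, length, numeric(1)))
}

#' Number of weighted layers of the trunk
#'
#' Convention: stem convolution + 16 residual-block convolutions + the
#' feature projection; shortcut 1x1 projections and batch norms are not
#' counted.
#'
#' @param encoder an encoder from [build_encoder()].
#' @return Integer layer count (18 for this trunk).
#' @export
encoder_layer_count <- function(encoder) {
  1L + 2L * length(encoder_layout(encoder$cfg)) + 1L
}

#' Build the 1D ResNet-V2 encoder trunk
#'
#' Initialises the trunk described in [encoder_config()]. Initialisation is
#' He-normal and reproducible under `set.seed`. If the configuration carries
#' a parameter budget, the realised trainable-parameter count must round to
#' it (within [0.95, 1.05) of the budget), otherwise a configuration error
#' naming the count is raised.
#'
#' @param cfg a `harssl_encoder_config`.
#' @return A list of class `harssl_encoder` with `params` (named list of
#'   trainable arrays), `state` (batch-norm running statistics) and `cfg`.
#' @export
build_encoder <- function(cfg = encoder_config()) {
  stopifnot(inherits(cfg, "harssl_encoder_config"))
  params <- init_encoder_params(cfg)
  enc <- structure(list(params = params, state = init_bn_state(params),
                        cfg = cfg),
                   class = "harssl_encoder")
  if (!is.null(cfg$param_budget)) {
    n <- count_parameters(enc)
    if (n < 0.95 * cfg$param_budget || n >= 1.05 * cfg$param_budget)
      stop_config(sprintf(
        "encoder has %d trainable parameters; budget %g requires [%g, %g)",
        n, cfg$param_budget, 0.95 * cfg$param_budget, 1.05 * cfg$param_budget))
  }
  enc
}

#' @export
print.harssl_encoder <- function(x, ...) {
  cat(sprintf("<ResNet-V2 1D encoder> %d layers, %s parameters, %d-d features\n",
              encoder_layer_count(x),
              format(count_parameters(x), big.mark = ","),
              x$cfg$feature_dim))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Forward / backward.

# X: (B*L) x 3 activation matrix. Returns features (B x feature_dim), caches
# for backward when training, and updated batch-norm state.
#' @noRd
encoder_forward <- function(enc, X, B, training = FALSE) {
  cfg <- enc$cfg
  p <- enc$params
  st <- enc$state
  k <- cfg$kernel_size
  pad <- (k - 1L) %/% 2L
  L <- nrow(X) / B
  caches <- list()

  stem_in <- X
  Xc <- conv_fwd(X, p[["stem.W"]], B, L, k, 2L, pad)
  Lc <- conv_out_len(L, k, 2L, pad)
  caches$stem <- list(X = stem_in, L = L)

  for (bl in encoder_layout(cfg)) {
    nm <- bl$name
    b1 <- bn_fwd(Xc, p[[paste0(nm, ".bn1.gamma")]], p[[paste0(nm, ".bn1.beta")]],
                 st[[paste0(nm, ".bn1.mean")]], st[[paste0(nm, ".bn1.var")]],
                 training)
    st[[paste0(nm, ".bn1.mean")]] <- b1$run_mean
    st[[paste0(nm, ".bn1.var")]] <- b1$run_var
    h1 <- pmax(b1$Y, 0)
    c1 <- conv_fwd(h1, p[[paste0(nm, ".conv1.W")]], B, Lc, k, bl$stride, pad)
    L1 <- conv_out_len(Lc, k, bl$stride, pad)
    b2 <- bn_fwd(c1, p[[paste0(nm, ".bn2.gamma")]], p[[paste0(nm, ".bn2.beta")]],
                 st[[paste0(nm, ".bn2.mean")]], st[[paste0(nm, ".bn2.var")]],
                 training)
    st[[paste0(nm, ".bn2.mean")]] <- b2$run_mean
    st[[paste0(nm, ".bn2.var")]] <- b2$run_var
    h2 <- pmax(b2$Y, 0)
    c2 <- conv_fwd(h2, p[[paste0(nm, ".conv2.W")]], B, L1, k, 1L, pad)
    short <- if (bl$proj) {
      conv_fwd(h1, p[[paste0(nm, ".proj.W")]], B, Lc, 1L, bl$stride, 0L)
    } else Xc
    out <- c2 + short
    if (training) {
      caches[[nm]] <- list(Xin = Xc, Lin = Lc, bn1 = b1$cache, h1 = h1,
                           a1pos = b1$Y > 0, c1 = c1, L1 = L1,
                           bn2 = b2$cache, h2 = h2, a2pos = b2$Y > 0,
                           proj = bl$proj, stride = bl$stride)
    }
    Xc <- out
    Lc <- L1
  }

  bh <- bn_fwd(Xc, p[["head.bn.gamma"]], p[["head.bn.beta"]],
               st[["head.bn.mean"]], st[["head.bn.var"]], training)
  st[["head.bn.mean"]] <- bh$run_mean
  st[["head.bn.var"]] <- bh$run_var
  hh <- pmax(bh$Y, 0)
  g <- gap_fwd(hh, B, Lc)
  feats <- g %*% p[["head.fc.W"]] + rep(p[["head.fc.b"]], each = B)
  if (training) {
    caches$head <- list(Xin = Xc, Lout = Lc, bn = bh$cache, apos = bh$Y > 0,
                        hh = hh, g = g, B = B)
  }
  list(features = feats, caches = caches, state = st, B = B)
}

# dF: B x feature_dim gradient at the features. Returns named grads.
#' @noRd
encoder_backward <- function(enc, fwd, dF) {
  cfg <- enc$cfg
  p <- enc$params
  k <- cfg$kernel_size
  pad <- (k - 1L) %/% 2L
  caches <- fwd$caches
  B <- fwd$B
  grads <- list()

  hc <- caches$head
  grads[["head.fc.W"]] <- crossprod(hc$g, dF)
  grads[["head.fc.b"]] <- colSums(dF)
  dg <- dF %*% t(p[["head.fc.W"]])
  dh <- gap_bwd(dg, B, hc$Lout)
  dh[!hc$apos] <- 0
  bb <- bn_bwd(dh, hc$bn)
  grads[["head.bn.gamma"]] <- bb$dgamma
  grads[["head.bn.beta"]] <- bb$dbeta
  dXc <- bb$dX

  for (bl in rev(encoder_layout(cfg))) {
    nm <- bl$name
    cc <- caches[[nm]]
    dout <- dXc
    g2 <- conv_bwd(cc$h2, p[[paste0(nm, ".conv2.W")]], dout, B, cc$L1, k, 1L, pad)
    grads[[paste0(nm, ".conv2.W")]] <- g2$dW
    dh2 <- g2$dX
    dh2[!cc$a2pos] <- 0
    b2 <- bn_bwd(dh2, cc$bn2)
    grads[[paste0(nm, ".bn2.gamma")]] <- b2$dgamma
    grads[[paste0(nm, ".bn2.beta")]] <- b2$dbeta
    g1 <- conv_bwd(cc$h1, p[[paste0(nm, ".conv1.W")]], b2$dX, B, cc$Lin, k,
                   cc$stride, pad)
    grads[[paste0(nm, ".conv1.W")]] <- g1$dW
    dh1 <- g1$dX
    if (cc$proj) {
      gp <- conv_bwd(cc$h1, p[[paste0(nm, ".proj.W")]], dout, B, cc$Lin, 1L,
                     cc$stride, 0L)
      grads[[paste0(nm, ".proj.W")]] <- gp$dW
      dh1 <- dh1 + gp$dX
    }
    dh1[!cc$a1pos] <- 0
    b1 <- bn_bwd(dh1, cc$bn1)
    grads[[paste0(nm, ".bn1.gamma")]] <- b1$dgamma
    grads[[paste0(nm, ".bn1.beta")]] <- b1$dbeta
    dXc <- b1$dX
    if (!cc$proj) dXc <- dXc + dout
  }

  gs <- conv_bwd(caches$stem$X, p[["stem.W"]], dXc, B, caches$stem$L, k, 2L, pad)
  grads[["stem.W"]] <- gs$dW
  grads
}

# ---------------------------------------------------------------------------
# Heads.

#' Attach binary pretext heads to a trunk
#'
#' One independent 2-way softmax readout (feature_dim -> 2) per enabled task,
#' all reading the same shared feature vector.
#'
#' @param encoder a `harssl_encoder`.
#' @param tasks character vector of enabled pretext tasks.
#' @return A list of class `harssl_multitask_net` with the trunk and one head
#'   per task.
#' @export
attach_pretext_heads <- function(encoder, tasks) {
  if (length(tasks) == 0L) stop_param("at least one pretext task required")
  fd <- encoder$cfg$feature_dim
  heads <- list()
  for (task in tasks) {
    heads[[paste0(task, ".W")]] <- he_init(fd, 2L, fd)
    heads[[paste0(task, ".b")]] <- rep(0, 2L)
  }
  structure(list(encoder = encoder, heads = heads, tasks = tasks),
            class = "harssl_multitask_net")
}

#' Attach the downstream classification head to a trunk
#'
#' A fully connected layer of 512 units (ReLU) between the feature extractor
#' and the softmax readout; this structure is fixed for all downstream
#' evaluations.
#'
#' @param encoder a `harssl_encoder`.
#' @param n_classes number of activity classes (>= 2).
#' @param class_names optional class name vector of length `n_classes`.
#' @param hidden hidden width (default 512).
#' @return A list of class `harssl_classifier`.
#' @export
attach_downstream_head <- function(encoder, n_classes, class_names = NULL,
                                   hidden = 512L) {
  if (!is_count(n_classes, 2L)) stop_param("n_classes must be >= 2")
  fd <- encoder$cfg$feature_dim
  heads <- list(fc1.W = he_init(fd, hidden, fd),
                fc1.b = rep(0, hidden),
                fc2.W = he_init(hidden, n_classes, hidden),
                fc2.b = rep(0, n_classes))
  structure(list(encoder = encoder, heads = heads,
                 n_classes = as.integer(n_classes),
                 class_names = class_names %||% as.character(seq_len(n_classes)),
                 hidden = as.integer(hidden)),
            class = "harssl_classifier")
}

# Batch windows (B x L x 3) -> (B*L) x 3 activation matrix.
#' @noRd
batch_to_activation <- function(batch) {
  win <- batch$windows
  B <- dim(win)[1L]; L <- dim(win)[2L]
  X <- matrix(0, B * L, 3L)
  for (a in 1:3) X[, a] <- as.vector(t(win[, , a]))
  X
}

#' Extract encoder features for a batch of windows
#'
#' Deterministic inference-mode forward pass (batch norm uses running
#' statistics, so single-window and batched calls agree).
#'
#' @param encoder a `harssl_encoder`.
#' @param batch a `harssl_window_batch`.
#' @return A `B x feature_dim` numeric matrix.
#' @export
extract_features <- function(encoder, batch) {
  L <- dim(batch$windows)[2L]
  if (L != encoder$cfg$input_len)
    stop_shape(sprintf("window length %d != encoder input_len %d",
                       L, encoder$cfg$input_len))
  X <- batch_to_activation(batch)
  encoder_forward(encoder, X, n_windows(batch), training = FALSE)$features
}

# Pretext heads forward: features -> per-task logits (list of B x 2).
#' @noRd
pretext_forward <- function(net, feats) {
  lapply(stats::setNames(net$tasks, net$tasks), function(task) {
    feats %*% net$heads[[paste0(task, ".W")]] +
      rep(net$heads[[paste0(task, ".b")]], each = nrow(feats))
  })
}

# Downstream head forward; caches for backward.
#' @noRd
classifier_head_forward <- function(clf, feats) {
  h <- feats %*% clf$heads$fc1.W + rep(clf$heads$fc1.b, each = nrow(feats))
  hr <- pmax(h, 0)
  logits <- hr %*% clf$heads$fc2.W + rep(clf$heads$fc2.b, each = nrow(feats))
  list(logits = logits, hr = hr, hpos = h > 0, feats = feats)
}

#' @noRd
classifier_head_backward <- function(clf, cache, dlogits) {
  grads <- list(fc2.W = crossprod(cache$hr, dlogits),
                fc2.b = colSums(dlogits))
  dh <- dlogits %*% t(clf$heads$fc2.W)
  dh[!cache$hpos] <- 0
  grads$fc1.W <- crossprod(cache$feats, dh)
  grads$fc1.b <- colSums(dh)
  grads$dfeats <- dh %*% t(clf$heads$fc1.W)
  grads
}

#' Predict activity classes for a batch
#'
#' @param object a `harssl_classifier`.
#' @param batch a `harssl_window_batch`.
#' @param ... unused.
#' @return Character vector of predicted class names, one per window.
#' @export
predict.harssl_classifier <- function(object, batch, ...) {
  feats <- extract_features(object$encoder, batch)
  logits <- classifier_head_forward(object, feats)$logits
  object$class_names[max.col(logits, ties.method = "first")]
}
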