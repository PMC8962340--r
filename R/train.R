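# Training of the patch classifier: augmentation, Adam with inverse-time
# learning-rate decay, early stopping on validation loss, batched prediction.

#' Data augmentation settings
#'
#' The three investigated augmentation methods: right-angle rotation, additive
#' Gaussian noise (parameterised by its 3-sigma bound on preprocessed
#' intensities) and random occlusion of a contiguous square.
#'
#' @param rotations Subset of `c(90, 180, 270)` degrees; a rotation is drawn
#'   uniformly from `{0} + rotations` per sample. Empty = no rotation.
#' @param gaussian_3sigma Three-sigma bound of the additive noise (0 = off;
#'   the investigated non-zero value is 0.00625, i.e. sigma = 0.00625/3).
#' @param occlusion_fraction Fraction of the patch area zeroed as one square
#'   at a uniform random position (0 = off; investigated value 0.25).
#' @return Object of class `"augment_config"`.
#' @export
augment_config <- function(rotations = numeric(0), gaussian_3sigma = 0,
                           occlusion_fraction = 0) {
  if (length(rotations) && !all(rotations %in% c(90, 180, 270))) {
    stop("rotations must be a subset of 90/180/270 degrees", call. = FALSE)
  }
  stopifnot(gaussian_3sigma >= 0, occlusion_fraction >= 0, occlusion_fraction < 1)
  structure(list(rotations = as.numeric(rotations),
                 gaussian_3sigma = gaussian_3sigma,
                 occlusion_fraction = occlusion_fraction),
            class = "augment_config")
}

augment_active <- function(cfg) {
  length(cfg$rotations) > 0 || cfg$gaussian_3sigma > 0 || cfg$occlusion_fraction > 0
}

# Rotate the spatial plane of an (H, W, C) array by 90 degrees clockwise.
rot90_patch <- function(v) {
  d <- dim(v)
  aperm(v[d[1L]:1L, , , drop = FALSE], c(2L, 1L, 3L))
}

#' Augment one ROI patch
#'
#' Applies, in order: a rotation drawn from the configured set, additive
#' Gaussian noise, and random square occlusion (fill value 0). The class
#' label is never touched. Uses the R random number generator.
#'
#' @param values `(l, k, bands)` array (square spatial patch).
#' @param cfg An [augment_config()].
#' @return Augmented array of the same shape.
#' @export
augment_patch <- function(values, cfg) {
  stopifnot(inherits(cfg, "augment_config"))
  d <- dim(values)
  if (d[1L] != d[2L]) stop("augmentation expects a square spatial patch", call. = FALSE)
  if (length(cfg$rotations)) {
    ang <- sample(c(0, cfg$rotations), 1L)
    for (i in seq_len(ang / 90)) values <- rot90_patch(values)
  }
  if (cfg$gaussian_3sigma > 0) {
    values <- values + stats::rnorm(length(values), 0, cfg$gaussian_3sigma / 3)
  }
  if (cfg$occlusion_fraction > 0) {
    side <- max(1L, round(sqrt(cfg$occlusion_fraction * d[1L] * d[2L])))
    side <- min(side, d[1L], d[2L])
    y0 <- sample.int(d[1L] - side + 1L, 1L)
    x0 <- sample.int(d[2L] - side + 1L, 1L)
    values[y0:(y0 + side - 1L), x0:(x0 + side - 1L), ] <- 0
  }
  values
}

#' Training configuration
#'
#' Bundles the investigated training-parameter grid (data origin, dropout
#' rate, weight decay, learning-rate decay, augmentation) with the fixed Adam
#' settings. The learning rate follows inverse-time decay
#' `lr_t = base_lr / (1 + lr_decay * t)` with `t` the 0-based epoch index, so
#' `lr_decay = 0` keeps it constant.
#'
#' @param data_origin `"absorbance"` or `"reflectance"` — which corrected cube
#'   feeds the pipeline.
#' @param dropout_rate Dropout before the fully connected layer (grid values
#'   0, 0.25, 0.5).
#' @param weight_decay L2 penalty added to convolution/fully-connected
#'   gradients (grid values 0, 5e-4).
#' @param lr_decay Inverse-time decay coefficient (grid values 0, 0.11).
#' @param base_lr,batch_size,max_epochs,patience Adam base learning rate,
#'   minibatch size, epoch cap and early-stopping patience.
#' @param seed Integer controlling initialisation, shuffling, dropout and
#'   augmentation draws (reproducible in single-threaded runs).
#' @param augment An [augment_config()].
#' @param block_channels Stage widths passed to [model_spec()].
#' @param n_classes Number of classes.
#' @return Object of class `"train_config"`.
#' @export
train_config <- function(data_origin = c("absorbance", "reflectance"),
                         dropout_rate = 0, weight_decay = 0, lr_decay = 0,
                         base_lr = 1e-3, batch_size = 32L, max_epochs = 30L,
                         patience = 5L, seed = 0L,
                         augment = augment_config(),
                         block_channels = c(64L, 128L, 256L, 512L),
                         n_classes = 3L) {
  data_origin <- match.arg(data_origin)
  stopifnot(dropout_rate >= 0, dropout_rate < 1, weight_decay >= 0,
            lr_decay >= 0, base_lr > 0, batch_size >= 1L, max_epochs >= 1L,
            patience >= 1L, inherits(augment, "augment_config"))
  structure(list(data_origin = data_origin, dropout_rate = dropout_rate,
                 weight_decay = weight_decay, lr_decay = lr_decay,
                 base_lr = base_lr, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed),
                 augment = augment,
                 block_channels = as.integer(block_channels),
                 n_classes = as.integer(n_classes)),
            class = "train_config")
}

# Per-epoch accumulation of batch-norm batch statistics. The inference
# statistics become the plain average of the epoch's batch means/variances,
# so short trainings are not biased by the running-state initialisation.
accumulate_bn_stats <- function(sums, caches) {
  grab <- function(sums, key_m, key_v, cache) {
    if (is.null(sums[[key_m]])) {
      sums[[key_m]] <- cache$mu
      sums[[key_v]] <- cache$v
    } else {
      sums[[key_m]] <- sums[[key_m]] + cache$mu
      sums[[key_v]] <- sums[[key_v]] + cache$v
    }
    sums
  }
  if (is.null(sums)) sums <- list()
  sums <- grab(sums, "stem.rm", "stem.rv", caches$stem$bn)
  for (s in 1:4) for (b in 1:2) {
    p <- sprintf("s%db%d.", s, b)
    sums <- grab(sums, paste0(p, "rm1"), paste0(p, "rv1"), caches[[p]]$bn1)
    sums <- grab(sums, paste0(p, "rm2"), paste0(p, "rv2"), caches[[p]]$bn2)
  }
  sums
}

finalize_bn_stats <- function(sums, n_batches) {
  lapply(sums, function(x) x / n_batches)
}

# Stack a list of ROI samples into an (H, W, C, N) tensor plus labels.
samples_to_tensor <- function(samples) {
  stopifnot(length(samples) >= 1L)
  d <- dim(samples[[1L]]$values)
  X <- array(0, c(d, length(samples)))
  for (i in seq_along(samples)) {
    if (!identical(dim(samples[[i]]$values), d)) {
      stop("samples differ in patch shape", call. = FALSE)
    }
    X[, , , i] <- samples[[i]]$values
  }
  labels <- vapply(samples, function(s) as.integer(s$label), integer(1L))
  list(X = X, labels = labels)
}

#' Train the patch classifier
#'
#' Minibatch Adam on softmax cross-entropy. Augmentation (if configured) is
#' applied on the fly to training batches only. When validation samples are
#' given, validation loss is evaluated after every epoch; training stops once
#' it has not improved for `patience` epochs, and the returned model carries
#' the parameters of the best epoch, whose index is the recorded stopping
#' epoch (the quantity pooled across folds by the median-epoch rule). Without
#' validation samples the model trains for exactly `max_epochs`.
#'
#' @param train_samples,val_samples Lists of preprocessed ROI samples with
#'   labels 1..n_classes (`val_samples` may be `NULL`).
#' @param cfg A [train_config()].
#' @return Object of class `"kidney_resnet_fit"`: the fitted model,
#'   `stopping_epoch`, and a per-epoch `history` data frame.
#' @export
train_model <- function(train_samples, val_samples = NULL, cfg) {
  stopifnot(inherits(cfg, "train_config"))
  if (length(train_samples) == 0L) stop("empty training set", call. = FALSE)
  set.seed(cfg$seed)

  tr <- samples_to_tensor(train_samples)
  if (any(is.na(tr$labels)) || any(tr$labels < 1L) || any(tr$labels > cfg$n_classes)) {
    stop("training labels must lie in 1..n_classes", call. = FALSE)
  }
  va <- if (!is.null(val_samples) && length(val_samples)) samples_to_tensor(val_samples) else NULL

  d <- dim(tr$X)
  spec <- model_spec(d[3L], cfg$n_classes, cfg$block_channels)
  model <- build_model(spec, cfg$dropout_rate)
  opt <- adam_init(model$params)
  n <- d[4L]
  do_aug <- augment_active(cfg$augment)

  best <- list(loss = Inf, epoch = 0L, params = model$params, state = model$state)
  wait <- 0L
  hist <- data.frame(epoch = integer(0), lr = numeric(0), train_loss = numeric(0),
                     val_loss = numeric(0), val_accuracy = numeric(0))

  for (epoch in seq_len(cfg$max_epochs)) {
    lr <- cfg$base_lr / (1 + cfg$lr_decay * (epoch - 1L))
    ord <- sample.int(n)
    ep_loss <- 0
    nb <- 0L
    bn_sums <- NULL
    for (start in seq.int(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      Xb <- tr$X[, , , idx, drop = FALSE]
      if (do_aug) {
        for (j in seq_along(idx)) {
          Xb[, , , j] <- augment_patch(Xb[, , , j, drop = TRUE], cfg$augment)
        }
      }
      fw <- resnet_forward(model, Xb, training = TRUE)
      ls <- ce_loss(fw$logits, tr$labels[idx])
      grads <- resnet_backward(model, fw$caches, ls$dlogits)
      upd <- adam_step(model$params, grads, opt, lr, cfg$weight_decay)
      model$params <- upd$params
      opt <- upd$opt
      bn_sums <- accumulate_bn_stats(bn_sums, fw$caches)
      ep_loss <- ep_loss + ls$loss
      nb <- nb + 1L
    }
    ep_loss <- ep_loss / nb
    # inference statistics: average of this epoch's batch statistics, which
    # is unbiased by the initial running values even for very short runs
    model$state <- finalize_bn_stats(bn_sums, nb)

    val_loss <- NA_real_; val_acc <- NA_real_
    if (!is.null(va)) {
      pv <- predict_tensor(model, va$X)
      vls <- ce_loss(pv$logits, va$labels)
      val_loss <- vls$loss
      val_acc <- mean(pv$labels == va$labels)
      if (val_loss < best$loss) {
        best <- list(loss = val_loss, epoch = epoch,
                     params = model$params, state = model$state)
        wait <- 0L
      } else {
        wait <- wait + 1L
      }
    }
    hist <- rbind(hist, data.frame(epoch = epoch, lr = lr, train_loss = ep_loss,
                                   val_loss = val_loss, val_accuracy = val_acc))
    if (!is.null(va) && wait >= cfg$patience) break
  }

  if (!is.null(va) && best$epoch > 0L) {
    model$params <- best$params
    model$state <- best$state
    stopping_epoch <- best$epoch
  } else {
    stopping_epoch <- nrow(hist)
  }
  structure(list(model = model, cfg = cfg, stopping_epoch = stopping_epoch,
                 history = hist),
            class = "kidney_resnet_fit")
}

# Batched inference on a prepared tensor.
predict_tensor <- function(model, X, batch_size = 64L) {
  n <- dim(X)[4L]
  logits <- NULL
  for (start in seq.int(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    fw <- resnet_forward(model, X[, , , idx, drop = FALSE], training = FALSE)
    logits <- rbind(logits, fw$logits)
  }
  list(logits = logits, scores = softmax(logits),
       labels = max.col(logits, ties.method = "first"))
}

#' Classify ROI samples
#'
#' Deterministic inference (dropout off, batch-norm running statistics).
#'
#' @param fit A `kidney_resnet_fit` from [train_model()] (or a bare
#'   `kidney_resnet`).
#' @param samples List of preprocessed ROI samples matching the model's patch
#'   shape and band count.
#' @param batch_size Inference batch size (memory knob).
#' @return List with per-sample `labels` (argmax class) and `scores`
#'   (n x n_classes softmax matrix).
#' @export
predict_rois <- function(fit, samples, batch_size = 64L) {
  model <- if (inherits(fit, "kidney_resnet_fit")) fit$model else fit
  stopifnot(inherits(model, "kidney_resnet"))
  st <- samples_to_tensor(samples)
  if (dim(st$X)[3L] != model$spec$in_channels) {
    stop("sample band count does not match the model's input channels", call. = FALSE)
  }
  out <- predict_tensor(model, st$X, batch_size = batch_size)
  list(labels = out$labels, scores = out$scores)
}
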