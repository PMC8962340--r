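# An 18-weight-layer residual network over multi-band square patches:
# stem conv + 4 stages x 2 basic blocks x 2 convs + fully connected head.
# Every conv is 3x3/stride 1 with batch normalization; each stage is followed
# by a 2x2 max pool; channel increases use zero-padded identity shortcuts so
# the weight-layer count stays exactly 18. Forward, backward and the Adam
# update are implemented here directly on BLAS-backed im2col matrices: the
# network is the scientific core of the package, not an imported component.
#
# Tensor convention: activations are arrays of dim (H, W, C, N).

#' Architecture specification for the patch classifier
#'
#' @param in_channels Number of spectral bands fed to the first convolution.
#' @param n_classes Number of output classes (default 3: nonfunctional,
#'   limited functional, functional).
#' @param block_channels Channel widths of the four residual stages (default
#'   `c(64, 128, 256, 512)`; tests and desk-scale runs may shrink these).
#' @return Object of class `"model_spec"`.
#' @export
model_spec <- function(in_channels, n_classes = 3L,
                       block_channels = c(64L, 128L, 256L, 512L)) {
  stopifnot(in_channels >= 1L, n_classes >= 2L, length(block_channels) == 4L,
            all(block_channels >= 1L))
  structure(list(in_channels = as.integer(in_channels),
                 n_classes = as.integer(n_classes),
                 block_channels = as.integer(block_channels)),
            class = "model_spec")
}

## ---- primitive layers -----------------------------------------------------

conv_fwd <- function(X, W, stride = 1L, pad = 1L, want_cache = TRUE) {
  d <- dim(X); H <- d[1L]; Wd <- d[2L]; C <- d[3L]; N <- d[4L]
  kd <- dim(W); kh <- kd[1L]; kw <- kd[2L]; Cout <- kd[4L]
  if (pad > 0L) {
    Xp <- array(0, c(H + 2L * pad, Wd + 2L * pad, C, N))
    Xp[(pad + 1L):(pad + H), (pad + 1L):(pad + Wd), , ] <- X
  } else Xp <- X
  oH <- (H + 2L * pad - kh) %/% stride + 1L
  oW <- (Wd + 2L * pad - kw) %/% stride + 1L
  P <- matrix(0, oH * oW * N, kh * kw * C)
  for (kx in seq_len(kw)) for (ky in seq_len(kh)) {
    ys <- seq.int(ky, by = stride, length.out = oH)
    xs <- seq.int(kx, by = stride, length.out = oW)
    blk <- aperm(Xp[ys, xs, , , drop = FALSE], c(1L, 2L, 4L, 3L))
    P[, ((seq_len(C)) - 1L) * (kh * kw) + (kx - 1L) * kh + ky] <-
      matrix(blk, oH * oW * N, C)
  }
  out <- P %*% matrix(W, kh * kw * C, Cout)
  Y <- aperm(array(out, c(oH, oW, N, Cout)), c(1L, 2L, 4L, 3L))
  cache <- if (want_cache) {
    list(P = P, H = H, W = Wd, C = C, N = N, kh = kh, kw = kw,
         Cout = Cout, stride = stride, pad = pad, oH = oH, oW = oW)
  } else NULL
  list(Y = Y, cache = cache)
}

conv_bwd <- function(dY, W, cache) {
  ch <- cache
  M <- matrix(aperm(dY, c(1L, 2L, 4L, 3L)), ch$oH * ch$oW * ch$N, ch$Cout)
  dW <- array(crossprod(ch$P, M), dim(W))
  dP <- M %*% t(matrix(W, ch$kh * ch$kw * ch$C, ch$Cout))
  Hp <- ch$H + 2L * ch$pad; Wp <- ch$W + 2L * ch$pad
  dXp <- array(0, c(Hp, Wp, ch$C, ch$N))
  for (kx in seq_len(ch$kw)) for (ky in seq_len(ch$kh)) {
    ys <- seq.int(ky, by = ch$stride, length.out = ch$oH)
    xs <- seq.int(kx, by = ch$stride, length.out = ch$oW)
    cols <- ((seq_len(ch$C)) - 1L) * (ch$kh * ch$kw) + (kx - 1L) * ch$kh + ky
    blk <- array(dP[, cols], c(ch$oH, ch$oW, ch$N, ch$C))
    dXp[ys, xs, , ] <- dXp[ys, xs, , , drop = FALSE] + aperm(blk, c(1L, 2L, 4L, 3L))
  }
  dX <- if (ch$pad > 0L) {
    dXp[(ch$pad + 1L):(ch$pad + ch$H), (ch$pad + 1L):(ch$pad + ch$W), , , drop = FALSE]
  } else dXp
  list(dX = dX, dW = dW)
}

bn_fwd <- function(X, gamma, beta, rm, rv, training, momentum = 0.1, eps = 1e-5) {
  d <- dim(X)
  Xm <- matrix(aperm(X, c(1L, 2L, 4L, 3L)), d[1L] * d[2L] * d[4L], d[3L])
  if (training) {
    mu <- colMeans(Xm)
    xc <- sweep(Xm, 2L, mu)
    v <- colMeans(xc^2)
    rm <- (1 - momentum) * rm + momentum * mu
    rv <- (1 - momentum) * rv + momentum * v
  } else {
    mu <- rm; v <- rv
    xc <- sweep(Xm, 2L, mu)
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2L, istd, `*`)
  Ym <- sweep(sweep(xhat, 2L, gamma, `*`), 2L, beta, `+`)
  Y <- aperm(array(Ym, c(d[1L], d[2L], d[4L], d[3L])), c(1L, 2L, 4L, 3L))
  list(Y = Y, cache = list(xhat = xhat, istd = istd, d = d, mu = mu, v = v),
       rm = rm, rv = rv)
}

bn_bwd <- function(dY, gamma, cache) {
  d <- cache$d
  m <- d[1L] * d[2L] * d[4L]
  dYm <- matrix(aperm(dY, c(1L, 2L, 4L, 3L)), m, d[3L])
  dgamma <- colSums(dYm * cache$xhat)
  dbeta <- colSums(dYm)
  dxhat <- sweep(dYm, 2L, gamma, `*`)
  t1 <- sweep(dxhat, 2L, colMeans(dxhat))
  t2 <- sweep(cache$xhat, 2L, colMeans(dxhat * cache$xhat), `*`)
  dXm <- sweep(t1 - t2, 2L, cache$istd, `*`)
  dX <- aperm(array(dXm, c(d[1L], d[2L], d[4L], d[3L])), c(1L, 2L, 4L, 3L))
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

pool_fwd <- function(X) {
  d <- dim(X)
  oH <- d[1L] %/% 2L; oW <- d[2L] %/% 2L
  if (oH < 1L || oW < 1L) {
    return(list(Y = X, cache = list(skip = TRUE)))   # too small to pool
  }
  i1 <- seq.int(1L, by = 2L, length.out = oH)
  j1 <- seq.int(1L, by = 2L, length.out = oW)
  a <- X[i1, j1, , , drop = FALSE];      b <- X[i1, j1 + 1L, , , drop = FALSE]
  cc <- X[i1 + 1L, j1, , , drop = FALSE]; e <- X[i1 + 1L, j1 + 1L, , , drop = FALSE]
  Y <- pmax(a, b, cc, e)
  # route gradient to the first maximal element (fixed a/b/c/e priority)
  wa <- a == Y
  wb <- (b == Y) & !wa
  wc <- (cc == Y) & !(wa | wb)
  we <- !(wa | wb | wc)
  list(Y = Y, cache = list(skip = FALSE, wa = wa, wb = wb, wc = wc, we = we,
                           i1 = i1, j1 = j1, d = d))
}

pool_bwd <- function(dY, cache) {
  if (cache$skip) return(dY)
  d <- cache$d
  dX <- array(0, d)
  dX[cache$i1, cache$j1, , ] <- dY * cache$wa
  dX[cache$i1, cache$j1 + 1L, , ] <- dY * cache$wb
  dX[cache$i1 + 1L, cache$j1, , ] <- dY * cache$wc
  dX[cache$i1 + 1L, cache$j1 + 1L, , ] <- dY * cache$we
  dX
}

relu_fwd <- function(X) {
  mask <- X > 0
  X[!mask] <- 0
  list(Y = X, mask = mask)
}

pad_channels <- function(X, Cout) {
  d <- dim(X)
  if (d[3L] == Cout) return(X)
  Y <- array(0, c(d[1L], d[2L], Cout, d[4L]))
  Y[, , seq_len(d[3L]), ] <- X
  Y
}

global_avg_pool <- function(X) {
  d <- dim(X)
  feat <- t(matrix(colMeans(matrix(X, d[1L] * d[2L], d[3L] * d[4L])), d[3L], d[4L]))
  list(feat = feat, d = d)   # feat: (N, C)
}

gap_bwd <- function(dfeat, d) {
  v <- rep(as.vector(t(dfeat)) / (d[1L] * d[2L]), each = d[1L] * d[2L])
  array(v, d)
}

## ---- parameter initialisation --------------------------------------------

#' Build an untrained patch classifier
#'
#' Initialises all 18 weight layers (He-scaled Gaussian convolution kernels,
#' unit-gain batch-norm parameters, zero biases). Initialisation draws from
#' the R random number generator, so `set.seed()` before calling makes two
#' builds identical.
#'
#' @param spec A [model_spec()].
#' @param dropout_rate Dropout probability applied to the pooled features
#'   before the fully connected layer during training (0, 0.25 or 0.5 in the
#'   investigated grid).
#' @return Object of class `"kidney_resnet"` with `params`, batch-norm
#'   `state`, `spec` and `dropout_rate`.
#' @export
build_model <- function(spec, dropout_rate = 0) {
  stopifnot(inherits(spec, "model_spec"), dropout_rate >= 0, dropout_rate < 1)
  ch <- spec$block_channels
  he <- function(kh, kw, ci, co) {
    array(stats::rnorm(kh * kw * ci * co, 0, sqrt(2 / (kh * kw * ci))),
          c(kh, kw, ci, co))
  }
  params <- list()
  state <- list()
  add_bn <- function(prefix, c) {
    params[[paste0(prefix, "g")]] <<- rep(1, c)
    params[[paste0(prefix, "b")]] <<- rep(0, c)
    state[[paste0(prefix, "rm")]] <<- rep(0, c)
    state[[paste0(prefix, "rv")]] <<- rep(1, c)
  }
  params[["stem.W"]] <- he(3L, 3L, spec$in_channels, ch[1L])
  add_bn("stem.", ch[1L])
  cin <- ch[1L]
  for (s in 1:4) {
    for (b in 1:2) {
      p <- sprintf("s%db%d.", s, b)
      cout <- ch[s]
      params[[paste0(p, "W1")]] <- he(3L, 3L, cin, cout)
      params[[paste0(p, "g1")]] <- rep(1, cout)
      params[[paste0(p, "b1")]] <- rep(0, cout)
      state[[paste0(p, "rm1")]] <- rep(0, cout)
      state[[paste0(p, "rv1")]] <- rep(1, cout)
      params[[paste0(p, "W2")]] <- he(3L, 3L, cout, cout)
      params[[paste0(p, "g2")]] <- rep(1, cout)
      params[[paste0(p, "b2")]] <- rep(0, cout)
      state[[paste0(p, "rm2")]] <- rep(0, cout)
      state[[paste0(p, "rv2")]] <- rep(1, cout)
      cin <- cout
    }
  }
  params[["fc.W"]] <- matrix(stats::rnorm(ch[4L] * spec$n_classes, 0, sqrt(2 / ch[4L])),
                             ch[4L], spec$n_classes)
  params[["fc.b"]] <- rep(0, spec$n_classes)
  structure(list(params = params, state = state, spec = spec,
                 dropout_rate = dropout_rate),
            class = "kidney_resnet")
}

#' Count of weight layers (convolutions + fully connected)
#'
#' @param model A `kidney_resnet`.
#' @return Integer (18 for this architecture).
#' @export
n_weight_layers <- function(model) {
  sum(vapply(names(model$params), function(n) grepl("\\.W", n), logical(1L)))
}

## ---- forward / backward ---------------------------------------------------

# Forward pass. Returns logits (N x n_classes), updated BN state and, when
# training, the caches required by resnet_backward.
resnet_forward <- function(model, X, training = FALSE) {
  params <- model$params
  state <- model$state
  caches <- if (training) list() else NULL
  wc <- training

  cv <- conv_fwd(X, params[["stem.W"]], want_cache = wc)
  bn <- bn_fwd(cv$Y, params[["stem.g"]], params[["stem.b"]],
               state[["stem.rm"]], state[["stem.rv"]], training)
  state[["stem.rm"]] <- bn$rm; state[["stem.rv"]] <- bn$rv
  rl <- relu_fwd(bn$Y)
  A <- rl$Y
  if (training) caches$stem <- list(conv = cv$cache, bn = bn$cache, mask = rl$mask)

  for (s in 1:4) {
    for (b in 1:2) {
      p <- sprintf("s%db%d.", s, b)
      idn <- pad_channels(A, dim(params[[paste0(p, "W1")]])[4L])
      cv1 <- conv_fwd(A, params[[paste0(p, "W1")]], want_cache = wc)
      bn1 <- bn_fwd(cv1$Y, params[[paste0(p, "g1")]], params[[paste0(p, "b1")]],
                    state[[paste0(p, "rm1")]], state[[paste0(p, "rv1")]], training)
      state[[paste0(p, "rm1")]] <- bn1$rm; state[[paste0(p, "rv1")]] <- bn1$rv
      rl1 <- relu_fwd(bn1$Y)
      cv2 <- conv_fwd(rl1$Y, params[[paste0(p, "W2")]], want_cache = wc)
      bn2 <- bn_fwd(cv2$Y, params[[paste0(p, "g2")]], params[[paste0(p, "b2")]],
                    state[[paste0(p, "rm2")]], state[[paste0(p, "rv2")]], training)
      state[[paste0(p, "rm2")]] <- bn2$rm; state[[paste0(p, "rv2")]] <- bn2$rv
      rl2 <- relu_fwd(bn2$Y + idn)
      if (training) {
        caches[[p]] <- list(conv1 = cv1$cache, bn1 = bn1$cache, mask1 = rl1$mask,
                            conv2 = cv2$cache, bn2 = bn2$cache, mask2 = rl2$mask,
                            cin = dim(A)[3L])
      }
      A <- rl2$Y
    }
    pl <- pool_fwd(A)
    A <- pl$Y
    if (training) caches[[sprintf("pool%d", s)]] <- pl$cache
  }

  gp <- global_avg_pool(A)
  feat <- gp$feat
  drop_mask <- NULL
  if (training && model$dropout_rate > 0) {
    drop_mask <- matrix(stats::runif(length(feat)) >= model$dropout_rate,
                        nrow(feat), ncol(feat)) / (1 - model$dropout_rate)
    feat <- feat * drop_mask
  }
  logits <- feat %*% params[["fc.W"]] +
    matrix(params[["fc.b"]], nrow(feat), length(params[["fc.b"]]), byrow = TRUE)
  if (training) {
    caches$gap_d <- gp$d
    caches$feat <- feat
    caches$drop_mask <- drop_mask
  }
  list(logits = logits, state = state, caches = caches)
}

softmax <- function(logits) {
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Mean cross-entropy and its gradient with respect to the logits.
ce_loss <- function(logits, labels) {
  p <- softmax(logits)
  n <- nrow(p)
  idx <- cbind(seq_len(n), labels)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, dlogits = dlogits / n)
}

resnet_backward <- function(model, caches, dlogits) {
  params <- model$params
  grads <- list()
  grads[["fc.W"]] <- crossprod(caches$feat, dlogits)
  grads[["fc.b"]] <- colSums(dlogits)
  dfeat <- dlogits %*% t(params[["fc.W"]])
  if (!is.null(caches$drop_mask)) dfeat <- dfeat * caches$drop_mask
  dA <- gap_bwd(dfeat, caches$gap_d)

  for (s in 4:1) {
    dA <- pool_bwd(dA, caches[[sprintf("pool%d", s)]])
    for (b in 2:1) {
      p <- sprintf("s%db%d.", s, b)
      ch <- caches[[p]]
      dsum <- dA * ch$mask2
      bb2 <- bn_bwd(dsum, params[[paste0(p, "g2")]], ch$bn2)
      grads[[paste0(p, "g2")]] <- bb2$dgamma
      grads[[paste0(p, "b2")]] <- bb2$dbeta
      cb2 <- conv_bwd(bb2$dX, params[[paste0(p, "W2")]], ch$conv2)
      grads[[paste0(p, "W2")]] <- cb2$dW
      drl1 <- cb2$dX * ch$mask1
      bb1 <- bn_bwd(drl1, params[[paste0(p, "g1")]], ch$bn1)
      grads[[paste0(p, "g1")]] <- bb1$dgamma
      grads[[paste0(p, "b1")]] <- bb1$dbeta
      cb1 <- conv_bwd(bb1$dX, params[[paste0(p, "W1")]], ch$conv1)
      grads[[paste0(p, "W1")]] <- cb1$dW
      # identity branch: zero-padded shortcut passes the first cin channels
      dA <- cb1$dX + dsum[, , seq_len(ch$cin), , drop = FALSE]
    }
  }

  dstem <- dA * caches$stem$mask
  bb <- bn_bwd(dstem, params[["stem.g"]], caches$stem$bn)
  grads[["stem.g"]] <- bb$dgamma
  grads[["stem.b"]] <- bb$dbeta
  cb <- conv_bwd(bb$dX, params[["stem.W"]], caches$stem$conv)
  grads[["stem.W"]] <- cb$dW
  grads
}

## ---- Adam -----------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, opt, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (weight_decay > 0 && grepl("\\.W", nm)) g <- g + weight_decay * params[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}
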