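# A compact CPU convolutional network for TRS images. Deliberately small:
# the images are near-binary polylines, so a couple of conv blocks plus one
# dense layer carries all the signal, and CPU training stays in seconds.
# All randomness (init, shuffling, dropout) comes from R's RNG so a seed
# fixes the fitted weights exactly.

# Fixed parameter-free average pooling applied once per dataset before any
# training: 4x vertically, 8x horizontally, 200x400 -> 50x50. The polyline
# becomes a grayscale ridge whose vertical position carries the signal.
.CNN_DOWNSAMPLE <- c(4L, 8L)

# downsample a raw (200, 400, 1, n) stack once; all internal layers work on
# the pooled array
.prep_stack <- function(X) {
  .cpp_avgpool(X, .CNN_DOWNSAMPLE[1], .CNN_DOWNSAMPLE[2])
}

# stack a list of equal-size matrices into an (h, w, 1, n) array
.stack_images <- function(images, expect_h = 200L, expect_w = 400L) {
  n <- length(images)
  if (!n) stop("no images")
  for (m in images) {
    if (!is.matrix(m) || nrow(m) != expect_h || ncol(m) != expect_w)
      stop(sprintf("wrong image shape: expected %d x %d matrix",
                   expect_h, expect_w))
  }
  arr <- array(0, c(expect_h, expect_w, 1L, n))
  for (i in seq_len(n)) arr[, , 1L, i] <- images[[i]]
  arr
}

.cnn_arch <- function(config, in_h, in_w) {
  nl <- config$n_conv_layers
  ks <- rep_len(config$kernel_size, nl)
  nf <- rep_len(config$n_conv_patches, nl)
  h <- in_h
  w <- in_w
  cin <- 1L
  layers <- list()
  for (l in seq_len(nl)) {
    layers[[l]] <- list(k = ks[l], cin = cin, f = nf[l])
    cin <- nf[l]
    h <- h %/% 2L; w <- w %/% 2L   # maxpool 2 after every conv block
  }
  list(conv = layers, flat = h * w * cin, h = h, w = w,
       dense = rep_len(config$dense_units, config$n_dense_layers))
}

.cnn_init <- function(config, in_h = 200L, in_w = 400L) {
  arch <- .cnn_arch(config, in_h, in_w)
  par <- list()
  for (l in seq_along(arch$conv)) {
    a <- arch$conv[[l]]
    fan_in <- a$k * a$k * a$cin
    par[[paste0("Wc", l)]] <- array(
      stats::rnorm(a$k * a$k * a$cin * a$f, 0, sqrt(2 / fan_in)),
      c(a$k, a$k, a$cin, a$f))
    par[[paste0("bc", l)]] <- numeric(a$f)
  }
  din <- arch$flat
  for (l in seq_along(arch$dense)) {
    dout <- arch$dense[l]
    par[[paste0("Wd", l)]] <- matrix(
      stats::rnorm(din * dout, 0, sqrt(2 / din)), din, dout)
    par[[paste0("bd", l)]] <- numeric(dout)
    din <- dout
  }
  par$Wo <- matrix(stats::rnorm(din, 0, sqrt(1 / din)), din, 1)
  par$bo <- 0
  list(par = par, arch = arch, in_h = in_h, in_w = in_w)
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

# forward pass on a pooled stack; returns probabilities and caches
.cnn_forward <- function(net, A, train = FALSE, dropout_rate = 0) {
  cache <- list()
  for (l in seq_along(net$arch$conv)) {
    Z <- .cpp_conv_fwd(A, net$par[[paste0("Wc", l)]],
                       net$par[[paste0("bc", l)]])
    R <- Z; R[R < 0] <- 0
    mp <- .cpp_maxpool_fwd(R, 2L)
    cache[[paste0("conv", l)]] <- list(A_in = A, Z = Z, R = R,
                                       argmax = mp$argmax,
                                       rdim = dim(R))
    A <- mp$Y
  }
  n <- dim(A)[4]
  Fm <- matrix(A, nrow = net$arch$flat, ncol = n)  # features x samples
  cache$flat_dim <- dim(A)
  H <- Fm
  for (l in seq_along(net$arch$dense)) {
    Z <- crossprod(net$par[[paste0("Wd", l)]], H) +
      net$par[[paste0("bd", l)]]
    Rm <- Z; Rm[Rm < 0] <- 0
    if (train && dropout_rate > 0) {
      mask <- matrix(stats::rbinom(length(Rm), 1, 1 - dropout_rate),
                     nrow(Rm), ncol(Rm)) / (1 - dropout_rate)
      Rm <- Rm * mask
      cache[[paste0("drop", l)]] <- mask
    }
    cache[[paste0("dense", l)]] <- list(H_in = H, Z = Z, R = Rm)
    H <- Rm
  }
  z <- as.numeric(crossprod(net$par$Wo, H)) + net$par$bo
  p <- .sigmoid(z)
  cache$H_last <- H
  cache$Fm <- Fm
  list(p = p, cache = cache)
}

# weighted binary cross-entropy gradient wrt the output logit
.cnn_backward <- function(net, fwd, y, w_pos, dropout_rate = 0) {
  cache <- fwd$cache
  p <- fwd$p
  n <- length(y)
  wts <- ifelse(y == 1, w_pos, 1)
  dz <- (wts * (p - y)) / n        # d(mean weighted BCE)/dz
  g <- list()
  g$Wo <- cache$H_last %*% matrix(dz, ncol = 1)
  g$bo <- sum(dz)
  dH <- net$par$Wo %*% matrix(dz, nrow = 1)
  for (l in rev(seq_along(net$arch$dense))) {
    cc <- cache[[paste0("dense", l)]]
    if (dropout_rate > 0 && !is.null(cache[[paste0("drop", l)]]))
      dH <- dH * cache[[paste0("drop", l)]]
    dZ <- dH * (cc$Z > 0)
    g[[paste0("Wd", l)]] <- cc$H_in %*% t(dZ)
    g[[paste0("bd", l)]] <- rowSums(dZ)
    dH <- net$par[[paste0("Wd", l)]] %*% dZ
  }
  dA <- array(dH, cache$flat_dim)
  for (l in rev(seq_along(net$arch$conv))) {
    cc <- cache[[paste0("conv", l)]]
    dR <- .cpp_maxpool_bwd(dA, cc$argmax, as.integer(cc$rdim))
    dZ <- dR * (cc$Z > 0)
    bw <- .cpp_conv_bwd(cc$A_in, net$par[[paste0("Wc", l)]], dZ)
    g[[paste0("Wc", l)]] <- bw$dW
    g[[paste0("bc", l)]] <- bw$db
    dA <- bw$dX
  }
  g
}

.adam_init <- function(par) {
  list(m = lapply(par, function(p) p * 0),
       v = lapply(par, function(p) p * 0), t = 0)
}

.adam_step <- function(par, grad, st, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  st$t <- st$t + 1
  for (nm in names(grad)) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * grad[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * grad[[nm]]^2
    mhat <- st$m[[nm]] / (1 - beta1^st$t)
    vhat <- st$v[[nm]] / (1 - beta2^st$t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, st = st)
}

.bce_loss <- function(p, y, w_pos = 1) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  mean(-w_pos * y * log(p) - (1 - y) * log(1 - p))
}

# train one binary CNN; X arrays are pooled (see .prep_stack) stacks
.cnn_train <- function(X, y, Xval, yval, config) {
  set.seed(config$seed)
  net <- .cnn_init(config, dim(X)[1], dim(X)[2])
  w_pos <- if (config$class_weight) max(1, sum(y == 0) / max(1, sum(y == 1)))
           else 1
  st <- .adam_init(net$par)
  n <- dim(X)[4]
  bs <- min(config$batch_size, n)
  best <- list(loss = Inf, par = net$par, epoch = 0)
  wait <- 0
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n)
    for (b in seq_len(ceiling(n / bs))) {
      take <- ord[seq.int((b - 1) * bs + 1, min(b * bs, n))]
      Xb <- X[, , , take, drop = FALSE]
      fwd <- .cnn_forward(net, Xb, train = TRUE,
                          dropout_rate = config$dropout_rate)
      grad <- .cnn_backward(net, fwd, y[take], w_pos,
                            dropout_rate = config$dropout_rate)
      upd <- .adam_step(net$par, grad, st, config$learning_rate)
      net$par <- upd$par; st <- upd$st
    }
    pval <- .cnn_forward(net, Xval)$p
    vloss <- .bce_loss(pval, yval, w_pos)
    if (vloss < best$loss - 1e-6) {
      best <- list(loss = vloss, par = net$par, epoch = epoch)
      wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= config$patience) break
    }
  }
  net$par <- best$par
  net$val_loss <- best$loss
  net$best_epoch <- best$epoch
  net$w_pos <- w_pos
  net
}

.cnn_predict <- function(net, X, batch = 64L) {
  n <- dim(X)[4]
  p <- numeric(n)
  for (b in seq_len(ceiling(n / batch))) {
    take <- seq.int((b - 1) * batch + 1, min(b * batch, n))
    p[take] <- .cnn_forward(net, X[, , , take, drop = FALSE])$p
  }
  p
}
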