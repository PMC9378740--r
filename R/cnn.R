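# Minimal convolutional network ("small_cnn"): three 3x3 same-padding conv
# blocks with relu + 2x2 max pooling, followed by three fully-connected
# layers. Written against base R matrix ops (im2col via 9 shifted slices, so
# the heavy lifting is BLAS matrix multiplication). Designed for CPU-scale
# synthetic experiments, not ImageNet-scale work.

conv_forward <- function(x, W, bias) {
  # x: (n, H, W, Cin) array; W: (9*Cin, Cout); same padding, stride 1
  dm <- dim(x)
  n <- dm[1]; H <- dm[2]; Wd <- dm[3]; Cin <- dm[4]
  pad <- array(0, c(n, H + 2, Wd + 2, Cin))
  pad[, 2:(H + 1), 2:(Wd + 1), ] <- x
  cols <- matrix(0, n * H * Wd, 9 * Cin)
  k <- 0
  for (di in 0:2) for (dj in 0:2) {
    sl <- pad[, di + seq_len(H), dj + seq_len(Wd), , drop = FALSE]
    cols[, k * Cin + seq_len(Cin)] <- matrix(sl, n * H * Wd, Cin)
    k <- k + 1
  }
  out <- cols %*% W
  out <- sweep(out, 2, bias, "+")
  list(out = array(out, c(n, H, Wd, ncol(W))), cols = cols)
}

conv_backward <- function(dout, cols, W, xdim) {
  n <- xdim[1]; H <- xdim[2]; Wd <- xdim[3]; Cin <- xdim[4]
  dmat <- matrix(dout, n * H * Wd, dim(dout)[4])
  dW <- crossprod(cols, dmat)
  db <- colSums(dmat)
  dcols <- tcrossprod(dmat, W)
  dpad <- array(0, c(n, H + 2, Wd + 2, Cin))
  k <- 0
  for (di in 0:2) for (dj in 0:2) {
    dpad[, di + seq_len(H), dj + seq_len(Wd), ] <-
      dpad[, di + seq_len(H), dj + seq_len(Wd), , drop = FALSE] +
      array(dcols[, k * Cin + seq_len(Cin)], c(n, H, Wd, Cin))
    k <- k + 1
  }
  list(dx = dpad[, 2:(H + 1), 2:(Wd + 1), , drop = FALSE], dW = dW, db = db)
}

maxpool_forward <- function(x) {
  dm <- dim(x)
  n <- dm[1]; H <- dm[2]; Wd <- dm[3]; C <- dm[4]
  h2 <- H %/% 2; w2 <- Wd %/% 2
  s <- list(
    x[, seq(1, 2 * h2, 2), seq(1, 2 * w2, 2), , drop = FALSE],
    x[, seq(1, 2 * h2, 2), seq(2, 2 * w2, 2), , drop = FALSE],
    x[, seq(2, 2 * h2, 2), seq(1, 2 * w2, 2), , drop = FALSE],
    x[, seq(2, 2 * h2, 2), seq(2, 2 * w2, 2), , drop = FALSE]
  )
  out <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  list(out = out, slices = s, xdim = dm)
}

maxpool_backward <- function(dout, cache) {
  dm <- cache$xdim
  h2 <- dm[2] %/% 2; w2 <- dm[3] %/% 2
  dx <- array(0, dm)
  out <- pmax(cache$slices[[1]], cache$slices[[2]], cache$slices[[3]],
              cache$slices[[4]])
  taken <- array(FALSE, dim(out))
  offs <- list(c(1, 1), c(1, 2), c(2, 1), c(2, 2))
  for (k in 1:4) {
    m <- (cache$slices[[k]] == out) & !taken
    taken <- taken | m
    oi <- offs[[k]]
    dx[, seq(oi[1], 2 * h2, 2), seq(oi[2], 2 * w2, 2), ] <-
      dx[, seq(oi[1], 2 * h2, 2), seq(oi[2], 2 * w2, 2), , drop = FALSE] +
      dout * m
  }
  dx
}

init_cnn_params <- function(resolution, channels, filters, fc_units, K, seed) {
  stopifnot(resolution %% 8 == 0)
  with_seed(seed, {
    p <- list()
    cin <- channels
    for (i in seq_along(filters)) {
      p[[paste0("Wc", i)]] <- matrix(
        rnorm(9 * cin * filters[i], sd = sqrt(2 / (9 * cin))),
        9 * cin, filters[i])
      p[[paste0("bc", i)]] <- rep(0, filters[i])
      cin <- filters[i]
    }
    flat <- (resolution / 2^length(filters))^2 * cin
    dims <- c(flat, fc_units, K)
    for (i in seq_len(length(dims) - 1)) {
      p[[paste0("Wf", i)]] <- matrix(
        rnorm(dims[i] * dims[i + 1], sd = sqrt(2 / dims[i])),
        dims[i], dims[i + 1])
      p[[paste0("bf", i)]] <- rep(0, dims[i + 1])
    }
    p
  })
}

cnn_forward <- function(x, p, n_conv, n_fc, keep_cache = FALSE) {
  cache <- list()
  h <- x
  for (i in seq_len(n_conv)) {
    cv <- conv_forward(h, p[[paste0("Wc", i)]], p[[paste0("bc", i)]])
    a <- pmax(cv$out, 0)
    pl <- maxpool_forward(a)
    if (keep_cache) {
      cache[[paste0("conv", i)]] <- list(cols = cv$cols, pre = cv$out,
                                         xdim = dim(h), pool = pl)
    }
    h <- pl$out
  }
  n <- dim(h)[1]
  flat <- matrix(h, n, prod(dim(h)[-1]))
  if (keep_cache) cache$flat_dim <- dim(h)
  z <- flat
  for (i in seq_len(n_fc)) {
    pre <- sweep(z %*% p[[paste0("Wf", i)]], 2, p[[paste0("bf", i)]], "+")
    if (keep_cache) cache[[paste0("fc", i)]] <- list(input = z, pre = pre)
    z <- if (i < n_fc) pmax(pre, 0) else pre
  }
  list(scores = z, cache = cache)
}

cnn_backward <- function(dscores, p, cache, n_conv, n_fc) {
  g <- list()
  dz <- dscores
  for (i in rev(seq_len(n_fc))) {
    cc <- cache[[paste0("fc", i)]]
    if (i < n_fc) dz <- dz * (cc$pre > 0)
    g[[paste0("Wf", i)]] <- crossprod(cc$input, dz)
    g[[paste0("bf", i)]] <- colSums(dz)
    dz <- tcrossprod(dz, p[[paste0("Wf", i)]])
  }
  dh <- array(dz, cache$flat_dim)
  for (i in rev(seq_len(n_conv))) {
    cc <- cache[[paste0("conv", i)]]
    da <- maxpool_backward(dh, cc$pool)
    da <- da * (cc$pre > 0)
    bk <- conv_backward(da, cc$cols, p[[paste0("Wc", i)]], cc$xdim)
    g[[paste0("Wc", i)]] <- bk$dW
    g[[paste0("bc", i)]] <- bk$db
    dh <- bk$dx
  }
  g
}

# images: (n, r, r, 3) array scaled to [0,1]; y one-hot matrix
train_small_cnn <- function(images, Y, epochs = 8, batch_size = 32, lr = 1e-3,
                            filters = c(8, 16, 32), fc_units = c(64, 32),
                            seed = 1) {
  dm <- dim(images)
  n <- dm[1]; r <- dm[2]; K <- ncol(Y)
  p <- init_cnn_params(r, dm[4], filters, fc_units, K, derive_seed(seed, "init"))
  mstate <- lapply(p, function(z) z * 0)
  vstate <- lapply(p, function(z) z * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0
  n_conv <- length(filters); n_fc <- length(fc_units) + 1
  xc <- images - 0.5
  losses <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- with_seed(derive_seed(seed, paste0("epoch", ep)), sample(n))
    ep_loss <- 0; nb <- 0
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      xb <- xc[idx, , , , drop = FALSE]
      yb <- Y[idx, , drop = FALSE]
      fw <- cnn_forward(xb, p, n_conv, n_fc, keep_cache = TRUE)
      P <- softmax_rows(fw$scores)
      ep_loss <- ep_loss - mean(log(pmax(rowSums(P * yb), 1e-12)))
      nb <- nb + 1
      dscores <- (P - yb) / nrow(yb)
      g <- cnn_backward(dscores, p, fw$cache, n_conv, n_fc)
      step <- step + 1
      for (nm in names(p)) {
        mstate[[nm]] <- b1 * mstate[[nm]] + (1 - b1) * g[[nm]]
        vstate[[nm]] <- b2 * vstate[[nm]] + (1 - b2) * g[[nm]]^2
        mh <- mstate[[nm]] / (1 - b1^step)
        vh <- vstate[[nm]] / (1 - b2^step)
        p[[nm]] <- p[[nm]] - lr * mh / (sqrt(vh) + eps)
      }
    }
    losses[ep] <- ep_loss / nb
  }
  list(params = p, n_conv = n_conv, n_fc = n_fc, losses = losses,
       resolution = r, channels = dm[4])
}

predict_small_cnn <- function(net, images, batch_size = 64) {
  dm <- dim(images)
  out <- NULL
  for (start in seq(1, dm[1], by = batch_size)) {
    idx <- start:min(start + batch_size - 1, dm[1])
    xb <- images[idx, , , , drop = FALSE] - 0.5
    fw <- cnn_forward(xb, net$params, net$n_conv, net$n_fc)
    out <- rbind(out, softmax_rows(fw$scores))
  }
  out
}

#' Bilinear image resize
#'
#' @param img H-by-W-by-3 numeric array in \[0, 1\]
#' @param out_size output side length (square)
#' @return `out_size`-by-`out_size`-by-3 array
#' @export
resize_bilinear <- function(img, out_size) {
  dm <- dim(img)
  if (length(dm) == 2) img <- array(rep(img, 3), c(dm, 3))
  dm <- dim(img)
  if (dm[1] == out_size && dm[2] == out_size) return(img)
  yy <- seq(1, dm[1], length.out = out_size)
  xx <- seq(1, dm[2], length.out = out_size)
  y0 <- pmin(floor(yy), dm[1] - 1); x0 <- pmin(floor(xx), dm[2] - 1)
  fy <- yy - y0; fx <- xx - x0
  out <- array(0, c(out_size, out_size, dm[3]))
  for (c in seq_len(dm[3])) {
    ch <- img[, , c]
    a <- ch[y0, x0] * outer(1 - fy, 1 - fx) +
      ch[y0, x0 + 1] * outer(1 - fy, fx) +
      ch[y0 + 1, x0] * outer(fy, 1 - fx) +
      ch[y0 + 1, x0 + 1] * outer(fy, fx)
    out[, , c] <- a
  }
  out
}
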