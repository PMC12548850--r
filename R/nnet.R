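# Minimal convolutional network engine: strided 2-D convolution layers via
# im2col/col2im, leaky-ReLU activations, and SGD with momentum, warm-up and
# linear learning-rate decay. Just enough machinery for the compact
# single-stage detector; not a general-purpose framework.

make_conv_layer <- function(kh, kw, cin, cout, stride, pad,
                            act = c("leaky", "linear"), norm = FALSE) {
  act <- match.arg(act)
  k <- kh * kw * cin
  # He-style init; biases zero (the head objectness bias is set by the caller)
  W <- matrix(rnorm(k * cout, 0, sqrt(2 / k)), k, cout)
  list(kh = kh, kw = kw, cin = cin, cout = cout, stride = stride, pad = pad,
       act = act, norm = norm, W = W, b = numeric(cout))
}

conv_out_hw <- function(layer, H, W) {
  c((H + 2 * layer$pad - layer$kh) %/% layer$stride + 1,
    (W + 2 * layer$pad - layer$kw) %/% layer$stride + 1)
}

leaky_relu <- function(x, alpha = 0.1) x * (alpha + (1 - alpha) * (x > 0))
leaky_relu_grad <- function(x, alpha = 0.1) alpha + (1 - alpha) * (x > 0)

# Forward pass through the layer stack. Trunk layers use a parameter-free
# per-channel spatial normalization between the convolution and its bias
# (the stand-in for the batch normalization this detector family carries
# after every convolution; per-image statistics keep it deterministic).
# Returns the head output array and, when `keep_cache`, the per-layer
# intermediates needed for backprop.
net_forward <- function(layers, x, keep_cache = FALSE) {
  cache <- if (keep_cache) vector("list", length(layers)) else NULL
  eps <- 1e-5
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    d <- dim(x)
    if (d[3] != ly$cin) {
      stop(sprintf("layer %d expects %d input channels, got %d", i, ly$cin, d[3]))
    }
    cols <- cpp_im2col(as.numeric(x), d[1], d[2], d[3],
                       ly$kh, ly$kw, ly$stride, ly$pad)
    raw <- crossprod(ly$W, cols)          # cout x L
    if (isTRUE(ly$norm)) {
      mu <- rowMeans(raw)
      ctr <- raw - mu
      sg <- sqrt(rowMeans(ctr * ctr) + eps)
      xhat <- ctr / sg
      pre <- xhat + ly$b
    } else {
      xhat <- NULL; sg <- NULL
      pre <- raw + ly$b
    }
    hw <- conv_out_hw(ly, d[1], d[2])
    out <- array(t(pre), dim = c(hw[1], hw[2], ly$cout))
    act <- if (ly$act == "leaky") leaky_relu(out) else out
    if (keep_cache) {
      cache[[i]] <- list(cols = cols, pre = out, in_dim = d,
                         xhat = xhat, sg = sg)
    }
    x <- act
  }
  list(out = x, cache = cache)
}

# Backward pass; `dout` is the gradient w.r.t. the head output array.
# Returns per-layer dW/db lists.
net_backward <- function(layers, cache, dout) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]
    cc <- cache[[i]]
    if (ly$act == "leaky") dout <- dout * leaky_relu_grad(cc$pre)
    L <- prod(dim(dout)[1:2])
    dmat <- t(matrix(dout, nrow = L, ncol = ly$cout))  # cout x L
    db <- rowSums(dmat)
    if (isTRUE(ly$norm)) {
      # back through xhat = (raw - mu) / sg, per output channel
      dmat <- (dmat - rowMeans(dmat) -
                 cc$xhat * rowMeans(dmat * cc$xhat)) / cc$sg
    }
    grads[[i]] <- list(dW = cc$cols %*% t(dmat), db = db)
    if (i > 1L) {
      dcols <- ly$W %*% dmat
      dout <- cpp_col2im(dcols, cc$in_dim[1], cc$in_dim[2], cc$in_dim[3],
                         ly$kh, ly$kw, ly$stride, ly$pad)
    }
  }
  grads
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' SGD schedule: learning rate and momentum per epoch
#'
#' Linear decay of the nominal learning rate from `lr0` to `lr0 * lr_decay`
#' over `max_epochs`. During the warm-up epochs the effective weight learning
#' rate ramps from 0 (bias groups from `warmup_bias_lr`) to the nominal rate
#' and the momentum ramps from its warm-up value to its final value.
#'
#' @param cfg a [train_config()].
#' @param epoch 1-based epoch index.
#' @param frac_epoch fraction of the epoch already completed, in \[0, 1).
#' @return list with `lr` (nominal), `lr_weight`, `lr_bias`, `momentum`.
#' @export
sgd_schedule <- function(cfg, epoch, frac_epoch = 0) {
  span <- max(1, cfg$max_epochs - 1)
  lf <- 1 - ((epoch - 1) / span) * (1 - cfg$lr_decay)
  lr <- cfg$lr0 * lf
  prog <- (epoch - 1 + frac_epoch) / cfg$warmup_epochs
  if (prog < 1) {
    list(lr = lr,
         lr_weight = prog * lr,
         lr_bias = cfg$warmup_bias_lr + prog * (lr - cfg$warmup_bias_lr),
         momentum = cfg$warmup_momentum + prog * (cfg$momentum - cfg$warmup_momentum))
  } else {
    list(lr = lr, lr_weight = lr, lr_bias = lr, momentum = cfg$momentum)
  }
}
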