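# Minimal neural-network layer framework with hand-written reverse-mode
# gradients. Batches are 3-D arrays (batch x channels x length) for
# convolutional layers and (batch x length x features) for recurrent ones.
# Layers are environments so parameters and optimizer state update in place.

new_layer <- function(type, .pars = character(0), ...) {
  l <- new.env(parent = emptyenv())
  l$type <- type
  l$par_names <- .pars
  extra <- list(...)
  for (nm in names(extra)) assign(nm, extra[[nm]], envir = l)
  class(l) <- "nn_layer"
  l
}

# Uniform init in [-1/sqrt(fan_in), 1/sqrt(fan_in)], the standard default for
# small conv/linear layers. Draws from the current RNG stream.
init_uniform <- function(dims, fan_in) {
  s <- 1 / sqrt(fan_in)
  array(stats::runif(prod(dims), -s, s), dims)
}

nn_conv1d <- function(in_ch, out_ch, k) {
  pad <- (k - 1L) %/% 2L
  new_layer("conv", .pars = c("W", "b"),
            in_ch = in_ch, out_ch = out_ch, k = k, pad = pad,
            W = init_uniform(c(out_ch, in_ch, k), in_ch * k),
            b = as.vector(init_uniform(out_ch, in_ch * k)))
}

nn_bn1d <- function(ch, eps = 1e-5, momentum = 0.1) {
  new_layer("bn", .pars = c("gamma", "beta"),
            ch = ch, eps = eps, momentum = momentum,
            gamma = rep(1, ch), beta = rep(0, ch),
            running_mean = rep(0, ch), running_var = rep(1, ch))
}

nn_relu <- function() new_layer("relu")
nn_maxpool2 <- function() new_layer("maxpool")
nn_gap <- function() new_layer("gap")
nn_flatten_conv <- function() new_layer("to_seq")   # (N,C,L) -> (N,L,C)
nn_take_last <- function() new_layer("take_last")   # (N,L,H) -> (N,H)
nn_dropout <- function(p) new_layer("dropout", p = p)
nn_logsoftmax <- function() new_layer("logsoftmax")

nn_linear <- function(in_f, out_f) {
  new_layer("linear", .pars = c("W", "b"),
            W = init_uniform(c(out_f, in_f), in_f),
            b = as.vector(init_uniform(out_f, in_f)))
}

# One LSTM layer, gate order (i, f, g, o); forget-gate bias initialized at 1.
nn_lstm <- function(in_f, hidden) {
  s <- 1 / sqrt(hidden)
  b <- rep(0, 4 * hidden)
  b[(hidden + 1):(2 * hidden)] <- 1
  new_layer("lstm", .pars = c("Wx", "Wh", "b"),
            in_f = in_f, hidden = hidden,
            Wx = array(stats::runif(in_f * 4 * hidden, -s, s),
                       c(in_f, 4 * hidden)),
            Wh = array(stats::runif(hidden * 4 * hidden, -s, s),
                       c(hidden, 4 * hidden)),
            b = b)
}

layer_forward <- function(l, x, training = FALSE) {
  switch(l$type,
    conv = conv_forward(l, x),
    bn = bn_forward(l, x, training),
    relu = { l$mask <- x > 0; x * l$mask },
    maxpool = maxpool_forward(l, x),
    gap = gap_forward(l, x),
    to_seq = { l$dims <- dim(x); aperm(x, c(1, 3, 2)) },
    take_last = {
      d <- dim(x); l$L <- d[2]
      matrix(x[, d[2], , drop = FALSE], d[1], d[3])
    },
    dropout = dropout_forward(l, x, training),
    linear = linear_forward(l, x),
    logsoftmax = logsoftmax_forward(l, x),
    lstm = lstm_forward(l, x),
    stopf("unknown layer type: %s", l$type))
}

layer_backward <- function(l, dy) {
  switch(l$type,
    conv = conv_backward(l, dy),
    bn = bn_backward(l, dy),
    relu = dy * l$mask,
    maxpool = maxpool_backward(l, dy),
    gap = gap_backward(l, dy),
    to_seq = aperm(dy, c(1, 3, 2)),
    take_last = take_last_backward(l, dy),
    dropout = if (is.null(l$mask)) dy else dy * l$mask,
    linear = linear_backward(l, dy),
    logsoftmax = logsoftmax_backward(l, dy),
    lstm = lstm_backward(l, dy),
    stopf("unknown layer type: %s", l$type))
}

## ---- convolution (stride 1, zero padding preserving length) ----

conv_forward <- function(l, x) {
  d <- dim(x); N <- d[1]; C <- d[2]; L <- d[3]
  p <- l$pad; k <- l$k
  xp <- array(0, c(N, C, L + 2 * p))
  xp[, , (p + 1):(p + L)] <- x
  cols <- array(0, c(C, k, N, L))
  for (j in seq_len(k))
    cols[, j, , ] <- aperm(xp[, , j:(j + L - 1), drop = FALSE], c(2, 1, 3))
  Kmat <- matrix(cols, C * k, N * L)
  Wmat <- matrix(l$W, l$out_ch, C * k)
  y <- Wmat %*% Kmat + l$b
  l$Kmat <- Kmat; l$dims <- d
  aperm(array(y, c(l$out_ch, N, L)), c(2, 1, 3))
}

conv_backward <- function(l, dy) {
  d <- l$dims; N <- d[1]; C <- d[2]; L <- d[3]
  p <- l$pad; k <- l$k
  dym <- matrix(aperm(dy, c(2, 1, 3)), l$out_ch, N * L)
  l$gb <- rowSums(dym)
  l$gW <- array(dym %*% t(l$Kmat), c(l$out_ch, C, k))
  Wmat <- matrix(l$W, l$out_ch, C * k)
  dK <- array(t(Wmat) %*% dym, c(C, k, N, L))
  dxp <- array(0, c(N, C, L + 2 * p))
  for (j in seq_len(k))
    dxp[, , j:(j + L - 1)] <- dxp[, , j:(j + L - 1)] +
      aperm(array(dK[, j, , , drop = FALSE], c(C, N, L)), c(2, 1, 3))
  dxp[, , (p + 1):(p + L), drop = FALSE]
}

## ---- batch normalization over (batch, length) per channel ----

bn_forward <- function(l, x, training) {
  d <- dim(x); N <- d[1]; C <- d[2]; L <- d[3]
  xm <- matrix(aperm(x, c(2, 1, 3)), C, N * L)
  if (training) {
    mu <- rowMeans(xm)
    v <- rowMeans((xm - mu)^2)
    l$running_mean <- (1 - l$momentum) * l$running_mean + l$momentum * mu
    l$running_var <- (1 - l$momentum) * l$running_var + l$momentum * v
  } else {
    mu <- l$running_mean
    v <- l$running_var
  }
  inv <- 1 / sqrt(v + l$eps)
  xhat <- (xm - mu) * inv
  ym <- l$gamma * xhat + l$beta
  l$xhat <- xhat; l$inv <- inv; l$dims <- d; l$was_training <- training
  aperm(array(ym, c(C, N, L)), c(2, 1, 3))
}

bn_backward <- function(l, dy) {
  d <- l$dims; N <- d[1]; C <- d[2]; L <- d[3]
  dym <- matrix(aperm(dy, c(2, 1, 3)), C, N * L)
  l$ggamma <- rowSums(dym * l$xhat)
  l$gbeta <- rowSums(dym)
  if (l$was_training) {
    m <- ncol(dym)
    dxm <- (l$gamma * l$inv) *
      (dym - rowMeans(dym) - l$xhat * rowMeans(dym * l$xhat))
  } else {
    dxm <- (l$gamma * l$inv) * dym
  }
  aperm(array(dxm, c(C, N, L)), c(2, 1, 3))
}

## ---- pooling ----

maxpool_forward <- function(l, x) {
  d <- dim(x); L <- d[3]
  if (L %% 2 != 0) stopf("maxpool requires an even input length, got %d", L)
  a <- x[, , seq(1, L, 2), drop = FALSE]
  b <- x[, , seq(2, L, 2), drop = FALSE]
  l$first <- a >= b   # ties take the earlier position
  l$dims <- d
  pmax(a, b)
}

maxpool_backward <- function(l, dy) {
  d <- l$dims
  dx <- array(0, d)
  dx[, , seq(1, d[3], 2)] <- dy * l$first
  dx[, , seq(2, d[3], 2)] <- dy * !l$first
  dx
}

gap_forward <- function(l, x) {
  d <- dim(x); l$dims <- d
  matrix(rowMeans(matrix(x, d[1] * d[2], d[3])), d[1], d[2])
}

gap_backward <- function(l, dy) {
  d <- l$dims
  array(rep(as.vector(dy) / d[3], d[3]), d)
}

take_last_backward <- function(l, dy) {
  dx <- array(0, c(nrow(dy), l$L, ncol(dy)))
  dx[, l$L, ] <- dy
  dx
}

dropout_forward <- function(l, x, training) {
  if (!training || l$p <= 0) { l$mask <- NULL; return(x) }
  l$mask <- array((stats::runif(length(x)) >= l$p) / (1 - l$p), dim(x))
  x * l$mask
}

## ---- dense / output ----

linear_forward <- function(l, x) {
  l$x <- x
  sweep(x %*% t(l$W), 2, l$b, "+")
}

linear_backward <- function(l, dy) {
  l$gW <- t(dy) %*% l$x
  l$gb <- colSums(dy)
  dy %*% l$W
}

logsoftmax_forward <- function(l, x) {
  mx <- apply(x, 1, max)
  z <- x - mx
  y <- z - log(rowSums(exp(z)))
  l$y <- y
  y
}

logsoftmax_backward <- function(l, dy) {
  dy - exp(l$y) * rowSums(dy)
}

## ---- LSTM ----

sigmoid <- function(x) 1 / (1 + exp(-x))

lstm_forward <- function(l, x) {
  d <- dim(x); N <- d[1]; L <- d[2]; H <- l$hidden
  h <- matrix(0, N, H); cc <- matrix(0, N, H)
  out <- array(0, c(N, L, H))
  cache <- vector("list", L)
  for (t in seq_len(L)) {
    xt <- x[, t, , drop = TRUE]
    if (is.null(dim(xt))) xt <- matrix(xt, N, l$in_f)
    z <- xt %*% l$Wx + h %*% l$Wh
    z <- sweep(z, 2, l$b, "+")
    i <- sigmoid(z[, 1:H, drop = FALSE])
    f <- sigmoid(z[, (H + 1):(2 * H), drop = FALSE])
    g <- tanh(z[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- sigmoid(z[, (3 * H + 1):(4 * H), drop = FALSE])
    c_prev <- cc
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    h_prev <- h
    h <- o * tc
    out[, t, ] <- h
    cache[[t]] <- list(xt = xt, h_prev = h_prev, c_prev = c_prev,
                       i = i, f = f, g = g, o = o, tc = tc)
  }
  l$cache <- cache; l$dims <- d
  out
}

lstm_backward <- function(l, dH) {
  d <- l$dims; N <- d[1]; L <- d[2]; H <- l$hidden
  gWx <- array(0, dim(l$Wx)); gWh <- array(0, dim(l$Wh)); gb <- rep(0, 4 * H)
  dX <- array(0, d)
  dh_next <- matrix(0, N, H); dc_next <- matrix(0, N, H)
  for (t in rev(seq_len(L))) {
    cc <- l$cache[[t]]
    dh <- dH[, t, , drop = TRUE] + dh_next
    if (is.null(dim(dh))) dh <- matrix(dh, N, H)
    do_ <- dh * cc$tc
    dc <- dc_next + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g
    dg <- dc * cc$i
    df <- dc * cc$c_prev
    dc_next <- dc * cc$f
    dz <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do_ * cc$o * (1 - cc$o))
    gWx <- gWx + t(cc$xt) %*% dz
    gWh <- gWh + t(cc$h_prev) %*% dz
    gb <- gb + colSums(dz)
    dX[, t, ] <- dz %*% t(l$Wx)
    dh_next <- dz %*% t(l$Wh)
  }
  l$gWx <- gWx; l$gWh <- gWh; l$gb <- gb
  dX
}

## ---- network-level helpers ----

net_forward <- function(layers, x, training = FALSE) {
  for (l in layers) x <- layer_forward(l, x, training)
  x
}

net_backward <- function(layers, dy) {
  for (l in rev(layers)) dy <- layer_backward(l, dy)
  dy
}

grad_name <- function(par) {
  switch(par, W = "gW", b = "gb", gamma = "ggamma", beta = "gbeta",
         Wx = "gWx", Wh = "gWh", stopf("no gradient slot for %s", par))
}

net_parameters <- function(layers) {
  out <- list()
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    for (p in l$par_names)
      out[[sprintf("L%02d.%s", i, p)]] <- get(p, envir = l)
  }
  out
}

net_restore <- function(layers, pars) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    for (p in l$par_names) {
      nm <- sprintf("L%02d.%s", i, p)
      if (is.null(pars[[nm]])) stopf("missing parameter %s", nm)
      val <- pars[[nm]]
      cur <- get(p, envir = l)
      if (!is.null(dim(cur))) dim(val) <- dim(cur)
      assign(p, val, envir = l)
    }
  }
  invisible(layers)
}

adam_state <- function(layers) {
  st <- list(t = 0)
  for (i in seq_along(layers)) for (p in layers[[i]]$par_names) {
    nm <- sprintf("L%02d.%s", i, p)
    z <- get(p, envir = layers[[i]]) * 0
    st[[nm]] <- list(m = z, v = z)
  }
  st
}

adam_step <- function(layers, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    for (p in l$par_names) {
      nm <- sprintf("L%02d.%s", i, p)
      par <- get(p, envir = l)
      g <- get(grad_name(p), envir = l)
      if (weight_decay > 0) g <- g + weight_decay * par
      s <- state[[nm]]
      s$m <- beta1 * s$m + (1 - beta1) * g
      s$v <- beta2 * s$v + (1 - beta2) * g^2
      state[[nm]] <- s
      assign(p, par - lr * (s$m / bc1) / (sqrt(s$v / bc2) + eps), envir = l)
    }
  }
  state
}
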