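# A small stacked-LSTM regressor, trained by full backpropagation through
# time with Adam. Pure R, batch-vectorized over samples: inputs are a list
# of T matrices (N x D), one per timestep; the readout maps the last hidden
# state of the top layer to a scalar.
#
# At the scale this package runs (sequence length = number of schema
# entities, tens of samples to a few hundred) this trains in seconds; it is
# not intended as a general deep-learning engine.

sigmoid <- function(x) 1 / (1 + exp(-x))

lstm_init <- function(input_dim, layers, seed) {
  with_seed(seed, {
    params <- list()
    d <- input_dim
    for (l in seq_along(layers)) {
      H <- layers[l]
      sc <- 1 / sqrt(d + H)
      params[[l]] <- list(
        Wx = matrix(stats::runif(d * 4 * H, -sc, sc), d, 4 * H),
        Wh = matrix(stats::runif(H * 4 * H, -sc, sc), H, 4 * H),
        b = {
          b <- rep(0, 4 * H)
          b[(H + 1):(2 * H)] <- 1  # forget-gate bias at 1: standard init
          b
        })
      d <- H
    }
    H <- layers[length(layers)]
    list(layers = params,
         Wy = matrix(stats::runif(H, -1 / sqrt(H), 1 / sqrt(H)), H, 1),
         by = 0)
  })
}

lstm_layer_forward <- function(xs, W) {
  T_ <- length(xs)
  N <- nrow(xs[[1]])
  H <- ncol(W$Wh)/4
  h <- matrix(0, N, H); cc <- matrix(0, N, H)
  cache <- vector("list", T_)
  hs <- vector("list", T_)
  for (t in seq_len(T_)) {
    z <- xs[[t]] %*% W$Wx + h %*% W$Wh +
      matrix(W$b, N, 4 * H, byrow = TRUE)
    i <- sigmoid(z[, 1:H, drop = FALSE])
    f <- sigmoid(z[, (H + 1):(2 * H), drop = FALSE])
    o <- sigmoid(z[, (2 * H + 1):(3 * H), drop = FALSE])
    g <- tanh(z[, (3 * H + 1):(4 * H), drop = FALSE])
    c_prev <- cc
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    h_new <- o * tc
    cache[[t]] <- list(x = xs[[t]], h_prev = h, c_prev = c_prev,
                       i = i, f = f, o = o, g = g, c = cc, tc = tc)
    h <- h_new
    hs[[t]] <- h
  }
  list(hs = hs, cache = cache)
}

lstm_layer_backward <- function(dhs, W, cache) {
  T_ <- length(cache)
  N <- nrow(cache[[1]]$x)
  H <- ncol(W$Wh)/4
  dWx <- matrix(0, nrow(W$Wx), ncol(W$Wx))
  dWh <- matrix(0, H, 4 * H)
  db <- rep(0, 4 * H)
  dxs <- vector("list", T_)
  dh_next <- matrix(0, N, H)
  dc_next <- matrix(0, N, H)
  for (t in seq(T_, 1L)) {
    cc <- cache[[t]]
    dh <- dhs[[t]] + dh_next
    dc <- dc_next + dh * cc$o * (1 - cc$tc^2)
    do_ <- dh * cc$tc
    di <- dc * cc$g
    dg <- dc * cc$i
    df <- dc * cc$c_prev
    dc_next <- dc * cc$f
    dz <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                do_ * cc$o * (1 - cc$o),
                dg * (1 - cc$g^2))
    dWx <- dWx + t(cc$x) %*% dz
    dWh <- dWh + t(cc$h_prev) %*% dz
    db <- db + colSums(dz)
    dxs[[t]] <- dz %*% t(W$Wx)
    dh_next <- dz %*% t(W$Wh)
  }
  list(grads = list(Wx = dWx, Wh = dWh, b = db), dxs = dxs)
}

lstm_forward <- function(model, xs) {
  acts <- list()
  inp <- xs
  for (l in seq_along(model$layers)) {
    fw <- lstm_layer_forward(inp, model$layers[[l]])
    acts[[l]] <- fw
    inp <- fw$hs
  }
  hT <- inp[[length(inp)]]
  yhat <- as.numeric(hT %*% model$Wy + model$by)
  list(yhat = yhat, acts = acts, hT = hT)
}

lstm_gradients <- function(model, xs, y) {
  fw <- lstm_forward(model, xs)
  N <- length(y)
  T_ <- length(xs)
  dy <- matrix(2 * (fw$yhat - y) / N, N, 1)
  loss <- mean((fw$yhat - y)^2)
  gWy <- t(fw$hT) %*% dy
  gby <- sum(dy)
  L <- length(model$layers)
  H_top <- ncol(model$layers[[L]]$Wh)/4
  dhs <- lapply(seq_len(T_), function(t) matrix(0, N, H_top))
  dhs[[T_]] <- dy %*% t(model$Wy)
  layer_grads <- vector("list", L)
  for (l in seq(L, 1L)) {
    bw <- lstm_layer_backward(dhs, model$layers[[l]], fw$acts[[l]]$cache)
    layer_grads[[l]] <- bw$grads
    dhs <- bw$dxs
  }
  list(loss = loss, grads = list(layers = layer_grads, Wy = gWy, by = gby))
}

flatten_params <- function(p) {
  unlist(c(lapply(p$layers, function(l) c(l$Wx, l$Wh, l$b)), list(p$Wy, p$by)))
}

relist_like <- function(v, p) {
  pos <- 1L
  take <- function(n) { out <- v[pos:(pos + n - 1L)]; pos <<- pos + n; out }
  layers <- lapply(p$layers, function(l) {
    Wx <- matrix(take(length(l$Wx)), nrow(l$Wx), ncol(l$Wx))
    Wh <- matrix(take(length(l$Wh)), nrow(l$Wh), ncol(l$Wh))
    b <- take(length(l$b))
    list(Wx = Wx, Wh = Wh, b = b)
  })
  Wy <- matrix(take(length(p$Wy)), nrow(p$Wy), 1)
  by <- take(1L)
  list(layers = layers, Wy = Wy, by = by)
}

#' Fit the stacked-LSTM regressor
#'
#' @param xs list of T input matrices (N x D), schema-ordered timesteps.
#' @param y numeric targets, length N (standardized by the caller).
#' @param layers integer vector of hidden sizes, one per stacked layer.
#' @param epochs full-batch Adam steps.
#' @param lr Adam learning rate.
#' @param seed initialization seed.
#' @return An `lstm_model`; predict with [lstm_predict()].
#' @keywords internal
lstm_fit <- function(xs, y, layers = c(12L), epochs = 150L, lr = 0.02,
                     seed = 1L) {
  abort_if(length(layers) < 1, "need at least one recurrent layer")
  model <- lstm_init(ncol(xs[[1]]), layers, seed)
  theta <- flatten_params(model)
  m <- v <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (it in seq_len(epochs)) {
    gr <- lstm_gradients(model, xs, y)
    g <- flatten_params(gr$grads)
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    mhat <- m / (1 - b1^it); vhat <- v / (1 - b2^it)
    theta <- theta - lr * mhat / (sqrt(vhat) + eps)
    model <- relist_like(theta, model)
  }
  structure(model, class = "lstm_model")
}

#' @rdname lstm_fit
#' @param model an `lstm_model`.
#' @keywords internal
lstm_predict <- function(model, xs) lstm_forward(model, xs)$yhat
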