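# Minimal trainable-layer engine.
#
# Every layer is an environment ("nn module") holding its parameters, its
# accumulated gradients and cached activations from the last forward pass.
# Activations are 4-d arrays H x W x C x N; weights follow the layout of the
# compiled kernels in src/ (kh x kw x Cin x Cout).  Each module provides
# $forward(x, train) and $backward(dy); composite modules chain their
# children.  Backward passes are hand-derived and validated against central
# finite differences in the test suite.

new_module <- function(type) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$param_names <- character()
  e$children <- list()
  class(e) <- c(paste0("nn_", type), "nn_module")
  e
}

#' @export
print.nn_module <- function(x, ...) {
  cat(sprintf("<nn module: %s, %d trainable parameters>\n",
              x$type, module_param_count(x)))
  invisible(x)
}

# recursively collect leaf modules that own parameters
collect_modules <- function(m) {
  out <- list()
  if (length(m$param_names) > 0L) out[[length(out) + 1L]] <- m
  for (ch in m$children) out <- c(out, collect_modules(ch))
  out
}

#' Count trainable parameters of a network module
#'
#' Sums the lengths of every weight, bias and normalization parameter owned
#' by `m` and its children.  Used throughout for exact per-layer accounting.
#'
#' @param m an nn module (e.g. from [c3_block()], [gam()], [spike_yolo()]).
#' @return integer-valued count of trainable scalars.
#' @export
module_param_count <- function(m) {
  s <- 0
  for (leaf in collect_modules(m)) {
    for (p in leaf$param_names) s <- s + length(leaf[[p]])
  }
  s
}

zero_grads <- function(m) {
  for (leaf in collect_modules(m)) {
    for (p in leaf$param_names) {
      g <- paste0("d", p)
      leaf[[g]] <- leaf[[p]] * 0
    }
  }
  invisible(m)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- convolution -----------------------------------------------------------

nn_conv2d <- function(cin, cout, k, stride = 1L, pad = NULL, bias = FALSE) {
  m <- new_module("conv2d")
  m$cin <- cin; m$cout <- cout; m$k <- as.integer(k)
  m$stride <- as.integer(stride)
  m$pad <- if (is.null(pad)) as.integer(k %/% 2) else as.integer(pad)
  fan_in <- k * k * cin
  m$W <- array(stats::rnorm(k * k * cin * cout, sd = sqrt(2 / fan_in)),
               dim = c(k, k, cin, cout))
  m$dW <- m$W * 0
  m$param_names <- "W"
  if (bias) {
    m$b <- numeric(cout)
    m$db <- numeric(cout)
    m$param_names <- c("W", "b")
  }
  m$need_dx <- TRUE   # cleared on the stem conv, whose input has no grad
  m$forward <- function(x, train = FALSE) {
    if (train) m$x <- x
    .cpp_conv2d_forward(x, m$W, if (length(m$param_names) > 1L) m$b else NULL,
                        m$stride, m$pad)
  }
  m$backward <- function(dy) {
    res <- .cpp_conv2d_backward(m$x, m$W, dy, m$stride, m$pad,
                                length(m$param_names) > 1L, m$need_dx)
    m$dW <- m$dW + res$dw
    if (length(m$param_names) > 1L) m$db <- m$db + res$db
    res$dx
  }
  m
}

# ---- batch normalization ---------------------------------------------------

nn_batchnorm <- function(c, eps = 1e-3, momentum = 0.03) {
  m <- new_module("batchnorm")
  m$c <- c; m$eps <- eps; m$momentum <- momentum
  m$gamma <- rep(1, c); m$beta <- numeric(c)
  m$dgamma <- numeric(c); m$dbeta <- numeric(c)
  m$running_mean <- numeric(c)
  m$running_var <- rep(1, c)
  m$param_names <- c("gamma", "beta")

  m$forward <- function(x, train = FALSE) {
    d <- dim(x); n_eff <- d[1] * d[2] * d[4]
    if (train) {
      st <- .cpp_channel_stats(x)
      mu <- st$sum / n_eff
      var <- pmax(st$sumsq / n_eff - mu^2, 0)
      m$running_mean <- (1 - m$momentum) * m$running_mean + m$momentum * mu
      m$running_var <- (1 - m$momentum) * m$running_var + m$momentum * var
    } else {
      mu <- m$running_mean
      var <- m$running_var
    }
    istd <- 1 / sqrt(var + m$eps)
    if (train) {
      xhat <- .cpp_scale_shift(x, istd, -mu * istd)
      m$xhat <- xhat; m$istd <- istd; m$n_eff <- n_eff
      .cpp_scale_shift(xhat, m$gamma, m$beta)
    } else {
      .cpp_scale_shift(x, m$gamma * istd, m$beta - mu * istd * m$gamma)
    }
  }
  m$backward <- function(dy) {
    xhat <- m$xhat
    st <- .cpp_channel_stats(dy)
    m$dbeta <- m$dbeta + st$sum
    prod_stats <- .cpp_channel_stats(dy * xhat)
    m$dgamma <- m$dgamma + prod_stats$sum
    # dxhat = dy * gamma; per-channel means fold into the fused kernel
    s1 <- m$gamma * st$sum / m$n_eff
    s2 <- m$gamma * prod_stats$sum / m$n_eff
    dxhat <- .cpp_scale_shift(dy, m$gamma, numeric(m$c))
    .cpp_bn_backward_dx(dxhat, xhat, s1, s2, m$istd)
  }
  m
}

# ---- activations -----------------------------------------------------------

nn_activation <- function(kind = c("silu", "relu", "sigmoid")) {
  kind <- match.arg(kind)
  m <- new_module(paste0("act_", kind))
  m$kind <- kind
  m$forward <- function(x, train = FALSE) {
    y <- switch(kind,
                silu = .cpp_silu_forward(x),
                relu = pmax(x, 0),
                sigmoid = sigmoid(x))
    if (train) { m$x <- x; if (kind == "sigmoid") m$y <- y }
    y
  }
  m$backward <- function(dy) {
    switch(kind,
           silu = .cpp_silu_backward(dy, m$x),
           relu = dy * (m$x > 0),
           sigmoid = dy * m$y * (1 - m$y))
  }
  m
}

# ---- max pooling (SPP) -----------------------------------------------------

nn_maxpool <- function(k, stride = 1L, pad = NULL) {
  m <- new_module("maxpool")
  m$k <- as.integer(k); m$stride <- as.integer(stride)
  m$pad <- if (is.null(pad)) as.integer(k %/% 2) else as.integer(pad)
  m$forward <- function(x, train = FALSE) {
    res <- .cpp_maxpool_forward(x, m$k, m$stride, m$pad)
    if (train) { m$idx <- res$idx; m$in_dim <- dim(x) }
    res$y
  }
  m$backward <- function(dy) .cpp_maxpool_backward(dy, m$idx, m$in_dim)
  m
}

# ---- nearest-neighbour 2x upsample ----------------------------------------

nn_upsample2 <- function() {
  m <- new_module("upsample")
  m$forward <- function(x, train = FALSE) {
    d <- dim(x)
    x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , ,
      drop = FALSE]
  }
  m$backward <- function(dy) {
    d <- dim(dy)
    o1 <- seq(1L, d[1], 2L); e1 <- o1 + 1L
    o2 <- seq(1L, d[2], 2L); e2 <- o2 + 1L
    dy[o1, o2, , , drop = FALSE] + dy[e1, o2, , , drop = FALSE] +
      dy[o1, e2, , , drop = FALSE] + dy[e1, e2, , , drop = FALSE]
  }
  m
}

# ---- channel concat --------------------------------------------------------

cat_channels <- function(xs) {
  d1 <- dim(xs[[1]])
  cs <- vapply(xs, function(x) dim(x)[3], numeric(1))
  out <- array(0, dim = c(d1[1], d1[2], sum(cs), d1[4]))
  at <- 0L
  for (x in xs) {
    cc <- dim(x)[3]
    out[, , at + seq_len(cc), ] <- x
    at <- at + cc
  }
  out
}

split_channels <- function(dy, cs) {
  out <- vector("list", length(cs))
  at <- 0L
  for (i in seq_along(cs)) {
    out[[i]] <- dy[, , at + seq_len(cs[i]), , drop = FALSE]
    at <- at + cs[i]
  }
  out
}

nn_concat <- function() {
  m <- new_module("concat")
  m$forward <- function(xs, train = FALSE) {
    if (train) m$cs <- vapply(xs, function(x) dim(x)[3], numeric(1))
    cat_channels(xs)
  }
  m$backward <- function(dy) split_channels(dy, m$cs)
  m
}

# ---- sequential ------------------------------------------------------------

nn_sequential <- function(...) {
  mods <- list(...)
  if (length(mods) == 1L && is.list(mods[[1]]) &&
      !inherits(mods[[1]], "nn_module")) mods <- mods[[1]]
  m <- new_module("sequential")
  m$children <- mods
  m$forward <- function(x, train = FALSE) {
    for (ch in m$children) x <- ch$forward(x, train)
    x
  }
  m$backward <- function(dy) {
    for (ch in rev(m$children)) dy <- ch$backward(dy)
    dy
  }
  m
}

# conv + batch norm + SiLU, the standard composite block (bias-free conv)
conv_block <- function(cin, cout, k = 1L, stride = 1L, act = "silu") {
  m <- new_module("conv_block")
  m$children <- list(nn_conv2d(cin, cout, k, stride),
                     nn_batchnorm(cout),
                     nn_activation(act))
  m$forward <- function(x, train = FALSE) {
    for (ch in m$children) x <- ch$forward(x, train)
    x
  }
  m$backward <- function(dy) {
    for (ch in rev(m$children)) dy <- ch$backward(dy)
    dy
  }
  m
}
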