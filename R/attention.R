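# Attention operators: the efficient channel attention (ECA) gate and the
# global attention mechanism (GAM).  Both are shape-preserving: they output
# an elementwise product of the input with a sigmoid attention map.

#' ECA kernel size from the channel count
#'
#' The adaptive rule maps the channel dimension C to an odd 1-d kernel size
#' \eqn{k = | \log_2(C)/\gamma + b/\gamma |_{odd}} (nearest odd integer, ties
#' broken toward the smaller odd number), floored at 1.
#'
#' @param C positive integer channel count.
#' @param gamma,b rule coefficients (defaults 2 and 1).
#' @return odd positive integer kernel size.
#' @examples
#' eca_kernel_size(32)   # 3
#' eca_kernel_size(256)  # 5
#' @export
eca_kernel_size <- function(C, gamma = 2, b = 1) {
  if (length(C) != 1L || !is.finite(C) || C < 1) {
    stop("C must be a positive integer")
  }
  t <- log2(C) / gamma + b / gamma
  lo <- 2 * floor((t - 1) / 2) + 1          # largest odd <= t
  hi <- lo + 2
  k <- if ((t - lo) <= (hi - t)) lo else hi # tie -> smaller odd
  as.integer(max(1, k))
}

# 1-d channel convolution helpers (zero padding, no bias).  g is a C x N
# matrix of per-channel descriptors.
shift_rows <- function(g, o) {
  C <- nrow(g)
  out <- matrix(0, C, ncol(g))
  if (o >= 0) {
    if (o < C) out[seq_len(C - o), ] <- g[(o + 1):C, , drop = FALSE]
  } else {
    if (-o < C) out[(1 - o):C, ] <- g[seq_len(C + o), , drop = FALSE]
  }
  out
}

conv1d_channels <- function(g, w) {
  p <- (length(w) - 1L) / 2L
  s <- matrix(0, nrow(g), ncol(g))
  for (j in seq_along(w)) s <- s + w[j] * shift_rows(g, j - 1L - p)
  s
}

#' ECA channel-attention layer
#'
#' Builds the efficient channel attention gate: global average pooling over
#' each channel, a weight-sharing bias-free 1-d convolution across channels
#' (zero padding `k %/% 2`), a sigmoid, and multiplication back onto the
#' input.  Trainable parameter count is exactly `k`.
#'
#' In `"fixed3"` mode the kernel size is 3 regardless of the channel count
#' (the convention pinned by the per-layer parameter table of the improved
#' detector, where every ECA-augmented C3 block costs exactly 3 extra
#' parameters); `"adaptive"` mode derives k from `channels` via
#' [eca_kernel_size()].
#'
#' @param channels channel count (only needed in adaptive mode).
#' @param kernel_mode `"fixed3"` (default) or `"adaptive"`.
#' @param k explicit odd kernel size, overriding the mode.
#' @param gamma,b coefficients of the adaptive rule.
#' @return an nn module; apply with [eca_gate()].
#' @export
eca_layer <- function(channels = NULL, kernel_mode = c("fixed3", "adaptive"),
                      k = NULL, gamma = 2, b = 1) {
  kernel_mode <- match.arg(kernel_mode)
  if (is.null(k)) {
    k <- if (kernel_mode == "fixed3") 3L else eca_kernel_size(channels, gamma, b)
  }
  k <- as.integer(k)
  if (k < 1L || k %% 2L == 0L) stop("ECA kernel size must be odd and positive")
  m <- new_module("eca")
  m$k <- k
  m$w <- stats::rnorm(k, sd = 0.1)
  m$dw <- numeric(k)
  m$param_names <- "w"
  m$forward <- function(x, train = FALSE) {
    d <- dim(x); HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
    xv <- x; dim(xv) <- c(HW, C * N)
    g <- colSums(xv) / HW
    dim(g) <- c(C, N)
    gate <- sigmoid(conv1d_channels(g, m$w))
    y <- xv * rep(as.vector(gate), each = HW)
    dim(y) <- d
    m$g <- g; m$gate <- gate
    if (train) m$x <- x
    y
  }
  m$backward <- function(dy) {
    d <- dim(dy); HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
    gate_v <- rep(as.vector(m$gate), each = HW)
    dyv <- dy; dim(dyv) <- c(HW, C * N)
    xv <- m$x; dim(xv) <- c(HW, C * N)
    dx <- dyv * gate_v
    dgate <- colSums(dyv * xv)
    dim(dgate) <- c(C, N)
    ds <- dgate * m$gate * (1 - m$gate)
    p <- (m$k - 1L) / 2L
    for (j in seq_len(m$k)) {
      m$dw[j] <- m$dw[j] + sum(shift_rows(m$g, j - 1L - p) * ds)
    }
    dg <- matrix(0, C, N)
    for (j in seq_len(m$k)) dg <- dg + m$w[j] * shift_rows(ds, -(j - 1L - p))
    dx <- dx + rep(as.vector(dg) / HW, each = HW)
    dim(dx) <- d
    dx
  }
  m
}

# ---- GAM -------------------------------------------------------------------

# channel submodule: permute to put channels last, apply a shared two-layer
# perceptron (C -> C/r -> C, rectifier between, biases on both layers),
# permute back, sigmoid -> gate
gam_channel_module <- function(c, r = 4L) {
  if (c %% r != 0L) stop("channels must be divisible by the reduction rate")
  h <- c %/% r
  m <- new_module("gam_channel")
  m$c <- c; m$h <- h
  m$W1 <- matrix(stats::rnorm(h * c, sd = sqrt(2 / c)), h, c)
  m$b1 <- numeric(h)
  m$W2 <- matrix(stats::rnorm(c * h, sd = sqrt(2 / h)), c, h)
  m$b2 <- numeric(c)
  m$dW1 <- m$W1 * 0; m$db1 <- numeric(h)
  m$dW2 <- m$W2 * 0; m$db2 <- numeric(c)
  m$param_names <- c("W1", "b1", "W2", "b2")
  m$forward <- function(x, train = FALSE) {
    d <- dim(x)
    xm <- aperm(x, c(1, 2, 4, 3))
    dim(xm) <- c(d[1] * d[2] * d[4], d[3])
    hpre <- xm %*% t(m$W1)
    hpre <- hpre + rep(m$b1, each = nrow(hpre))
    hid <- pmax(hpre, 0)
    o <- hid %*% t(m$W2)
    o <- o + rep(m$b2, each = nrow(o))
    mc <- sigmoid(o)
    gate <- mc
    dim(gate) <- c(d[1], d[2], d[4], d[3])
    gate <- aperm(gate, c(1, 2, 4, 3))
    m$gate <- gate
    if (train) { m$x <- x; m$xm <- xm; m$hpre <- hpre; m$hid <- hid; m$mc <- mc }
    gate * x
  }
  m$backward <- function(dy) {
    d <- dim(dy)
    dx1 <- dy * m$gate
    dgate <- dy * m$x
    dmc <- aperm(dgate, c(1, 2, 4, 3))
    dim(dmc) <- c(d[1] * d[2] * d[4], d[3])
    do <- dmc * m$mc * (1 - m$mc)
    m$dW2 <- m$dW2 + t(do) %*% m$hid
    m$db2 <- m$db2 + colSums(do)
    dh <- (do %*% m$W2) * (m$hpre > 0)
    m$dW1 <- m$dW1 + t(dh) %*% m$xm
    m$db1 <- m$db1 + colSums(dh)
    dxm <- dh %*% m$W1
    dim(dxm) <- c(d[1], d[2], d[4], d[3])
    dx1 + aperm(dxm, c(1, 2, 4, 3))
  }
  m
}

# spatial submodule: 7x7 conv C -> C/r (bias) + BN + rectifier, 7x7 conv
# C/r -> C (bias) + BN, sigmoid -> gate.  No pooling anywhere in this path.
gam_spatial_module <- function(c, r = 4L) {
  if (c %% r != 0L) stop("channels must be divisible by the reduction rate")
  h <- c %/% r
  m <- new_module("gam_spatial")
  m$seq <- nn_sequential(nn_conv2d(c, h, 7L, bias = TRUE),
                         nn_batchnorm(h),
                         nn_activation("relu"),
                         nn_conv2d(h, c, 7L, bias = TRUE),
                         nn_batchnorm(c))
  m$children <- list(m$seq)
  m$forward <- function(x, train = FALSE) {
    if (dim(x)[1] < 1 || dim(x)[2] < 1) stop("spatial dims must be >= 1")
    t <- m$seq$forward(x, train)
    m$gate <- sigmoid(t)
    if (train) m$x <- x
    m$gate * x
  }
  m$backward <- function(dy) {
    dx1 <- dy * m$gate
    dt <- dy * m$x * m$gate * (1 - m$gate)
    dx1 + m$seq$backward(dt)
  }
  m
}

#' Global attention mechanism (GAM) layer
#'
#' Sequential channel attention (a two-layer perceptron shared across spatial
#' positions, applied after permuting channels to the last axis) followed by
#' spatial attention (two 7x7 convolutions through a `channels/reduction`
#' bottleneck, batch-normalized, no pooling).  Each stage multiplies its
#' input by a sigmoid gate, so the whole operator is shape-preserving and
#' elementwise attenuating.
#'
#' @param channels input channel count C; must be divisible by `reduction`.
#' @param reduction bottleneck reduction rate r (default 4).
#' @return an nn module with `$ch` and `$sp` submodules; apply with
#'   [gam_gate()], or stage-wise with [gam_channel()] / [gam_spatial()].
#' @seealso [gam_param_count()] for the closed-form parameter count.
#' @export
gam <- function(channels, reduction = 4L) {
  m <- new_module("gam")
  m$c <- channels; m$r <- as.integer(reduction)
  m$ch <- gam_channel_module(channels, m$r)
  m$sp <- gam_spatial_module(channels, m$r)
  m$children <- list(m$ch, m$sp)
  m$forward <- function(x, train = FALSE) {
    m$sp$forward(m$ch$forward(x, train), train)
  }
  m$backward <- function(dy) m$ch$backward(m$sp$backward(dy))
  m
}

#' Closed-form GAM parameter count
#'
#' Under the module's bias/normalization conventions (biases on both MLP
#' layers and both 7x7 convolutions; affine batch norm after each spatial
#' convolution; none after the MLP) the trainable parameter count of a GAM
#' on C channels with reduction r is
#' \deqn{2C^2/r + 98C^2/r + 2C/r + 2C + 2C/r + 2C,}
#' which for the default r = 4 simplifies to \eqn{25C^2 + 5C}.
#'
#' @param C channel count, divisible by `r`.
#' @param r reduction rate (default 4).
#' @return integer parameter count; always equals
#'   `module_param_count(gam(C, r))`.
#' @examples
#' gam_param_count(128)  # 410240
#' @export
gam_param_count <- function(C, r = 4L) {
  if (C %% r != 0L) stop("C must be divisible by r")
  h <- C %/% r
  channel <- h * C + h + C * h + C
  spatial <- 49 * C * h + h + 49 * h * C + C + 2 * h + 2 * C
  channel + spatial
}

# ---- functional wrappers on channel-first feature maps ---------------------

as_internal <- function(x) {
  if (length(dim(x)) != 3L) stop("feature map must be a 3-d array C x H x W")
  if (!all(is.finite(x))) stop("feature map must be finite")
  y <- aperm(x, c(2, 3, 1))
  dim(y) <- c(dim(y), 1L)
  y
}

as_channel_first <- function(x) {
  d <- dim(x)
  dim(x) <- d[1:3]
  aperm(x, c(3, 1, 2))
}

#' Apply an ECA gate to a feature map
#'
#' @param x a C x H x W array.
#' @param m an [eca_layer()] module (a fresh fixed-k layer is created when
#'   omitted).
#' @param weights optional numeric vector of odd length replacing the
#'   module's 1-d kernel (handy for deterministic use).
#' @return gated C x H x W array, same shape as `x`.
#' @export
eca_gate <- function(x, m = NULL, weights = NULL) {
  if (is.null(m)) m <- eca_layer(k = if (is.null(weights)) 3L else length(weights))
  if (!is.null(weights)) m$w <- as.numeric(weights)
  as_channel_first(m$forward(as_internal(x)))
}

#' GAM channel-attention stage
#'
#' @param x a C x H x W array with C divisible by the module's reduction.
#' @param m a [gam()] module (fresh random one if omitted).
#' @return list with `Mc` (the channel attention map, entries in (0,1)) and
#'   `F2 = Mc * x`, both C x H x W.
#' @export
gam_channel <- function(x, m = NULL) {
  if (is.null(m)) m <- gam(dim(x)[1])
  f2 <- m$ch$forward(as_internal(x))
  list(Mc = as_channel_first(m$ch$gate), F2 = as_channel_first(f2))
}

#' GAM spatial-attention stage
#'
#' @param x a C x H x W array (normally the output of [gam_channel()]).
#' @param m a [gam()] module.
#' @return list with `Ms` (spatial attention map) and `F3 = Ms * x`.
#' @export
gam_spatial <- function(x, m = NULL) {
  if (is.null(m)) m <- gam(dim(x)[1])
  f3 <- m$sp$forward(as_internal(x))
  list(Ms = as_channel_first(m$sp$gate), F3 = as_channel_first(f3))
}

#' Apply a full GAM (channel then spatial attention)
#'
#' @inheritParams gam_channel
#' @return gated C x H x W array.
#' @export
gam_gate <- function(x, m = NULL) {
  if (is.null(m)) m <- gam(dim(x)[1])
  as_channel_first(m$forward(as_internal(x)))
}
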