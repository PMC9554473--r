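# Composite CSP-Darknet building blocks: bottleneck, C3 / ECA-C3, SPP, Focus.
# All convolutions are bias-free and followed by affine batch norm + SiLU,
# the convention that reproduces the published per-layer parameter table.

nn_bottleneck <- function(c, shortcut = TRUE, e = 1.0) {
  ch <- as.integer(c * e)
  m <- new_module("bottleneck")
  m$shortcut <- shortcut
  m$cv1 <- conv_block(c, ch, 1L)
  m$cv2 <- conv_block(ch, c, 3L)
  m$children <- list(m$cv1, m$cv2)
  m$forward <- function(x, train = FALSE) {
    y <- m$cv2$forward(m$cv1$forward(x, train), train)
    if (m$shortcut) y + x else y
  }
  m$backward <- function(dy) {
    dx <- m$cv1$backward(m$cv2$backward(dy))
    if (m$shortcut) dx + dy else dx
  }
  m
}

#' Cross-stage-partial (C3) block
#'
#' Two parallel 1x1 branches (each to `cout/2` hidden channels), `n` stacked
#' bottlenecks on the first branch, channel concatenation and a 1x1 fusion
#' convolution.  Hidden-channel expansion is 0.5.
#'
#' @param cin,cout input/output channel counts.
#' @param n number of bottlenecks.
#' @param shortcut residual connections inside the bottlenecks (on in the
#'   backbone, off in the neck).
#' @return an nn module.
#' @export
c3_block <- function(cin, cout, n = 1L, shortcut = TRUE) {
  ch <- as.integer(cout * 0.5)
  m <- new_module("c3")
  m$cv1 <- conv_block(cin, ch, 1L)
  m$cv2 <- conv_block(cin, ch, 1L)
  m$cv3 <- conv_block(2L * ch, cout, 1L)
  m$m <- nn_sequential(lapply(seq_len(n), function(i) {
    nn_bottleneck(ch, shortcut)
  }))
  m$children <- list(m$cv1, m$cv2, m$cv3, m$m)
  m$forward <- function(x, train = FALSE) {
    y1 <- m$m$forward(m$cv1$forward(x, train), train)
    y2 <- m$cv2$forward(x, train)
    m$ch <- c(dim(y1)[3], dim(y2)[3])
    m$cv3$forward(cat_channels(list(y1, y2)), train)
  }
  m$backward <- function(dy) {
    dcat <- m$cv3$backward(dy)
    ds <- split_channels(dcat, m$ch)
    m$cv1$backward(m$m$backward(ds[[1]])) + m$cv2$backward(ds[[2]])
  }
  m
}

#' C3 block with an ECA channel gate
#'
#' A [c3_block()] whose 1x1 fusion output passes through an efficient
#' channel attention gate.  With the default fixed 3-tap kernel this adds
#' exactly 3 trainable parameters over the plain block.
#'
#' @inheritParams c3_block
#' @param eca_mode `"fixed3"` or `"adaptive"` (kernel from [eca_kernel_size()]).
#' @return an nn module.
#' @export
eca_c3_block <- function(cin, cout, n = 1L, shortcut = TRUE,
                         eca_mode = c("fixed3", "adaptive")) {
  eca_mode <- match.arg(eca_mode)
  m <- new_module("eca_c3")
  m$c3 <- c3_block(cin, cout, n, shortcut)
  m$eca <- eca_layer(channels = cout, kernel_mode = eca_mode)
  m$children <- list(m$c3, m$eca)
  m$forward <- function(x, train = FALSE) {
    m$eca$forward(m$c3$forward(x, train), train)
  }
  m$backward <- function(dy) m$c3$backward(m$eca$backward(dy))
  m
}

#' Spatial pyramid pooling (SPP) block
#'
#' 1x1 reduction to `cin/2`, parallel max-pools (stride 1, same padding) of
#' sizes `pools`, concatenation with the unpooled map, 1x1 expansion.
#'
#' @param cin,cout channel counts.
#' @param pools pooling window sizes (default 5, 9, 13).
#' @return an nn module.
#' @export
spp_block <- function(cin, cout, pools = c(5L, 9L, 13L)) {
  ch <- cin %/% 2L
  m <- new_module("spp")
  m$cv1 <- conv_block(cin, ch, 1L)
  m$cv2 <- conv_block(ch * (length(pools) + 1L), cout, 1L)
  m$pools <- lapply(pools, nn_maxpool)
  m$children <- c(list(m$cv1, m$cv2), m$pools)
  m$forward <- function(x, train = FALSE) {
    y <- m$cv1$forward(x, train)
    ys <- c(list(y), lapply(m$pools, function(p) p$forward(y, train)))
    m$ch <- vapply(ys, function(v) dim(v)[3], numeric(1))
    m$cv2$forward(cat_channels(ys), train)
  }
  m$backward <- function(dy) {
    ds <- split_channels(m$cv2$backward(dy), m$ch)
    dcv1 <- ds[[1]]
    for (i in seq_along(m$pools)) {
      dcv1 <- dcv1 + m$pools[[i]]$backward(ds[[i + 1L]])
    }
    m$cv1$backward(dcv1)
  }
  m
}

# Focus stem: space-to-depth slicing of the RGB input into 12 channels
# (2x2 pixel dealiasing) followed by a 3x3 conv block.
nn_focus <- function(cout) {
  m <- new_module("focus")
  m$conv <- conv_block(12L, cout, 3L)
  m$conv$children[[1]]$need_dx <- FALSE   # stem: no gradient to the image
  m$children <- list(m$conv)
  slice_idx <- function(n) list(o = seq(1L, n, 2L), e = seq(2L, n, 2L))
  m$forward <- function(x, train = FALSE) {
    d <- dim(x)
    r <- slice_idx(d[1]); cc <- slice_idx(d[2])
    y <- cat_channels(list(x[r$o, cc$o, , , drop = FALSE],
                           x[r$e, cc$o, , , drop = FALSE],
                           x[r$o, cc$e, , , drop = FALSE],
                           x[r$e, cc$e, , , drop = FALSE]))
    m$in_dim <- d
    m$conv$forward(y, train)
  }
  m$backward <- function(dy) {
    ds <- m$conv$backward(dy)
    d <- m$in_dim
    dx <- array(0, dim = d)
    r <- slice_idx(d[1]); cc <- slice_idx(d[2])
    dx[r$o, cc$o, , ] <- ds[, , 1:3, , drop = FALSE]
    dx[r$e, cc$o, , ] <- ds[, , 4:6, , drop = FALSE]
    dx[r$o, cc$e, , ] <- ds[, , 7:9, , drop = FALSE]
    dx[r$e, cc$e, , ] <- ds[, , 10:12, , drop = FALSE]
    dx
  }
  m
}

# Detection stage: per scale a GAM (when enabled) followed by a biased 1x1
# prediction convolution to 3 anchors x (5 + nc) channels.
nn_detect <- function(chs, nc = 1L, strides = c(8L, 16L, 32L),
                      use_gam = TRUE, gam_reduction = 4L) {
  m <- new_module("detect")
  no <- 3L * (5L + nc)
  m$nc <- nc; m$no <- no
  m$gams <- if (use_gam) {
    lapply(chs, function(c) gam(c, gam_reduction))
  } else {
    list()
  }
  m$convs <- lapply(seq_along(chs), function(i) {
    cv <- nn_conv2d(chs[i], no, 1L, bias = TRUE)
    # objectness prior: start expecting ~8 objects per 640-pixel image scale
    obj_idx <- (0:2) * (5L + nc) + 5L
    cv$b[obj_idx] <- log(8 / (640 / strides[i])^2)
    cv
  })
  m$children <- c(m$gams, m$convs)
  m$forward <- function(xs, train = FALSE) {
    lapply(seq_along(xs), function(i) {
      x <- xs[[i]]
      if (length(m$gams)) x <- m$gams[[i]]$forward(x, train)
      m$convs[[i]]$forward(x, train)
    })
  }
  m$backward <- function(dys) {
    lapply(seq_along(dys), function(i) {
      dx <- m$convs[[i]]$backward(dys[[i]])
      if (length(m$gams)) dx <- m$gams[[i]]$backward(dx)
      dx
    })
  }
  m
}
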