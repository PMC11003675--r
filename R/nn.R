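# Minimal neural-network engine: dense / 1-D and 2-D same-padded convolution /
# 2x average pooling layers with hand-written backpropagation, Glorot-uniform
# initialization and the Adam optimizer.  Tensors are base-R arrays with the
# batch as the first dimension; all heavy lifting is BLAS-backed matrix
# multiplication.  Internal: none of this is part of the package interface.

glorot_init <- function(fan_in, fan_out, dims = c(fan_in, fan_out)) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

relu <- function(x) x * (x > 0)

# --- Adam -------------------------------------------------------------------

adam_new <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# --- 1-D convolution (kernel 3, same padding) --------------------------------
# x: array (B, d, Cin); W: matrix (3*Cin, Cout); b: numeric Cout

conv1d_cat <- function(x) {
  dm <- dim(x); B <- dm[1]; d <- dm[2]; C <- dm[3]
  xl <- array(0, dm); xr <- array(0, dm)
  if (d > 1) {
    xl[, 2:d, ] <- x[, 1:(d - 1), , drop = FALSE]
    xr[, 1:(d - 1), ] <- x[, 2:d, , drop = FALSE]
  }
  array(c(xl, x, xr), dim = c(B, d, 3 * C))
}

conv1d_fwd <- function(x, W, b) {
  xc <- conv1d_cat(x)
  dm <- dim(x)
  y <- matrix(xc, dm[1] * dm[2], dim(W)[1]) %*% W
  y <- sweep(y, 2L, b, `+`)
  list(y = array(y, c(dm[1], dm[2], dim(W)[2])), xc = xc)
}

conv1d_bwd <- function(dy, xc, W) {
  dm <- dim(dy); B <- dm[1]; d <- dm[2]
  dym <- matrix(dy, B * d, dm[3])
  xcm <- matrix(xc, B * d, dim(W)[1])
  dW <- crossprod(xcm, dym)
  db <- colSums(dym)
  dxc <- array(dym %*% t(W), c(B, d, dim(W)[1]))
  C <- dim(W)[1] / 3
  dl <- dxc[, , 1:C, drop = FALSE]
  dm_ <- dxc[, , (C + 1):(2 * C), drop = FALSE]
  dr <- dxc[, , (2 * C + 1):(3 * C), drop = FALSE]
  dx <- dm_
  if (d > 1) {
    dx[, 1:(d - 1), ] <- dx[, 1:(d - 1), , drop = FALSE] + dl[, 2:d, , drop = FALSE]
    dx[, 2:d, ] <- dx[, 2:d, , drop = FALSE] + dr[, 1:(d - 1), , drop = FALSE]
  }
  list(dx = dx, dW = dW, db = db)
}

# --- 1-D average pooling, width 2 stride 2 (d must be even) ------------------

pool1d_fwd <- function(x) {
  dm <- dim(x); d2 <- dm[2] %/% 2L
  od <- seq(1L, 2L * d2, by = 2L)
  (x[, od, , drop = FALSE] + x[, od + 1L, , drop = FALSE]) / 2
}

pool1d_bwd <- function(dy, d) {
  dm <- dim(dy)
  dx <- array(0, c(dm[1], d, dm[3]))
  od <- seq(1L, 2L * dm[2], by = 2L)
  dx[, od, ] <- dy / 2
  dx[, od + 1L, ] <- dy / 2
  dx
}

# --- 2-D convolution (3x3, same padding) -------------------------------------
# Spatial tensors are handled as (B*H*W, C) matrices (batch-fastest layout);
# the nine kernel taps are gathered with precomputed row-index maps, which
# keeps the hot path in plain matrix indexing and one GEMM.

.conv_idx_cache <- new.env(parent = emptyenv())

get_conv_index <- function(B, H, W) {
  key <- paste(B, H, W, sep = "x")
  m <- .conv_idx_cache[[key]]
  if (is.null(m)) {
    m <- conv2d_index(B, H, W)
    .conv_idx_cache[[key]] <- m
  }
  m
}

conv2d_index <- function(B, H, W) {
  maps <- vector("list", 9L)
  o <- 1L
  for (dj in -1:1) for (di in -1:1) {
    ri <- max(1, 1 + di):min(H, H + di)
    rj <- max(1, 1 + dj):min(W, W + dj)
    b <- seq_len(B)
    # row index of (b, h, w) in the (B*H*W, C) matrix: b + B(h-1) + BH(w-1)
    dst <- as.vector(outer(outer(b, B * (ri - 1L), `+`),
                           B * H * (rj - 1L), `+`))
    src <- as.vector(outer(outer(b, B * (ri - di - 1L), `+`),
                           B * H * (rj - dj - 1L), `+`))
    maps[[o]] <- list(dst = dst, src = src)
    o <- o + 1L
  }
  maps
}

# x: array (B, H, W, Cin) or (n, Cin) matrix with `maps` from conv2d_index
conv2d_fwd <- function(x, W, b, maps = NULL) {
  dm <- dim(x)
  if (length(dm) == 4L) {
    if (is.null(maps)) maps <- conv2d_index(dm[1], dm[2], dm[3])
    x <- matrix(x, prod(dm[1:3]), dm[4])
  }
  n <- nrow(x); C <- ncol(x)
  xc <- matrix(0, n, 9L * C)
  for (o in 1:9) {
    xc[maps[[o]]$dst, ((o - 1L) * C + 1L):(o * C)] <-
      x[maps[[o]]$src, , drop = FALSE]
  }
  y <- xc %*% W
  y <- sweep(y, 2L, b, `+`)
  if (length(dm) == 4L) y <- array(y, c(dm[1:3], dim(W)[2]))
  list(y = y, xc = xc)
}

# dy: (n, Cout) matrix (or 4-D array); returns dx as (n, Cin) matrix
conv2d_bwd <- function(dy, xc, W, maps) {
  dm <- dim(dy)
  if (length(dm) == 4L) dy <- matrix(dy, prod(dm[1:3]), dm[4])
  dW <- crossprod(xc, dy)
  db <- colSums(dy)
  dxc <- dy %*% t(W)
  C <- dim(W)[1] / 9L
  dx <- matrix(0, nrow(dy), C)
  for (o in 1:9) {
    dx[maps[[o]]$src, ] <- dx[maps[[o]]$src, , drop = FALSE] +
      dxc[maps[[o]]$dst, ((o - 1L) * C + 1L):(o * C), drop = FALSE]
  }
  list(dx = dx, dW = dW, db = db)
}

# --- 2-D average pooling, 2x2 stride 2 (floor semantics) ---------------------

pool2d_fwd <- function(x) {
  dm <- dim(x); H2 <- dm[2] %/% 2L; W2 <- dm[3] %/% 2L
  oi <- seq(1L, 2L * H2, by = 2L); oj <- seq(1L, 2L * W2, by = 2L)
  (x[, oi, oj, , drop = FALSE] + x[, oi + 1L, oj, , drop = FALSE] +
   x[, oi, oj + 1L, , drop = FALSE] + x[, oi + 1L, oj + 1L, , drop = FALSE]) / 4
}

pool2d_bwd <- function(dy, H, W) {
  dm <- dim(dy)
  dx <- array(0, c(dm[1], H, W, dm[4]))
  oi <- seq(1L, 2L * dm[2], by = 2L); oj <- seq(1L, 2L * dm[3], by = 2L)
  q <- dy / 4
  dx[, oi, oj, ] <- q
  dx[, oi + 1L, oj, ] <- q
  dx[, oi, oj + 1L, ] <- q
  dx[, oi + 1L, oj + 1L, ] <- q
  dx
}
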