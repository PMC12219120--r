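# Low-level neural-network primitives for the attention ConvNet.
#
# Feature maps are stored as (H*W) x C matrices, pixels column-major
# (row index fastest), so convolutions become one BLAS matrix product over
# an im2col patch matrix. All geometry (patch and pool index tables) is
# precomputed once per architecture.

# im2col index table for a 3x3 same-padded convolution on an H x W map.
# Entry [q, o] is the padded linear index of offset o around position q;
# H*W + 1 addresses the shared zero pad row.
conv3_indices <- function(H, W) {
  i <- rep(seq_len(H), W)
  j <- rep(seq_len(W), each = H)
  pad <- H * W + 1L
  idx <- matrix(pad, H * W, 9L)
  o <- 0L
  for (dj in -1:1) {
    for (di in -1:1) {
      o <- o + 1L
      ii <- i + di
      jj <- j + dj
      ok <- ii >= 1L & ii <= H & jj >= 1L & jj <= W
      idx[ok, o] <- ii[ok] + (jj[ok] - 1L) * H
    }
  }
  idx
}

# 2x2 valid max-pool index table: [q_out, k] linear input index of the k-th
# element of output cell q_out. Odd trailing rows/cols are dropped.
pool2_indices <- function(H, W) {
  Hp <- H %/% 2L
  Wp <- W %/% 2L
  pi <- rep(seq_len(Hp), Wp)
  pj <- rep(seq_len(Wp), each = Hp)
  base_i <- 2L * pi - 1L
  base_j <- 2L * pj - 1L
  cbind(base_i + (base_j - 1L) * H,
        base_i + 1L + (base_j - 1L) * H,
        base_i + base_j * H,
        base_i + 1L + base_j * H)
}

# Patch matrix: x is (H*W) x Cin; returns (H*W) x (9*Cin), columns ordered
# offset-fastest within channel (matching the conv weight row layout).
im2col3 <- function(x, idx) {
  npos <- nrow(idx)
  cin <- ncol(x)
  xa <- rbind(x, 0)
  p <- xa[as.vector(idx), , drop = FALSE]     # (npos*9) x Cin, position fastest
  dim(p) <- c(npos, 9L * cin)
  p
}

# Adjoint of im2col3: scatter-add a (H*W) x (9*Cin) gradient back to the
# (H*W) x Cin input.
col2im3 <- function(dp, idx, cin) {
  npos <- nrow(idx)
  dim(dp) <- c(npos * 9L, cin)
  acc <- rowsum(dp, group = as.vector(idx))
  out <- matrix(0, npos + 1L, cin)
  out[as.integer(rownames(acc)), ] <- acc
  out[seq_len(npos), , drop = FALSE]
}

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) {
  x[x < 0] <- 0
  x
}

glorot <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -lim, lim), dims)
}

maxpool_forward <- function(x, pidx) {
  v1 <- x[pidx[, 1], , drop = FALSE]
  arg <- matrix(1L, nrow(pidx), ncol(x))
  mx <- v1
  for (k in 2:4) {
    vk <- x[pidx[, k], , drop = FALSE]
    upd <- vk > mx
    arg[upd] <- k
    mx[upd] <- vk[upd]
  }
  list(out = mx, arg = arg)
}

maxpool_backward <- function(dy, arg, pidx, npos_in) {
  dx <- matrix(0, npos_in, ncol(dy))
  for (k in 1:4) {
    rows <- pidx[, k]
    dx[rows, ] <- dx[rows, ] + dy * (arg == k)
  }
  dx
}

# Softmax over a vector of logits.
softmax_vec <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# ---- Adam optimiser state over a named list of arrays -----------------------

adam_init <- function(params) {
  zeros <- lapply(params, function(p) { p[] <- 0; p })
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-7) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}
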