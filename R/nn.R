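# Convolutional network primitives in base R. Convolutions are computed as
# BLAS matrix products of im2col patch matrices; backward passes reverse the
# same mapping. Arrays are laid out (H, W, C) per slice throughout.

conv_spec <- function(c_in, c_out, k, stride, pad) {
  list(c_in = c_in, c_out = c_out, k = k, stride = stride, pad = pad)
}

conv_out_size <- function(n, k, stride, pad) (n + 2L * pad - k) %/% stride + 1L

# He-normal initialization.
conv_init <- function(spec, gain = sqrt(2)) {
  fan_in <- spec$k * spec$k * spec$c_in
  W <- matrix(stats::rnorm(fan_in * spec$c_out, 0, gain / sqrt(fan_in)),
              fan_in, spec$c_out)
  c(spec, list(W = W, b = numeric(spec$c_out)))
}

pad_hwc <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2L * p, d[2] + 2L * p, d[3]))
  out[(p + 1L):(p + d[1]), (p + 1L):(p + d[2]), ] <- x
  out
}

# Patch matrix: rows = output positions (column-major over H' x W'),
# columns = (ky, kx) kernel offset blocks of c_in channels each.
# Implemented as one vectorized gather with a memoized linear-index matrix.
nn_env <- new.env(parent = emptyenv())

im2col_index <- function(ph, pw, k, stride, out_h, out_w, c_in) {
  key <- paste(ph, pw, k, stride, out_h, out_w, c_in, sep = "_")
  idx <- nn_env[[key]]
  if (is.null(idx)) {
    ry <- seq(0L, by = stride, length.out = out_h)           # 0-based row
    cx <- seq(0L, by = stride, length.out = out_w)           # 0-based col
    pos <- outer(ry, cx * ph, `+`)                           # out_h x out_w
    idx <- matrix(0L, out_h * out_w, k * k * c_in)
    j <- 0L
    for (kx in seq_len(k)) {
      for (ky in seq_len(k)) {
        base <- as.integer(pos) + (ky + (kx - 1L) * ph)
        for (c in seq_len(c_in)) {
          j <- j + 1L
          idx[, j] <- base + (c - 1L) * ph * pw
        }
      }
    }
    nn_env[[key]] <- idx
  }
  idx
}

im2col <- function(xp, k, stride, out_h, out_w, c_in) {
  d <- dim(xp)
  idx <- im2col_index(d[1], d[2], k, stride, out_h, out_w, c_in)
  cols <- xp[idx]
  dim(cols) <- dim(idx)
  cols
}

# Scatter-add of the patch-matrix gradient back onto the (padded) input grid.
col2im <- function(dcols, k, stride, out_h, out_w, c_in, ph, pw) {
  dxp <- array(0, c(ph, pw, c_in))
  j <- 0L
  for (kx in seq_len(k)) {
    cx <- seq(kx, by = stride, length.out = out_w)
    for (ky in seq_len(k)) {
      ry <- seq(ky, by = stride, length.out = out_h)
      dxp[ry, cx, ] <- dxp[ry, cx, ] +
        array(dcols[, (j + 1L):(j + c_in)], c(out_h, out_w, c_in))
      j <- j + c_in
    }
  }
  dxp
}

conv_forward <- function(x, layer, keep_cache = FALSE) {
  d <- dim(x)
  out_h <- conv_out_size(d[1], layer$k, layer$stride, layer$pad)
  out_w <- conv_out_size(d[2], layer$k, layer$stride, layer$pad)
  xp <- pad_hwc(x, layer$pad)
  cols <- im2col(xp, layer$k, layer$stride, out_h, out_w, layer$c_in)
  y <- cols %*% layer$W
  y <- sweep(y, 2L, layer$b, `+`)
  out <- array(y, c(out_h, out_w, layer$c_out))
  if (keep_cache) {
    list(y = out, cache = list(cols = cols, in_dim = d, out_h = out_h,
                               out_w = out_w))
  } else {
    list(y = out, cache = NULL)
  }
}

# Returns gradients w.r.t. weights, bias and (optionally) the layer input.
conv_backward <- function(dy, layer, cache, need_dx = TRUE) {
  dym <- matrix(dy, cache$out_h * cache$out_w, layer$c_out)
  dW <- crossprod(cache$cols, dym)
  db <- colSums(dym)
  dx <- NULL
  if (need_dx) {
    dcols <- dym %*% t(layer$W)
    d <- cache$in_dim
    dxp <- col2im(dcols, layer$k, layer$stride, cache$out_h, cache$out_w,
                  layer$c_in, d[1] + 2L * layer$pad, d[2] + 2L * layer$pad)
    p <- layer$pad
    dx <- if (p > 0L) {
      dxp[(p + 1L):(p + d[1]), (p + 1L):(p + d[2]), , drop = FALSE]
    } else dxp
  }
  list(dW = dW, db = db, dx = dx)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Fixed (parameter-free) box average pooling by an integer factor, applied to
# the raw input before the first convolution. Implemented as P X P' per
# channel with a banded pooling matrix.
pool_matrix <- function(n, factor) {
  out_n <- n %/% factor
  P <- matrix(0, out_n, n)
  for (i in seq_len(out_n)) P[i, ((i - 1L) * factor + 1L):(i * factor)] <- 1 / factor
  P
}

avgpool_hwc <- function(x, P) {
  d <- dim(x)
  out <- array(0, c(nrow(P), nrow(P), d[3]))
  for (c in seq_len(d[3])) out[, , c] <- P %*% x[, , c] %*% t(P)
  out
}

# Max pooling (used only by the frozen AlexNet-shaped backbone; no backward).
maxpool_hwc <- function(x, k, stride) {
  d <- dim(x)
  out_h <- (d[1] - k) %/% stride + 1L
  out_w <- (d[2] - k) %/% stride + 1L
  out <- array(-Inf, c(out_h, out_w, d[3]))
  for (ky in seq_len(k)) {
    ry <- seq(ky, by = stride, length.out = out_h)
    for (kx in seq_len(k)) {
      cx <- seq(kx, by = stride, length.out = out_w)
      out <- pmax(out, x[ry, cx, , drop = FALSE])
    }
  }
  out
}

# Adaptive average pooling to a fixed output grid (bin edges floor/ceil of
# the proportional positions, so it works for output sizes above or below
# the input size).
adaptive_avgpool_hwc <- function(x, out_n) {
  d <- dim(x)
  pool_1d <- function(n) {
    starts <- floor((seq_len(out_n) - 1L) * n / out_n) + 1L
    ends <- ceiling(seq_len(out_n) * n / out_n)
    list(starts = starts, ends = ends)
  }
  by <- pool_1d(d[1]); bx <- pool_1d(d[2])
  out <- array(0, c(out_n, out_n, d[3]))
  for (i in seq_len(out_n)) {
    for (j in seq_len(out_n)) {
      out[i, j, ] <- apply(x[by$starts[i]:by$ends[i],
                             bx$starts[j]:bx$ends[j], , drop = FALSE],
                           3, mean)
    }
  }
  out
}

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

# Adam optimizer state and update for a flat list of parameter matrices.
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

# `lr` is either a scalar or a named vector giving one learning rate per
# parameter (parameter-group learning rates).
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    lr_nm <- if (length(lr) > 1L) lr[[nm]] else lr
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr_nm * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
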