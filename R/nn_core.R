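# Minimal dense/conv neural-network primitives with manual backprop.
#
# Feature maps are arrays dim = c(channels, height, width, batch). Convs use
# im2col gather + one BLAS matmul; gather index maps are cached per shape.
# Stride-1 same-padding convolutions backpropagate the input gradient as a
# convolution with the spatially flipped, channel-transposed kernel (no
# scatter); strided convolutions fall back to an index scatter (rowsum).

.nn_cache <- new.env(parent = emptyenv())

# im2col gather indices into the zero-padded array (C, Hp, Wp, B).
# Column-matrix rows are ordered channel-fastest, then kh, then kw; columns
# are output positions (oh fastest), then batch.
.conv_idx <- function(C, H, W, B, k, stride, pad) {
  key <- paste("ci", C, H, W, B, k, stride, pad, sep = "_")
  hit <- .nn_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  OH <- (Hp - k) %/% stride + 1L
  OW <- (Wp - k) %/% stride + 1L
  ckk <- C * k * k
  c_i <- rep_len(seq_len(C), ckk)
  kh_i <- rep(rep(seq_len(k), each = C), times = k)
  kw_i <- rep(seq_len(k), each = C * k)
  oh_j <- rep(seq_len(OH), times = OW)
  ow_j <- rep(seq_len(OW), each = OH)
  h_mat <- outer(kh_i, (oh_j - 1L) * stride, "+")       # ckk x OH*OW
  w_mat <- outer(kw_i, (ow_j - 1L) * stride, "+")
  idx0 <- c_i + C * (h_mat - 1L) + C * Hp * (w_mat - 1L)
  per <- C * Hp * Wp
  idx <- as.integer(rep(as.vector(idx0), times = B) +
    rep((0:(B - 1L)) * per, each = length(idx0)))
  out <- list(idx = idx, OH = OH, OW = OW, Hp = Hp, Wp = Wp, ckk = ckk)
  .nn_cache[[key]] <- out
  out
}

.pad_input <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1], d[2] + 2L * pad, d[3] + 2L * pad, d[4]))
  xp[, pad + seq_len(d[2]), pad + seq_len(d[3]), ] <- x
  xp
}

# W: (Cout x Cin*k*k), b: length Cout. Returns out plus a backward cache.
conv_fwd <- function(x, W, b, k = 3L, stride = 1L, pad = 1L) {
  d <- dim(x)
  ci <- .conv_idx(d[1], d[2], d[3], d[4], k, stride, pad)
  xp <- .pad_input(x, pad)
  col <- xp[ci$idx]
  dim(col) <- c(ci$ckk, ci$OH * ci$OW * d[4])
  out <- W %*% col + b
  dim(out) <- c(nrow(W), ci$OH, ci$OW, d[4])
  list(out = out, col = col, xdim = d, k = k, stride = stride, pad = pad)
}

# Rearrange (Cout, Cin*k*k) into the transposed-flipped kernel
# (Cin, Cout*k*k) used to backpropagate a stride-1 convolution.
.flip_kernel <- function(W, Cin, k) {
  Wk <- array(W, c(nrow(W), Cin, k, k))
  Wk <- Wk[, , k:1, k:1, drop = FALSE]      # spatial flip
  Wk <- aperm(Wk, c(2, 1, 3, 4))            # swap in/out channels
  matrix(Wk, Cin, nrow(W) * k * k)
}

conv_bwd <- function(dout, W, cache) {
  co <- nrow(W)
  dmat <- dout
  dim(dmat) <- c(co, length(dout) / co)
  dW <- tcrossprod(dmat, cache$col)
  db <- rowSums(dmat)
  d <- cache$xdim
  if (cache$stride == 1L && cache$pad == (cache$k - 1L) %/% 2L) {
    Wt <- .flip_kernel(W, d[1], cache$k)
    dx <- conv_fwd(dout, Wt, numeric(d[1]), k = cache$k, stride = 1L,
                   pad = cache$pad)$out
  } else {
    ci <- .conv_idx(d[1], d[2], d[3], d[4], cache$k, cache$stride, cache$pad)
    dcol <- crossprod(W, dmat)
    dxp <- numeric(d[1] * ci$Hp * ci$Wp * d[4])
    # scatter-add row by row: within one im2col row (fixed channel and
    # kernel offset) every output position reads a distinct input pixel,
    # so plain indexed addition accumulates correctly
    idxm <- ci$idx
    dim(idxm) <- dim(dcol)
    for (r in seq_len(ci$ckk)) {
      ii <- idxm[r, ]
      dxp[ii] <- dxp[ii] + dcol[r, ]
    }
    dim(dxp) <- c(d[1], ci$Hp, ci$Wp, d[4])
    p <- cache$pad
    dx <- dxp[, p + seq_len(d[2]), p + seq_len(d[3]), , drop = FALSE]
  }
  list(dx = dx, dW = dW, db = db)
}

relu_fwd <- function(x) {
  out <- x
  out[out < 0] <- 0
  out
}
relu_bwd <- function(dout, x) dout * (x > 0)

# Leaky rectifier (used in the dose-difference decoder, where hard ReLU
# units die under the sign-based MAE gradient).
lrelu_fwd <- function(x, slope = 0.1) {
  neg <- x < 0
  x[neg] <- x[neg] * slope
  x
}
lrelu_bwd <- function(dout, x, slope = 0.1) dout * ifelse(x > 0, 1, slope)

# 1-D bilinear x2 interpolation operator (2n x n), pixel-centre aligned.
.up2_mat <- function(n) {
  key <- paste0("u2_", n)
  hit <- .nn_cache[[key]]
  if (!is.null(hit)) return(hit)
  U <- matrix(0, 2L * n, n)
  for (i in seq_len(2L * n)) {
    src <- (i - 0.5) / 2 + 0.5
    i0 <- floor(src)
    fr <- src - i0
    i0c <- min(max(i0, 1L), n)
    i1c <- min(max(i0 + 1L, 1L), n)
    U[i, i0c] <- U[i, i0c] + (1 - fr)
    U[i, i1c] <- U[i, i1c] + fr
  }
  .nn_cache[[key]] <- U
  U
}

# Apply matrix M along array dimension `along` (2 or 3).
.apply_dim <- function(x, M, along) {
  d <- dim(x)
  perm <- c(along, setdiff(1:4, along))
  xp <- aperm(x, perm)
  dim(xp) <- c(d[along], prod(d[-along]))
  y <- M %*% xp
  dim(y) <- c(nrow(M), d[perm[-1]])
  aperm(y, order(perm))
}

upsample2_fwd <- function(x) {
  d <- dim(x)
  .apply_dim(.apply_dim(x, .up2_mat(d[2]), 2L), .up2_mat(d[3]), 3L)
}
upsample2_bwd <- function(dout, in_dim) {
  .apply_dim(.apply_dim(dout, t(.up2_mat(in_dim[2])), 2L),
             t(.up2_mat(in_dim[3])), 3L)
}

# Global average pool (C,H,W,B) -> (C,B).
gap_fwd <- function(x) {
  d <- dim(x)
  m <- matrix(aperm(x, c(2, 3, 1, 4)), d[2] * d[3], d[1] * d[4])
  matrix(colMeans(m), d[1], d[4])
}
gap_bwd <- function(dout, d) {
  hw <- d[2] * d[3]
  g <- array(0, d)
  g[] <- aperm(array(rep(dout / hw, each = hw), c(d[2], d[3], d[1], d[4])),
               c(3, 1, 2, 4))
  g
}

# Adam optimizer state as an environment keyed like the parameter list.
adam_init <- function(params, lr = 5e-4, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  e <- new.env(parent = emptyenv())
  e$lr <- lr; e$beta1 <- beta1; e$beta2 <- beta2; e$eps <- eps; e$t <- 0L
  e$m <- lapply(params, function(p) p * 0)
  e$v <- lapply(params, function(p) p * 0)
  e
}

adam_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  c1 <- 1 - b1^opt$t; c2 <- 1 - b2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * g
    opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * g * g
    params[[nm]] <- params[[nm]] -
      opt$lr * (opt$m[[nm]] / c1) / (sqrt(opt$v[[nm]] / c2) + opt$eps)
  }
  params
}
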