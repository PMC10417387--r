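# Low-level tensor operations for the convolutional network.
#
# Feature maps are numeric arrays of dimension (C, H, W, N) — channel
# fastest — so per-channel broadcasting works by column-major recycling
# and im2col products map onto single BLAS calls. All backward passes are
# written out explicitly; there is no autodiff.

# ---- im2col machinery ------------------------------------------------

# Precompute the gather index for an im2col of a (C, H, W) volume with
# square kernel k, stride and symmetric zero padding. Row order of the
# column matrix is (c fastest, dh, dw); column order is (ho fastest, wo).
im2col_index <- function(C, H, W, k, stride, pad) {
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Ho <- (Hp - k) %/% stride + 1L
  Wo <- (Wp - k) %/% stride + 1L
  pe <- c(outer(c(outer(seq_len(C), (0:(k - 1L)) * C, "+")),
               (0:(k - 1L)) * C * Hp, "+"))
  bases <- c(outer((0:(Ho - 1L)) * stride * C,
                   (0:(Wo - 1L)) * stride * C * Hp, "+"))
  idx <- as.vector(outer(pe, bases, "+"))
  list(idx = idx, uidx = sort(unique(idx)), C = C, H = H, W = W, k = k,
       stride = stride, pad = pad, Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo)
}

pad_input <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1], d[2] + 2L * pad, d[3] + 2L * pad, d[4]))
  xp[, (pad + 1L):(pad + d[2]), (pad + 1L):(pad + d[3]), ] <- x
  xp
}

unpad_grad <- function(dxp, pad, H, W) {
  if (pad == 0L) return(dxp)
  dxp[, (pad + 1L):(pad + H), (pad + 1L):(pad + W), , drop = FALSE]
}

# column matrix (C*k*k, Ho*Wo*N) for a batch
im2col <- function(x, im) {
  N <- dim(x)[4]
  xp <- pad_input(x, im$pad)
  dim(xp) <- c(im$C * im$Hp * im$Wp, N)
  col <- xp[im$idx, , drop = FALSE]
  dim(col) <- c(im$C * im$k * im$k, im$Ho * im$Wo * N)
  col
}

# scatter-add a column-matrix gradient back to the input
col2im <- function(dcol, im, N) {
  dim(dcol) <- c(im$C * im$k * im$k * im$Ho * im$Wo, N)
  acc <- rowsum(dcol, group = im$idx, reorder = TRUE)
  dxp <- matrix(0, im$C * im$Hp * im$Wp, N)
  dxp[im$uidx, ] <- acc
  dim(dxp) <- c(im$C, im$Hp, im$Wp, N)
  unpad_grad(dxp, im$pad, im$H, im$W)
}

# ---- convolutions ----------------------------------------------------

# Standard convolution. Weights are stored as (C1, k, k, C2) so that
# matrix(w, C1*k*k, C2) rows line up with the im2col row order.
conv_forward <- function(x, w, bias = NULL, stride = 1L, pad = 0L,
                         im = NULL) {
  d <- dim(x); dw <- dim(w)
  if (d[1] != dw[1])
    stop("channel mismatch: input has ", d[1], ", kernel expects ", dw[1])
  if (is.null(im))
    im <- im2col_index(d[1], d[2], d[3], dw[2], stride, pad)
  col <- im2col(x, im)
  wm <- w; dim(wm) <- c(dw[1] * dw[2] * dw[3], dw[4])
  out <- crossprod(wm, col)
  if (!is.null(bias)) out <- out + bias
  dim(out) <- c(dw[4], im$Ho, im$Wo, d[4])
  list(out = out, col = col, im = im)
}

conv_backward <- function(dout, cache, w, has_bias = FALSE) {
  im <- cache$im; dw_dim <- dim(w)
  N <- dim(dout)[4]
  dm <- dout; dim(dm) <- c(dw_dim[4], im$Ho * im$Wo * N)
  dwm <- cache$col %*% t(dm)
  dw <- array(dwm, dw_dim)
  db <- if (has_bias) rowSums(dm) else NULL
  wm <- w; dim(wm) <- c(dw_dim[1] * dw_dim[2] * dw_dim[3], dw_dim[4])
  dcol <- wm %*% dm
  dx <- col2im(dcol, im, N)
  list(dx = dx, dw = dw, db = db)
}

# Depthwise convolution (one k x k filter per input channel, stride 1,
# same padding). Weights stored as (C, k, k).
depthwise_forward <- function(x, w, im = NULL) {
  d <- dim(x); C <- d[1]; k <- dim(w)[2]
  if (dim(w)[1] != C)
    stop("channel mismatch: input has ", d[1], ", depthwise kernel has ",
         dim(w)[1])
  if (is.null(im))
    im <- im2col_index(C, d[2], d[3], k, 1L, (k - 1L) %/% 2L)
  col <- im2col(x, im)                       # (C*k*k, P)
  P <- ncol(col)
  dim(col) <- c(C, k * k, P)
  wck <- matrix(w, C, k * k)
  out <- matrix(0, C, P)
  for (q in seq_len(k * k))
    out <- out + matrix(col[, q, ], C, P) * wck[, q]
  dim(out) <- c(C, im$Ho, im$Wo, d[4])
  list(out = out, col = col, im = im)
}

depthwise_backward <- function(dout, cache, w) {
  im <- cache$im; C <- dim(w)[1]; k <- dim(w)[2]
  N <- dim(dout)[4]
  P <- im$Ho * im$Wo * N
  dm <- dout; dim(dm) <- c(C, P)
  dwck <- matrix(0, C, k * k)
  dcol <- array(0, c(C, k * k, P))
  wck <- matrix(w, C, k * k)
  for (q in seq_len(k * k)) {
    dwck[, q] <- rowSums(matrix(cache$col[, q, ], C, P) * dm)
    dcol[, q, ] <- dm * wck[, q]
  }
  dw <- array(dwck, c(C, k, k))
  dx <- col2im(dcol, im, N)
  list(dx = dx, dw = dw)
}

# ---- other layers ----------------------------------------------------

gelu_forward <- function(x) x * pnorm(x)
gelu_backward <- function(dout, x) dout * (pnorm(x) + x * dnorm(x))

bn_forward <- function(x, gamma, beta, run_mean, run_var, training,
                       eps = 1e-5, momentum = 0.9) {
  C <- dim(x)[1]
  if (training) {
    xm <- matrix(x, nrow = C)
    m <- rowMeans(xm)
    v <- rowMeans(xm * xm) - m^2
    run_mean <- momentum * run_mean + (1 - momentum) * m
    run_var <- momentum * run_var + (1 - momentum) * v
  } else {
    m <- run_mean; v <- run_var
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- (x - m) * inv
  y <- gamma * xhat + beta
  list(out = y, xhat = xhat, inv = inv, run_mean = run_mean,
       run_var = run_var)
}

bn_backward <- function(dout, cache, gamma) {
  C <- dim(dout)[1]
  ne <- length(dout) / C
  dm <- matrix(dout, nrow = C)
  xh <- matrix(cache$xhat, nrow = C)
  dgamma <- rowSums(dm * xh)
  dbeta <- rowSums(dm)
  dxhat <- dout * gamma
  dxm <- matrix(dxhat, nrow = C)
  s1 <- rowSums(dxm)
  s2 <- rowSums(dxm * xh)
  dx <- (cache$inv / ne) * (ne * dxhat - s1 - cache$xhat * s2)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

maxpool_forward <- function(x) {
  d <- dim(x)
  if (d[2] %% 2L || d[3] %% 2L)
    stop("maxpool requires even spatial dimensions, got ", d[2], "x", d[3])
  i1 <- seq(1L, d[2], 2L); i2 <- seq(2L, d[2], 2L)
  j1 <- seq(1L, d[3], 2L); j2 <- seq(2L, d[3], 2L)
  s <- list(x[, i1, j1, , drop = FALSE], x[, i2, j1, , drop = FALSE],
            x[, i1, j2, , drop = FALSE], x[, i2, j2, , drop = FALSE])
  out <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  m1 <- s[[1]] == out
  m2 <- (s[[2]] == out) & !m1
  m3 <- (s[[3]] == out) & !m1 & !m2
  m4 <- !(m1 | m2 | m3)
  list(out = out, masks = list(m1, m2, m3, m4), in_dim = d)
}

maxpool_backward <- function(dout, cache) {
  d <- cache$in_dim
  dx <- array(0, d)
  i1 <- seq(1L, d[2], 2L); i2 <- seq(2L, d[2], 2L)
  j1 <- seq(1L, d[3], 2L); j2 <- seq(2L, d[3], 2L)
  dx[, i1, j1, ] <- dout * cache$masks[[1]]
  dx[, i2, j1, ] <- dx[, i2, j1, , drop = FALSE] + dout * cache$masks[[2]]
  dx[, i1, j2, ] <- dx[, i1, j2, , drop = FALSE] + dout * cache$masks[[3]]
  dx[, i2, j2, ] <- dx[, i2, j2, , drop = FALSE] + dout * cache$masks[[4]]
  dx
}

gap_forward <- function(x) {
  d <- dim(x)
  xm <- x; dim(xm) <- c(d[1], d[2] * d[3], d[4])
  out <- apply(xm, 3L, rowMeans)
  dim(out) <- c(d[1], d[4])
  list(out = out, in_dim = d)
}

gap_backward <- function(dout, cache) {
  d <- cache$in_dim
  dx <- array(rep(dout, each = d[2] * d[3]) / (d[2] * d[3]), c(d[2] * d[3], d[1], d[4]))
  # rebuild (C, H, W, N) ordering: dout entries vary (C, N); expand over HW
  dx <- aperm(dx, c(2L, 1L, 3L))
  dim(dx) <- d
  dx
}

dropout_forward <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(out = x, mask = NULL))
  mask <- array((runif(length(x)) >= rate) / (1 - rate), dim(x))
  list(out = x * mask, mask = mask)
}

dropout_backward <- function(dout, cache) {
  if (is.null(cache$mask)) dout else dout * cache$mask
}

softmax_cols <- function(z) {
  z <- z - rep(apply(z, 2L, max), each = nrow(z))
  e <- exp(z)
  e / rep(colSums(e), each = nrow(z))
}
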