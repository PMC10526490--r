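# Low-level network primitives (forward + backward) on N x C x H x W arrays.
# All backward passes are verified against finite differences in the test
# suite; everything runs on CPU in base R.

sigmoid <- function(x) 1 / (1 + exp(-x))

# broadcast a per-channel vector over an NCHW array
bcast_ch <- function(v, d) array(rep(v, each = d[1]), dim = d)

# per-channel sum over N, H, W
sum_ch <- function(x) {
  d <- dim(x)
  colSums(matrix(aperm(x, c(1, 3, 4, 2)), ncol = d[2]))
}

pad_nchw <- function(x, p) {
  if (p == 0) return(x)
  d <- dim(x)
  out <- array(0, dim = c(d[1], d[2], d[3] + 2 * p, d[4] + 2 * p))
  out[, , (p + 1):(p + d[3]), (p + 1):(p + d[4])] <- x
  out
}

#' Output size of a strided convolution
#'
#' The shape law `m = (n + 2 p - f) / s + 1` (integer division) for an input
#' of size `n`, padding `p`, kernel size `f` and stride `s`.
#'
#' @param n Input size. @param p Padding. @param f Kernel size. @param s Stride.
#' @return Output size `m`.
#' @export
conv_out_size <- function(n, p, f, s) {
  if (n + 2 * p < f) stop("kernel larger than padded input")
  (n + 2 * p - f) %/% s + 1L
}

# ---- standard convolution ----------------------------------------------

conv_fwd <- function(x, W, b = NULL, stride = 1L, pad = 0L) {
  d <- dim(x); N <- d[1]; Cin <- d[2]; H <- d[3]; Wd <- d[4]
  dw <- dim(W); Cout <- dw[1]; kh <- dw[3]; kw <- dw[4]
  stopifnot(dw[2] == Cin)
  xp <- pad_nchw(x, pad)
  Hout <- conv_out_size(H, pad, kh, stride)
  Wout <- conv_out_size(Wd, pad, kw, stride)
  Ymat <- matrix(0, Cout, N * Hout * Wout)
  for (i in seq_len(kh)) for (j in seq_len(kw)) {
    rows <- seq.int(i, by = stride, length.out = Hout)
    cols <- seq.int(j, by = stride, length.out = Wout)
    S <- xp[, , rows, cols, drop = FALSE]
    M <- matrix(aperm(S, c(2, 1, 3, 4)), nrow = Cin)
    Ymat <- Ymat + matrix(W[, , i, j], Cout, Cin) %*% M
  }
  if (!is.null(b)) Ymat <- Ymat + b
  y <- aperm(array(Ymat, dim = c(Cout, N, Hout, Wout)), c(2, 1, 3, 4))
  list(y = y, cache = list(xp = xp, dimx = d, W = W, has_b = !is.null(b),
                           stride = stride, pad = pad,
                           Hout = Hout, Wout = Wout))
}

conv_bwd <- function(cache, dy) {
  xp <- cache$xp; W <- cache$W
  stride <- cache$stride; pad <- cache$pad
  Hout <- cache$Hout; Wout <- cache$Wout
  d <- cache$dimx; N <- d[1]; Cin <- d[2]
  dw <- dim(W); Cout <- dw[1]; kh <- dw[3]; kw <- dw[4]
  dYmat <- matrix(aperm(dy, c(2, 1, 3, 4)), nrow = Cout)
  dW <- array(0, dim = dw)
  dxp <- array(0, dim = dim(xp))
  for (i in seq_len(kh)) for (j in seq_len(kw)) {
    rows <- seq.int(i, by = stride, length.out = Hout)
    cols <- seq.int(j, by = stride, length.out = Wout)
    S <- xp[, , rows, cols, drop = FALSE]
    M <- matrix(aperm(S, c(2, 1, 3, 4)), nrow = Cin)
    dW[, , i, j] <- dYmat %*% t(M)
    dM <- t(matrix(W[, , i, j], Cout, Cin)) %*% dYmat
    dS <- aperm(array(dM, dim = c(Cin, N, Hout, Wout)), c(2, 1, 3, 4))
    dxp[, , rows, cols] <- dxp[, , rows, cols, drop = FALSE] + dS
  }
  dx <- if (pad > 0)
    dxp[, , (pad + 1):(pad + d[3]), (pad + 1):(pad + d[4]), drop = FALSE]
  else dxp
  out <- list(dx = dx, dW = dW)
  if (cache$has_b) out$db <- rowSums(dYmat)
  out
}

# ---- batch normalization ------------------------------------------------

bn_fwd <- function(x, gamma, beta, run_mean, run_var, train,
                   momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  if (train) {
    m <- d[1] * d[3] * d[4]
    mu <- sum_ch(x) / m
    xc <- x - bcast_ch(mu, d)
    v <- sum_ch(xc^2) / m
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * v * m / max(m - 1, 1)
  } else {
    mu <- run_mean; v <- run_var
    xc <- x - bcast_ch(mu, d)
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- xc * bcast_ch(invstd, d)
  y <- xhat * bcast_ch(gamma, d) + bcast_ch(beta, d)
  list(y = y, run_mean = run_mean, run_var = run_var,
       cache = list(xhat = xhat, invstd = invstd, gamma = gamma,
                    train = train, dimx = d))
}

bn_bwd <- function(cache, dy) {
  d <- cache$dimx
  xhat <- cache$xhat
  dgamma <- sum_ch(dy * xhat)
  dbeta <- sum_ch(dy)
  gb <- bcast_ch(cache$gamma * cache$invstd, d)
  if (cache$train) {
    m <- d[1] * d[3] * d[4]
    dx <- gb / m * (m * dy - bcast_ch(dbeta, d) - xhat * bcast_ch(dgamma, d))
  } else {
    dx <- gb * dy
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

relu_fwd <- function(x) {
  y <- pmax(x, 0)
  list(y = y, cache = x > 0)
}
relu_bwd <- function(cache, dy) dy * cache

# ---- efficient channel attention ---------------------------------------

#' Adaptive 1D kernel size for channel attention
#'
#' Maps the channel count `C` to an odd 1D-convolution kernel size via
#' `k = |(log2(C) + b) / gamma|_odd`, the nearest odd integer (exact halfway
#' values round down to the smaller odd number; results are clamped to be at
#' least 1). With the defaults `gamma = 2`, `b = 1`: C = 512 gives k = 5.
#'
#' @param C Channel count (>= 1).
#' @param gamma,b Constants of the mapping (defaults 2 and 1).
#' @return An odd integer kernel size.
#' @export
eca_kernel_size <- function(C, gamma = 2, b = 1) {
  if (length(C) != 1L || !is.numeric(C) || C < 1)
    stop("'C' must be a single number >= 1")
  if (gamma <= 0) stop("'gamma' must be positive")
  t <- (log2(C) + b) / gamma
  lower <- 2 * floor((t - 1) / 2) + 1
  k <- if (t - lower > 1) lower + 2 else lower   # tie (t - lower == 1) -> lower
  as.integer(max(1, k))
}

# 1D convolution across the channel axis of an N x C matrix, zero-padded
eca_conv1d <- function(V, w) {
  k <- length(w); half <- (k - 1L) %/% 2L
  C <- ncol(V)
  S <- matrix(0, nrow(V), C)
  for (j in seq_len(k)) {
    shift <- j - 1L - half
    src <- seq_len(C) + shift
    ok <- src >= 1L & src <= C
    S[, ok] <- S[, ok, drop = FALSE] + w[j] * V[, src[ok], drop = FALSE]
  }
  S
}

eca_fwd <- function(x, w, residual = TRUE) {
  d <- dim(x)
  V <- matrix(rowMeans(matrix(x, nrow = d[1] * d[2])), d[1], d[2]) # GAP
  S <- eca_conv1d(V, w)
  G <- sigmoid(S)
  gB <- array(rep(as.vector(G), times = d[3] * d[4]), dim = d)
  y <- x * gB
  if (residual) y <- y + x
  list(y = y, cache = list(x = x, V = V, G = G, gB = gB, w = w,
                           residual = residual, dimx = d))
}

eca_bwd <- function(cache, dy) {
  d <- cache$dimx; k <- length(cache$w); half <- (k - 1L) %/% 2L
  G <- cache$G
  # dG[n,c] = sum_{h,w} dy * x
  dG <- matrix(rowSums(matrix(dy * cache$x, nrow = d[1] * d[2])), d[1], d[2])
  dS <- dG * G * (1 - G)
  # weight gradient and upstream into the pooled vector (correlation transpose)
  dw <- numeric(k)
  dV <- matrix(0, d[1], d[2])
  C <- d[2]
  for (j in seq_len(k)) {
    shift <- j - 1L - half
    src <- seq_len(C) + shift
    ok <- src >= 1L & src <= C
    dw[j] <- sum(dS[, ok, drop = FALSE] * cache$V[, src[ok], drop = FALSE])
    dV[, src[ok]] <- dV[, src[ok], drop = FALSE] +
      cache$w[j] * dS[, ok, drop = FALSE]
  }
  dx <- dy * cache$gB +
    array(rep(as.vector(dV / (d[3] * d[4])), times = d[3] * d[4]), dim = d)
  if (cache$residual) dx <- dx + dy
  list(dx = dx, dw = dw)
}

# ---- bilinear sampling and deformable convolution -----------------------

#' Bilinear interpolation on a 2D map
#'
#' Standard 4-neighbour bilinear interpolation at a fractional position
#' `(row, col)` (1-based coordinates); positions outside the map contribute 0,
#' so a fully out-of-bounds query returns 0.
#'
#' @param x Numeric matrix.
#' @param q Length-2 numeric vector `(row, col)`.
#' @return Interpolated value.
#' @examples
#' m <- matrix(1:4, 2, 2)
#' bilinear_sample(m, c(1.5, 1.5)) # mean of all four pixels
#' @export
bilinear_sample <- function(x, q) {
  stopifnot(is.matrix(x), length(q) == 2L)
  py <- q[1]; px <- q[2]
  y0 <- floor(py); x0 <- floor(px)
  ty <- py - y0; tx <- px - x0
  val <- function(r, c) {
    if (r >= 1 && r <= nrow(x) && c >= 1 && c <= ncol(x)) x[r, c] else 0
  }
  (1 - ty) * (1 - tx) * val(y0, x0) +
    ty * (1 - tx) * val(y0 + 1, x0) +
    (1 - ty) * tx * val(y0, x0 + 1) +
    ty * tx * val(y0 + 1, x0 + 1)
}

# 3x3 sampling grid, row-major: (-1,-1), (-1,0), ..., (1,1)
DEFORM_GRID <- cbind(di = rep(-1:1, each = 3), dj = rep(-1:1, times = 3))

# gather x[n, c, y, x] for all channels at integer positions (vy, vx);
# returns an (NHW x Cin) matrix, zero where out of bounds
gather_corner <- function(xf, N, Cin, H, Wd, n_idx, vy, vx) {
  ok <- vy >= 1 & vy <= H & vx >= 1 & vx <= Wd
  base <- n_idx + N * Cin * (pmax(vy, 1) - 1) + N * Cin * H * (pmax(vx, 1) - 1)
  idx <- outer(base, (seq_len(Cin) - 1L) * N, "+")
  v <- matrix(xf[idx], nrow = length(base))
  v[!ok, ] <- 0
  v
}

deform_fwd <- function(x, off, W, b = NULL, stride = 1L, need_cache = TRUE) {
  d <- dim(x); N <- d[1]; Cin <- d[2]; H <- d[3]; Wd <- d[4]
  dw <- dim(W); Cout <- dw[1]; kh <- dw[3]; kw <- dw[4]
  stopifnot(dw[2] == Cin, kh == 3L, kw == 3L)
  nk <- kh * kw
  if (dim(off)[2] != 2L * nk)
    stop(sprintf("offset map must have %d channels (2 per kernel point), got %d",
                 2L * nk, dim(off)[2]))
  Hout <- conv_out_size(H, 1L, kh, stride)
  Wout <- conv_out_size(Wd, 1L, kw, stride)
  if (dim(off)[3] != Hout || dim(off)[4] != Wout)
    stop("offset map spatial dims must match the output dims")
  # base sampling centres (equivalent to pad-1 standard conv, OOB treated as 0)
  ho <- seq.int(1L, by = stride, length.out = Hout)
  wo <- seq.int(1L, by = stride, length.out = Wout)
  BH <- array(rep(rep(ho, each = N), times = Wout), dim = c(N, Hout, Wout))
  BW <- array(rep(wo, each = N * Hout), dim = c(N, Hout, Wout))
  n_idx <- rep(seq_len(N), times = Hout * Wout)
  xf <- as.vector(x)
  Ymat <- matrix(0, Cout, N * Hout * Wout)
  cache_n <- if (need_cache) vector("list", nk) else NULL
  for (n in seq_len(nk)) {
    offy <- array(off[, 2L * n - 1L, , ], dim = c(N, Hout, Wout))
    offx <- array(off[, 2L * n, , ], dim = c(N, Hout, Wout))
    py <- as.vector(BH + DEFORM_GRID[n, 1] + offy)
    px <- as.vector(BW + DEFORM_GRID[n, 2] + offx)
    y0 <- floor(py); x0 <- floor(px)
    ty <- py - y0; tx <- px - x0
    v00 <- gather_corner(xf, N, Cin, H, Wd, n_idx, y0, x0)
    v10 <- gather_corner(xf, N, Cin, H, Wd, n_idx, y0 + 1, x0)
    v01 <- gather_corner(xf, N, Cin, H, Wd, n_idx, y0, x0 + 1)
    v11 <- gather_corner(xf, N, Cin, H, Wd, n_idx, y0 + 1, x0 + 1)
    smp <- (1 - ty) * (1 - tx) * v00 + ty * (1 - tx) * v10 +
      (1 - ty) * tx * v01 + ty * tx * v11
    Ymat <- Ymat + matrix(W[, , n %/% 3L + (n %% 3L != 0L),
                            (n - 1L) %% 3L + 1L], Cout, Cin) %*% t(smp)
    if (need_cache)
      cache_n[[n]] <- list(y0 = y0, x0 = x0, ty = ty, tx = tx,
                           v00 = v00, v10 = v10, v01 = v01, v11 = v11,
                           smp = smp)
  }
  if (!is.null(b)) Ymat <- Ymat + b
  y <- aperm(array(Ymat, dim = c(Cout, N, Hout, Wout)), c(2, 1, 3, 4))
  list(y = y,
       cache = list(per_n = cache_n, dimx = d, W = W, has_b = !is.null(b),
                    stride = stride, Hout = Hout, Wout = Wout,
                    n_idx = n_idx))
}

deform_bwd <- function(cache, dy) {
  d <- cache$dimx; N <- d[1]; Cin <- d[2]; H <- d[3]; Wd <- d[4]
  W <- cache$W; dw <- dim(W); Cout <- dw[1]
  Hout <- cache$Hout; Wout <- cache$Wout
  nk <- 9L
  dYmat <- matrix(aperm(dy, c(2, 1, 3, 4)), nrow = Cout)
  dW <- array(0, dim = dw)
  dxf <- numeric(length = prod(d))
  doff <- array(0, dim = c(N, 2L * nk, Hout, Wout))
  n_idx <- cache$n_idx
  for (n in seq_len(nk)) {
    cn <- cache$per_n[[n]]
    i <- n %/% 3L + (n %% 3L != 0L); j <- (n - 1L) %% 3L + 1L
    dW[, , i, j] <- dYmat %*% cn$smp
    dsmp <- t(t(matrix(W[, , i, j], Cout, Cin)) %*% dYmat)  # NHW x Cin
    ty <- cn$ty; tx <- cn$tx
    # input gradient: scatter-add into the four corners
    corners <- list(
      list(vy = cn$y0,     vx = cn$x0,     w = (1 - ty) * (1 - tx)),
      list(vy = cn$y0 + 1, vx = cn$x0,     w = ty * (1 - tx)),
      list(vy = cn$y0,     vx = cn$x0 + 1, w = (1 - ty) * tx),
      list(vy = cn$y0 + 1, vx = cn$x0 + 1, w = ty * tx))
    for (co in corners) {
      ok <- co$vy >= 1 & co$vy <= H & co$vx >= 1 & co$vx <= Wd
      if (!any(ok)) next
      base <- n_idx + N * Cin * (co$vy - 1) + N * Cin * H * (co$vx - 1)
      idx <- outer(base, (seq_len(Cin) - 1L) * N, "+")
      v <- dsmp * co$w
      sel <- rep(ok, Cin)
      acc <- rowsum(as.vector(v)[sel], group = as.vector(idx)[sel])
      ii <- as.integer(rownames(acc))
      dxf[ii] <- dxf[ii] + acc[, 1]
    }
    # offset gradients via the interpolation derivative
    dpy <- rowSums(dsmp * ((cn$v10 - cn$v00) * (1 - tx) + (cn$v11 - cn$v01) * tx))
    dpx <- rowSums(dsmp * ((cn$v01 - cn$v00) * (1 - ty) + (cn$v11 - cn$v10) * ty))
    doff[, 2L * n - 1L, , ] <- array(dpy, dim = c(N, Hout, Wout))
    doff[, 2L * n, , ] <- array(dpx, dim = c(N, Hout, Wout))
  }
  out <- list(dx = array(dxf, dim = d), doff = doff, dW = dW)
  if (cache$has_b) out$db <- rowSums(dYmat)
  out
}

#' Deformable 3x3 convolution
#'
#' Evaluates `y(p0) = sum_n w(p_n) x(p0 + p_n + dp_n)`: a 3x3 convolution
#' whose nine sampling points are displaced by learned per-position offsets,
#' with fractional positions resolved by bilinear interpolation and
#' out-of-bounds samples treated as zero. With all offsets zero this reduces
#' exactly to a standard zero-padded 3x3 convolution.
#'
#' @param x Input array `N x Cin x H x W`.
#' @param offsets Offset array `N x 18 x Hout x Wout`; channels `2n-1`/`2n`
#'   hold the row/column displacement of kernel point `n` (row-major grid
#'   order).
#' @param weights Kernel array `Cout x Cin x 3 x 3`.
#' @param bias Optional length-`Cout` bias.
#' @param stride Sampling stride (default 1).
#' @return Output array `N x Cout x Hout x Wout`.
#' @export
deformable_conv2d <- function(x, offsets, weights, bias = NULL, stride = 1L) {
  deform_fwd(x, offsets, weights, bias, stride, need_cache = FALSE)$y
}

# ---- GRU ----------------------------------------------------------------

gru_init <- function(input_dim, hidden, seed = NULL) {
  with_seed(seed, {
    lim <- 1 / sqrt(hidden)
    rnd <- function(nr, nc) matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
    list(Wz = rnd(input_dim, hidden), Uz = rnd(hidden, hidden), bz = numeric(hidden),
         Wr = rnd(input_dim, hidden), Ur = rnd(hidden, hidden), br = numeric(hidden),
         Wh = rnd(input_dim, hidden), Uh = rnd(hidden, hidden), bh = numeric(hidden))
  })
}

# X: T x N x D array; returns H: T x N x hidden
gru_fwd <- function(X, p) {
  Tt <- dim(X)[1]; N <- dim(X)[2]
  hd <- ncol(p$Wz)
  H <- array(0, dim = c(Tt, N, hd))
  h <- matrix(0, N, hd)
  steps <- vector("list", Tt)
  for (t in seq_len(Tt)) {
    xt <- matrix(X[t, , ], N)
    z <- sigmoid(xt %*% p$Wz + h %*% p$Uz +
                   matrix(p$bz, N, hd, byrow = TRUE))
    r <- sigmoid(xt %*% p$Wr + h %*% p$Ur +
                   matrix(p$br, N, hd, byrow = TRUE))
    cc <- tanh(xt %*% p$Wh + (r * h) %*% p$Uh +
                 matrix(p$bh, N, hd, byrow = TRUE))
    hn <- (1 - z) * h + z * cc
    steps[[t]] <- list(xt = xt, hprev = h, z = z, r = r, cc = cc)
    h <- hn
    H[t, , ] <- h
  }
  list(H = H, cache = list(steps = steps, p = p, dims = c(Tt, N, hd)))
}

gru_bwd <- function(cache, dH) {
  p <- cache$p
  dms <- cache$dims; Tt <- dms[1]; N <- dms[2]; hd <- dms[3]
  g <- lapply(p, function(w) array(0, dim = dim(w) %||% length(w)))
  dX <- array(0, dim = c(Tt, N, nrow(p$Wz)))
  dh <- matrix(0, N, hd)
  for (t in rev(seq_len(Tt))) {
    st <- cache$steps[[t]]
    dht <- dh + matrix(dH[t, , ], N)
    z <- st$z; r <- st$r; cc <- st$cc; hprev <- st$hprev; xt <- st$xt
    dz <- dht * (cc - hprev) * z * (1 - z)
    dcc <- dht * z * (1 - cc^2)
    dr <- (dcc %*% t(p$Uh)) * hprev * r * (1 - r)
    g$Wz <- g$Wz + t(xt) %*% dz; g$Uz <- g$Uz + t(hprev) %*% dz
    g$bz <- g$bz + colSums(dz)
    g$Wr <- g$Wr + t(xt) %*% dr; g$Ur <- g$Ur + t(hprev) %*% dr
    g$br <- g$br + colSums(dr)
    g$Wh <- g$Wh + t(xt) %*% dcc; g$Uh <- g$Uh + t(r * hprev) %*% dcc
    g$bh <- g$bh + colSums(dcc)
    dX[t, , ] <- dz %*% t(p$Wz) + dr %*% t(p$Wr) + dcc %*% t(p$Wh)
    dh <- dht * (1 - z) + (dcc %*% t(p$Uh)) * r +
      dz %*% t(p$Uz) + dr %*% t(p$Ur)
  }
  list(dX = dX, grads = g)
}

#' Create a bidirectional GRU layer
#'
#' Two GRUs traverse the sequence in opposite directions; their per-step
#' outputs are concatenated, so the output feature width is `2 * hidden`.
#'
#' @param input_dim Input feature width.
#' @param hidden Hidden-state width of each direction.
#' @param seed Optional seed for weight initialization.
#' @return A list with `forward` and `backward` GRU parameter sets.
#' @export
bigru_layer <- function(input_dim, hidden, seed = NULL) {
  list(fwd = gru_init(input_dim, hidden, seed),
       bwd = gru_init(input_dim, hidden,
                      if (is.null(seed)) NULL else derive_seed(seed, 1L)))
}

bigru_fwd <- function(X, layer) {
  Tt <- dim(X)[1]
  f <- gru_fwd(X, layer$fwd)
  Xr <- X[rev(seq_len(Tt)), , , drop = FALSE]
  b <- gru_fwd(Xr, layer$bwd)
  Hb <- b$H[rev(seq_len(Tt)), , , drop = FALSE]
  H <- array(0, dim = c(Tt, dim(X)[2], 2L * dim(f$H)[3]))
  hd <- dim(f$H)[3]
  H[, , seq_len(hd)] <- f$H
  H[, , hd + seq_len(hd)] <- Hb
  list(H = H, cache = list(f = f$cache, b = b$cache, hd = hd, Tt = Tt))
}

bigru_bwd <- function(cache, dH) {
  hd <- cache$hd; Tt <- cache$Tt
  dHf <- dH[, , seq_len(hd), drop = FALSE]
  dHb <- dH[rev(seq_len(Tt)), , hd + seq_len(hd), drop = FALSE]
  f <- gru_bwd(cache$f, dHf)
  b <- gru_bwd(cache$b, dHb)
  dX <- f$dX + b$dX[rev(seq_len(Tt)), , , drop = FALSE]
  list(dX = dX, grads = list(fwd = f$grads, bwd = b$grads))
}

#' Run a bidirectional GRU over a feature sequence
#'
#' @param seq A `T x N x D` array (or `T x D` matrix, treated as batch of 1).
#' @param layer A [bigru_layer()].
#' @return A `T x N x 2*hidden` array (matching the input's batch form).
#' @export
bigru_forward <- function(seq, layer) {
  two_d <- is.matrix(seq)
  if (two_d) seq <- array(seq, dim = c(nrow(seq), 1L, ncol(seq)))
  if (length(dim(seq)) != 3L) stop("'seq' must be a T x N x D array")
  if (dim(seq)[1] < 1L) stop("empty sequence")
  H <- bigru_fwd(seq, layer)$H
  if (two_d) matrix(H, dim(H)[1], dim(H)[3]) else H
}

# ---- linear / softmax ---------------------------------------------------

linear_fwd <- function(x, W, b) {
  y <- x %*% W + matrix(b, nrow(x), length(b), byrow = TRUE)
  list(y = y, cache = list(x = x, W = W))
}

linear_bwd <- function(cache, dy) {
  list(dx = dy %*% t(cache$W), dW = t(cache$x) %*% dy, db = colSums(dy))
}

#' Row-wise softmax
#' @param z Numeric matrix of logits.
#' @return Matrix of probabilities; each row sums to 1.
#' @export
softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# cross-entropy loss; labels are 0-based class ids
softmax_ce <- function(logits, labels) {
  p <- softmax(logits)
  n <- nrow(p)
  idx <- cbind(seq_len(n), labels + 1L)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, dlogits = dlogits / n, probs = p)
}
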