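# Differentiable layer primitives. Activations are dense arrays laid out
# (H, W, C, N); every *_f returns list(y, cache) and every *_b consumes the
# cache plus the upstream gradient. The elementwise and GEMM kernels live in
# src/nnops.cpp; these wrappers own the calculus (what to cache, how
# gradients compose).

bn_f <- function(x, gamma, beta, training, rmean, rvar,
                 momentum = 0.1, eps = 1e-5) {
  d <- dim(x); m <- d[1] * d[2] * d[4]
  if (training) {
    st <- nn_ch_stats(x, NULL)
    mu <- st$s1 / m
    va <- pmax(st$s2 / m - mu^2, 0)
    rmean <- (1 - momentum) * rmean + momentum * mu
    rvar <- (1 - momentum) * rvar + momentum * va
  } else {
    mu <- rmean; va <- rvar
  }
  inv <- 1 / sqrt(va + eps)
  y <- nn_bn_apply(x, mu, inv, gamma, beta)
  list(y = y, cache = list(x = x, mu = mu, inv = inv, gamma = gamma),
       rmean = rmean, rvar = rvar)
}

bn_b <- function(cache, gy) {
  bw <- nn_bn_bw(cache$x, cache$mu, cache$inv, cache$gamma, gy)
  list(gx = bw$gx, ggamma = bw$ggamma, gbeta = bw$gbeta)
}

lrelu_f <- function(x, alpha) {
  list(y = nn_lrelu(x, alpha), cache = list(x = x, alpha = alpha))
}
lrelu_b <- function(cache, gy) nn_lrelu_bw(cache$x, cache$alpha, gy)

conv_f <- function(x, w, b, pad) {
  list(y = nn_conv2d(x, w, b, as.integer(pad)),
       cache = list(x = x, w = w, pad = pad))
}
conv_b <- function(cache, gy) nn_conv2d_bw(cache$x, cache$w, gy,
                                           as.integer(cache$pad))

maxpool2_f <- function(x) {
  mp <- nn_maxpool2(x)
  list(y = mp$y, cache = list(idx = mp$idx, d = dim(x)))
}
maxpool2_b <- function(cache, gy) nn_maxpool2_bw(cache$idx, gy, cache$d)

upsample2_f <- function(x) list(y = nn_upsample2(x), cache = NULL)
upsample2_b <- function(gy) nn_upsample2_bw(gy)

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}
split_ch <- function(g, c1) {
  d <- dim(g)
  list(g[, , seq_len(c1), , drop = FALSE],
       g[, , (c1 + 1):d[3], , drop = FALSE])
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# broadcast a (H,W,1,N) map across C channels
bcast_ch <- function(a, C) a[, , rep(1L, C), , drop = FALSE]
# collapse a gradient over channels back to (H,W,1,N)
collapse_ch <- function(g) {
  d <- dim(g)
  s <- g[, , 1L, , drop = FALSE]
  if (d[3] > 1L) for (cc in 2:d[3]) s <- s + g[, , cc, , drop = FALSE]
  s
}
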