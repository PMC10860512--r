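# 2D attention U-Net for slice-wise GTV segmentation.
#
# Architecture: `depth` encoder blocks, one bottleneck, `depth` decoder
# blocks (2*depth + 1 blocks in total; the reference configuration with
# depth 4 has 9). Every block is prefixed by batch normalization and uses
# two 3x3 stride-1 pad-1 convolutions with leaky-ReLU activations; encoder
# blocks end in 2x2 max-pooling and channel counts double per level.
# Decoder levels upsample (nearest-neighbour 2x followed by a 3x3
# convolution), gate the matching encoder skip with an additive attention
# gate, concatenate, and apply a batchnorm-prefixed double convolution.
# The head is a single 1x1 convolution with sigmoid activation, so outputs
# are per-pixel foreground probabilities in (0,1) at input resolution.

#' Network configuration
#'
#' @param input_size Square slice size in pixels. The full-scale clinical
#'   configuration uses 512; the scaled study and tests use 64. Must be
#'   divisible by `2^depth`.
#' @param depth Number of encoder (and decoder) levels. Default 4 gives the
#'   reference 9-block network (4 down, 1 bottleneck, 4 up).
#' @param base_channels Filter count of the first encoder block; doubles at
#'   each deeper level.
#' @param leaky_alpha Negative-slope coefficient of the leaky ReLU
#'   activations (default 0.1).
#' @param use_attention Gate skip connections with additive attention gates
#'   (default `TRUE`); `FALSE` yields a plain U-Net.
#' @return An object of class `gtv_network_config`.
#' @export
network_config <- function(input_size = 64L, depth = 4L, base_channels = 8L,
                           leaky_alpha = 0.1, use_attention = TRUE) {
  input_size <- as.integer(input_size); depth <- as.integer(depth)
  base_channels <- as.integer(base_channels)
  if (base_channels < 1L) stop("base_channels must be >= 1")
  if (input_size %% (2L^depth) != 0L)
    stop("input_size must be divisible by 2^depth")
  structure(list(input_size = input_size, depth = depth,
                 base_channels = base_channels, leaky_alpha = leaky_alpha,
                 use_attention = isTRUE(use_attention)),
            class = "gtv_network_config")
}

he_uniform <- function(dims, fan_in) {
  lim <- sqrt(6 / fan_in)
  array(stats::runif(prod(dims), -lim, lim), dims)
}

conv_par <- function(k, cin, cout) {
  list(w = he_uniform(c(k, k, cin, cout), k * k * cin), b = numeric(cout))
}

#' Build a segmentation model
#'
#' Instantiates the attention U-Net with He-uniform initial weights drawn
#' from a fixed seed, so construction is reproducible.
#'
#' @param config A [network_config()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `gtv_model` with elements `config`, `params`
#'   (named list of weight arrays), `running` (batch-norm running
#'   statistics) and `n_blocks`.
#' @export
build_model <- function(config, seed = 42L) {
  stopifnot(inherits(config, "gtv_network_config"))
  set.seed(as.integer(seed))
  d <- config$depth; base <- config$base_channels
  p <- list(); r <- list()
  ch <- function(l) base * 2L^(l - 1L)
  for (l in seq_len(d)) {
    cin <- if (l == 1L) 1L else ch(l - 1L)
    nm <- paste0("enc", l)
    p[[paste0(nm, "_bn_g")]] <- rep(1, cin)
    p[[paste0(nm, "_bn_b")]] <- rep(0, cin)
    r[[paste0(nm, "_bn_m")]] <- rep(0, cin)
    r[[paste0(nm, "_bn_v")]] <- rep(1, cin)
    cv <- conv_par(3L, cin, ch(l))
    p[[paste0(nm, "_c1_w")]] <- cv$w; p[[paste0(nm, "_c1_b")]] <- cv$b
    cv <- conv_par(3L, ch(l), ch(l))
    p[[paste0(nm, "_c2_w")]] <- cv$w; p[[paste0(nm, "_c2_b")]] <- cv$b
  }
  cb <- ch(d + 1L)  # bottleneck width
  p$bot_bn_g <- rep(1, ch(d)); p$bot_bn_b <- rep(0, ch(d))
  r$bot_bn_m <- rep(0, ch(d)); r$bot_bn_v <- rep(1, ch(d))
  cv <- conv_par(3L, ch(d), cb); p$bot_c1_w <- cv$w; p$bot_c1_b <- cv$b
  cv <- conv_par(3L, cb, cb);   p$bot_c2_w <- cv$w; p$bot_c2_b <- cv$b
  for (l in rev(seq_len(d))) {
    cl <- ch(l); nm <- paste0("dec", l)
    cv <- conv_par(3L, 2L * cl, cl)
    p[[paste0(nm, "_up_w")]] <- cv$w; p[[paste0(nm, "_up_b")]] <- cv$b
    if (config$use_attention) {
      fg <- max(1L, cl %/% 2L)
      cv <- conv_par(1L, cl, fg)
      p[[paste0(nm, "_at_th_w")]] <- cv$w; p[[paste0(nm, "_at_th_b")]] <- cv$b
      cv <- conv_par(1L, 2L * cl, fg)
      p[[paste0(nm, "_at_ph_w")]] <- cv$w; p[[paste0(nm, "_at_ph_b")]] <- cv$b
      cv <- conv_par(1L, fg, 1L)
      p[[paste0(nm, "_at_ps_w")]] <- cv$w; p[[paste0(nm, "_at_ps_b")]] <- cv$b
    }
    p[[paste0(nm, "_bn_g")]] <- rep(1, 2L * cl)
    p[[paste0(nm, "_bn_b")]] <- rep(0, 2L * cl)
    r[[paste0(nm, "_bn_m")]] <- rep(0, 2L * cl)
    r[[paste0(nm, "_bn_v")]] <- rep(1, 2L * cl)
    cv <- conv_par(3L, 2L * cl, cl)
    p[[paste0(nm, "_c1_w")]] <- cv$w; p[[paste0(nm, "_c1_b")]] <- cv$b
    cv <- conv_par(3L, cl, cl)
    p[[paste0(nm, "_c2_w")]] <- cv$w; p[[paste0(nm, "_c2_b")]] <- cv$b
  }
  cv <- conv_par(1L, base, 1L); p$head_w <- cv$w; p$head_b <- cv$b
  structure(list(config = config, params = p, running = r,
                 n_blocks = 2L * d + 1L),
            class = "gtv_model")
}

#' Number of trainable parameters
#' @param model A `gtv_model`.
#' @return Integer scalar.
#' @export
parameter_count <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

#' @export
print.gtv_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<gtv_model> attention U-Net: input %dx%d, depth %d, base %d, %d blocks, %s parameters\n",
    cfg$input_size, cfg$input_size, cfg$depth, cfg$base_channels,
    x$n_blocks, format(parameter_count(x), big.mark = ",")))
  invisible(x)
}

# Attention gate forward: skip (H,W,C), gating = coarser decoder feature
# (H/2,W/2,2C). alpha = sigmoid(psi(relu(theta(skip) + phi(up(gating))))).
att_f <- function(skip, gating, p, nm, override = NULL) {
  gu <- upsample2_f(gating)$y
  t1 <- conv_f(skip, p[[paste0(nm, "_at_th_w")]], p[[paste0(nm, "_at_th_b")]], 0L)
  t2 <- conv_f(gu, p[[paste0(nm, "_at_ph_w")]], p[[paste0(nm, "_at_ph_b")]], 0L)
  s <- t1$y + t2$y
  q <- pmax(s, 0)
  ps <- conv_f(q, p[[paste0(nm, "_at_ps_w")]], p[[paste0(nm, "_at_ps_b")]], 0L)
  alpha <- sigmoid(ps$y)
  if (!is.null(override)) alpha[] <- override
  gated <- skip * bcast_ch(alpha, dim(skip)[3])
  list(y = gated, alpha = alpha,
       cache = list(skip = skip, gu = gu, t1 = t1$cache, t2 = t2$cache,
                    s = s, q = q, ps = ps$cache, alpha = alpha))
}

att_b <- function(cache, gy) {
  C <- dim(cache$skip)[3]
  alpha <- cache$alpha
  gskip <- gy * bcast_ch(alpha, C)
  galpha <- collapse_ch(gy * cache$skip)
  gz <- galpha * alpha * (1 - alpha)
  bw <- conv_b(cache$ps, gz)
  gq <- bw$gx; gps_w <- bw$gw; gps_b <- bw$gb
  gs <- gq * (cache$s > 0)
  bw1 <- conv_b(cache$t1, gs)
  bw2 <- conv_b(cache$t2, gs)
  ggating <- upsample2_b(bw2$gx)
  list(gskip = gskip + bw1$gx, ggating = ggating,
       grads = list(th_w = bw1$gw, th_b = bw1$gb,
                    ph_w = bw2$gw, ph_b = bw2$gb,
                    ps_w = gps_w, ps_b = gps_b))
}

# Full forward pass. x: (H, W, 1, N) normalized intensities.
# Returns probabilities plus (optionally) the cache needed for backward and
# the updated batch-norm running statistics.
net_forward <- function(model, x, training = FALSE, keep_cache = FALSE,
                        alpha_override = NULL) {
  cfg <- model$config; p <- model$params; r <- model$running
  if (dim(x)[1] != cfg$input_size || dim(x)[2] != cfg$input_size)
    stop("input spatial size ", dim(x)[1], "x", dim(x)[2],
         " does not match model input_size ", cfg$input_size)
  al <- cfg$leaky_alpha; d <- cfg$depth
  K <- list(); skips <- list()
  h <- x
  block_f <- function(h, nm) {
    bn <- bn_f(h, p[[paste0(nm, "_bn_g")]], p[[paste0(nm, "_bn_b")]],
               training, r[[paste0(nm, "_bn_m")]], r[[paste0(nm, "_bn_v")]])
    r[[paste0(nm, "_bn_m")]] <<- bn$rmean
    r[[paste0(nm, "_bn_v")]] <<- bn$rvar
    c1 <- conv_f(bn$y, p[[paste0(nm, "_c1_w")]], p[[paste0(nm, "_c1_b")]], 1L)
    a1 <- lrelu_f(c1$y, al)
    c2 <- conv_f(a1$y, p[[paste0(nm, "_c2_w")]], p[[paste0(nm, "_c2_b")]], 1L)
    a2 <- lrelu_f(c2$y, al)
    list(y = a2$y, cache = list(bn = bn$cache, c1 = c1$cache, a1 = a1$cache,
                                c2 = c2$cache, a2 = a2$cache))
  }
  for (l in seq_len(d)) {
    nm <- paste0("enc", l)
    bl <- block_f(h, nm)
    skips[[l]] <- bl$y
    pl <- maxpool2_f(bl$y)
    K[[nm]] <- list(block = bl$cache, pool = pl$cache)
    h <- pl$y
  }
  bl <- block_f(h, "bot")
  K$bot <- list(block = bl$cache)
  prev <- bl$y
  for (l in rev(seq_len(d))) {
    nm <- paste0("dec", l)
    up <- upsample2_f(prev)$y
    uc <- conv_f(up, p[[paste0(nm, "_up_w")]], p[[paste0(nm, "_up_b")]], 1L)
    ua <- lrelu_f(uc$y, al)
    if (cfg$use_attention) {
      at <- att_f(skips[[l]], prev, p, nm, override = alpha_override)
      gated <- at$y; atc <- at$cache
    } else {
      gated <- skips[[l]]; atc <- NULL
    }
    mg <- concat_ch(ua$y, gated)
    bl <- block_f(mg, nm)
    K[[nm]] <- list(uc = uc$cache, ua = ua$cache, at = atc, block = bl$cache,
                    c_up = dim(ua$y)[3])
    prev <- bl$y
  }
  hd <- conv_f(prev, p$head_w, p$head_b, 0L)
  prob <- sigmoid(hd$y)
  K$head <- hd$cache; K$prob <- prob
  list(prob = prob, cache = if (keep_cache) K else NULL, running = r)
}

# Backward pass; gprob = dLoss/dprob. Returns gradients named like params.
net_backward <- function(model, cache, gprob) {
  cfg <- model$config; d <- cfg$depth
  g <- list()
  prob <- cache$prob
  gz <- gprob * prob * (1 - prob)
  bw <- conv_b(cache$head, gz)
  g$head_w <- bw$gw; g$head_b <- bw$gb
  gprev <- bw$gx
  block_b <- function(kc, nm, gy) {
    ga2 <- lrelu_b(kc$a2, gy)
    bw2 <- conv_b(kc$c2, ga2)
    g[[paste0(nm, "_c2_w")]] <<- bw2$gw; g[[paste0(nm, "_c2_b")]] <<- bw2$gb
    ga1 <- lrelu_b(kc$a1, bw2$gx)
    bw1 <- conv_b(kc$c1, ga1)
    g[[paste0(nm, "_c1_w")]] <<- bw1$gw; g[[paste0(nm, "_c1_b")]] <<- bw1$gb
    bnb <- bn_b(kc$bn, bw1$gx)
    g[[paste0(nm, "_bn_g")]] <<- bnb$ggamma
    g[[paste0(nm, "_bn_b")]] <<- bnb$gbeta
    bnb$gx
  }
  gskips <- vector("list", d)
  for (l in seq_len(d)) {   # decoder levels, shallowest first (reverse of fwd)
    nm <- paste0("dec", l)
    kc <- cache[[nm]]
    gm <- block_b(kc$block, nm, gprev)
    sp <- split_ch(gm, kc$c_up)
    gua <- sp[[1]]; ggated <- sp[[2]]
    guc <- lrelu_b(kc$ua, gua)
    bwu <- conv_b(kc$uc, guc)
    g[[paste0(nm, "_up_w")]] <- bwu$gw; g[[paste0(nm, "_up_b")]] <- bwu$gb
    gprev_next <- upsample2_b(bwu$gx)
    if (cfg$use_attention) {
      ab <- att_b(kc$at, ggated)
      gskips[[l]] <- ab$gskip
      gprev_next <- gprev_next + ab$ggating
      g[[paste0(nm, "_at_th_w")]] <- ab$grads$th_w
      g[[paste0(nm, "_at_th_b")]] <- ab$grads$th_b
      g[[paste0(nm, "_at_ph_w")]] <- ab$grads$ph_w
      g[[paste0(nm, "_at_ph_b")]] <- ab$grads$ph_b
      g[[paste0(nm, "_at_ps_w")]] <- ab$grads$ps_w
      g[[paste0(nm, "_at_ps_b")]] <- ab$grads$ps_b
    } else {
      gskips[[l]] <- ggated
    }
    gprev <- gprev_next
  }
  gh <- block_b(cache$bot$block, "bot", gprev)
  for (l in rev(seq_len(d))) {
    nm <- paste0("enc", l)
    kc <- cache[[nm]]
    gpool <- maxpool2_b(kc$pool, gh)
    gskip_total <- gpool + gskips[[l]]
    gh <- block_b(kc$block, nm, gskip_total)
  }
  g
}

#' Save a model checkpoint
#'
#' Stores weights, configuration, batch-norm running statistics and training
#' provenance in a versioned file.
#'
#' @param model A `gtv_model`.
#' @param path Destination file.
#' @param provenance Optional named list (epochs seen, cohort label, seeds).
#' @export
save_checkpoint <- function(model, path, provenance = list()) {
  obj <- list(format_version = 1L, config = unclass(model$config),
              params = model$params, running = model$running,
              n_blocks = model$n_blocks,
              provenance = c(model$provenance, provenance))
  saveRDS(obj, path)
  invisible(path)
}

#' Load a model checkpoint
#' @param path File written by [save_checkpoint()].
#' @return A `gtv_model`.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$format_version) || obj$format_version != 1L)
    stop("unsupported checkpoint format")
  structure(list(config = structure(obj$config, class = "gtv_network_config"),
                 params = obj$params, running = obj$running,
                 n_blocks = obj$n_blocks, provenance = obj$provenance),
            class = "gtv_model")
}

#' Slice-batch forward pass (inference)
#'
#' @param model A `gtv_model`.
#' @param x Array of slices `(H, W, N)` or `(H, W, 1, N)` with values in
#'   `[0, 1]`.
#' @param alpha_override Optional constant overriding every attention
#'   coefficient (testing hook; `1` reduces the network to a plain U-Net
#'   skip, `0` zeroes all skips).
#' @return Array `(H, W, N)` of foreground probabilities in (0, 1).
#' @export
predict_slices <- function(model, x, alpha_override = NULL) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x)[1:2], 1L, dim(x)[3])
  out <- net_forward(model, x, training = FALSE,
                     alpha_override = alpha_override)$prob
  array(out, dim(out)[c(1, 2, 4)])
}
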