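#' Network configuration
#'
#' Hyperparameters of the classifier: a four-stage residual backbone on the
#' 9x9xd feature tensor (3x3 stride-1 stem, stage strides 1/2/2/2 so a 9x9
#' map survives the network), every residual block gated by efficient channel
#' attention, deformable convolution substituted in one chosen stage, a
#' bottom-up feature pyramid fused into a single map P5, and a bidirectional
#' GRU head over the P5 positions.
#'
#' @param input_shape `(h, w, d)` of the feature tensors (default `c(9,9,4)`).
#' @param widths Channel widths of the four stages. The reference
#'   architecture uses `c(64, 128, 256, 512)`; tests use smaller widths.
#' @param blocks_per_stage Residual blocks per stage (2 in the reference
#'   18-layer layout).
#' @param dcn_block_index Which stage (1-4) uses deformable convolution in
#'   place of both standard 3x3 convolutions of each of its blocks; default 4.
#' @param lateral_channels Common width of the pyramid's 1x1 projections
#'   (default 128).
#' @param gru_hidden Hidden width per GRU direction.
#' @param gru_sequence_mode `"spatial"` (P5 positions unrolled row-major as
#'   the sequence) or `"temporal"` (P5 pooled per segment; consecutive
#'   segments grouped into sequences of length `gru_time_steps`).
#' @param gru_time_steps Sequence length for temporal mode.
#' @param n_classes Number of emotion classes (>= 2).
#' @param eca_residual Keep the extra identity addition inside the attention
#'   gate (default `TRUE`).
#' @param eca_gamma,eca_b Constants of the adaptive kernel-size rule.
#' @param seed Seed for weight initialization.
#' @return An object of class `model_config`.
#' @export
model_config <- function(input_shape = c(9L, 9L, 4L),
                         widths = c(64L, 128L, 256L, 512L),
                         blocks_per_stage = 2L,
                         dcn_block_index = 4L,
                         lateral_channels = 128L,
                         gru_hidden = 64L,
                         gru_sequence_mode = c("spatial", "temporal"),
                         gru_time_steps = 4L,
                         n_classes = 2L,
                         eca_residual = TRUE,
                         eca_gamma = 2,
                         eca_b = 1,
                         seed = 1L) {
  gru_sequence_mode <- match.arg(gru_sequence_mode)
  stopifnot(length(input_shape) == 3L, length(widths) == 4L)
  dcn_block_index <- check_count(dcn_block_index, "dcn_block_index")
  if (dcn_block_index > 4L) stop("'dcn_block_index' must be in 1..4")
  n_classes <- check_count(n_classes, "n_classes", 2L)
  structure(list(
    input_shape = as.integer(input_shape),
    widths = as.integer(widths),
    blocks_per_stage = check_count(blocks_per_stage, "blocks_per_stage"),
    dcn_block_index = dcn_block_index,
    lateral_channels = check_count(lateral_channels, "lateral_channels"),
    gru_hidden = check_count(gru_hidden, "gru_hidden"),
    gru_sequence_mode = gru_sequence_mode,
    gru_time_steps = check_count(gru_time_steps, "gru_time_steps"),
    n_classes = n_classes,
    eca_residual = isTRUE(eca_residual),
    eca_gamma = eca_gamma, eca_b = eca_b,
    seed = check_count(seed, "seed", 0L)
  ), class = "model_config")
}

STAGE_STRIDES <- c(1L, 2L, 2L, 2L)

he_conv <- function(cout, cin, kh, kw) {
  array(stats::rnorm(cout * cin * kh * kw, sd = sqrt(2 / (cin * kh * kw))),
        dim = c(cout, cin, kh, kw))
}

#' Build a classifier model from a configuration
#'
#' Initializes all weights (He initialization for convolutions; offset
#' branches of deformable convolutions start at zero so the network begins
#' exactly at its standard-convolution counterpart) and the batch-norm
#' running statistics.
#'
#' @param cfg A [model_config()].
#' @return An object of class `eegemo_model`: list with `cfg`, `params`
#'   (named list of arrays) and `state` (running statistics).
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  p <- list(); s <- list()
  with_seed(cfg$seed, {
    d_in <- cfg$input_shape[3]
    w <- cfg$widths
    p$stem.W <- he_conv(w[1], d_in, 3, 3)
    p$stem.bn.g <- rep(1, w[1]); p$stem.bn.b <- numeric(w[1])
    s$stem.bn.m <- numeric(w[1]); s$stem.bn.v <- rep(1, w[1])
    cin <- w[1]
    for (st in 1:4) {
      cout <- w[st]
      for (bl in seq_len(cfg$blocks_per_stage)) {
        pre <- sprintf("s%d.b%d", st, bl)
        bcin <- if (bl == 1L) cin else cout
        stride <- if (bl == 1L) STAGE_STRIDES[st] else 1L
        deform <- (st == cfg$dcn_block_index)
        for (cv in 1:2) {
          ci <- if (cv == 1L) bcin else cout
          p[[paste0(pre, sprintf(".conv%d.W", cv))]] <- he_conv(cout, ci, 3, 3)
          if (deform) {
            p[[paste0(pre, sprintf(".off%d.W", cv))]] <- array(0, c(18, ci, 3, 3))
            p[[paste0(pre, sprintf(".off%d.b", cv))]] <- numeric(18)
          }
          p[[paste0(pre, sprintf(".bn%d.g", cv))]] <- rep(1, cout)
          p[[paste0(pre, sprintf(".bn%d.b", cv))]] <- numeric(cout)
          s[[paste0(pre, sprintf(".bn%d.m", cv))]] <- numeric(cout)
          s[[paste0(pre, sprintf(".bn%d.v", cv))]] <- rep(1, cout)
        }
        k <- eca_kernel_size(cout, cfg$eca_gamma, cfg$eca_b)
        p[[paste0(pre, ".eca.w")]] <- stats::rnorm(k, sd = 0.1)
        if (bcin != cout || stride != 1L) {
          p[[paste0(pre, ".down.W")]] <- he_conv(cout, bcin, 1, 1)
          p[[paste0(pre, ".down.bn.g")]] <- rep(1, cout)
          p[[paste0(pre, ".down.bn.b")]] <- numeric(cout)
          s[[paste0(pre, ".down.bn.m")]] <- numeric(cout)
          s[[paste0(pre, ".down.bn.v")]] <- rep(1, cout)
        }
      }
      cin <- cout
    }
    L <- cfg$lateral_channels
    for (st in 1:4) {
      p[[sprintf("fpn.lat%d.W", st)]] <- he_conv(L, w[st], 1, 1)
      p[[sprintf("fpn.lat%d.b", st)]] <- numeric(L)
    }
    for (st in 2:4) {
      p[[sprintf("fpn.down%d.W", st)]] <- he_conv(L, L, 3, 3)
      p[[sprintf("fpn.down%d.b", st)]] <- numeric(L)
    }
    p$fpn.out.W <- he_conv(L, L, 3, 3)
    p$fpn.out.b <- numeric(L)
    gru <- bigru_layer(L, cfg$gru_hidden, seed = derive_seed(cfg$seed, 77L))
    for (dir in c("fwd", "bwd"))
      for (nm in names(gru[[dir]]))
        p[[sprintf("gru.%s.%s", dir, nm)]] <- gru[[dir]][[nm]]
    fcin <- 2L * cfg$gru_hidden
    p$fc.W <- matrix(stats::rnorm(fcin * cfg$n_classes, sd = sqrt(2 / fcin)),
                     fcin, cfg$n_classes)
    p$fc.b <- numeric(cfg$n_classes)
  })
  structure(list(cfg = cfg, params = p, state = s), class = "eegemo_model")
}

#' @export
print.eegemo_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 1L))
  cat(sprintf("<eegemo_model> widths %s, dcn stage %d, %d classes, %s parameters\n",
              paste(x$cfg$widths, collapse = "/"), x$cfg$dcn_block_index,
              x$cfg$n_classes, format(np, big.mark = ",")))
  invisible(x)
}

# forward through one residual block; returns y, caches, updated state
block_fwd <- function(x, p, st, sname, cfg, train, grad) {
  pre <- sname
  g <- function(n) p[[paste0(pre, n)]]
  deform <- !is.null(p[[paste0(pre, ".off1.W")]])
  stride <- st$stride
  cc <- list()
  h <- x
  for (cv in 1:2) {
    sv <- if (cv == 1L) stride else 1L
    if (deform) {
      oc <- conv_fwd(h, g(sprintf(".off%d.W", cv)), g(sprintf(".off%d.b", cv)),
                     stride = sv, pad = 1L)
      dc <- deform_fwd(h, oc$y, g(sprintf(".conv%d.W", cv)), NULL,
                       stride = sv, need_cache = grad)
      cc[[sprintf("off%d", cv)]] <- if (grad) oc$cache else NULL
      cc[[sprintf("conv%d", cv)]] <- if (grad) dc$cache else NULL
      h <- dc$y
    } else {
      fc <- conv_fwd(h, g(sprintf(".conv%d.W", cv)), NULL, stride = sv, pad = 1L)
      cc[[sprintf("conv%d", cv)]] <- if (grad) fc$cache else NULL
      h <- fc$y
    }
    bn <- bn_fwd(h, g(sprintf(".bn%d.g", cv)), g(sprintf(".bn%d.b", cv)),
                 st$state[[paste0(pre, sprintf(".bn%d.m", cv))]],
                 st$state[[paste0(pre, sprintf(".bn%d.v", cv))]],
                 train)
    st$state[[paste0(pre, sprintf(".bn%d.m", cv))]] <- bn$run_mean
    st$state[[paste0(pre, sprintf(".bn%d.v", cv))]] <- bn$run_var
    cc[[sprintf("bn%d", cv)]] <- bn$cache
    h <- bn$y
    if (cv == 1L) {
      rl <- relu_fwd(h)
      cc$relu1 <- rl$cache
      h <- rl$y
    }
  }
  ec <- eca_fwd(h, g(".eca.w"), residual = cfg$eca_residual)
  cc$eca <- ec$cache
  h <- ec$y
  if (!is.null(p[[paste0(pre, ".down.W")]])) {
    dn <- conv_fwd(x, g(".down.W"), NULL, stride = stride, pad = 0L)
    bn <- bn_fwd(dn$y, g(".down.bn.g"), g(".down.bn.b"),
                 st$state[[paste0(pre, ".down.bn.m")]],
                 st$state[[paste0(pre, ".down.bn.v")]], train)
    st$state[[paste0(pre, ".down.bn.m")]] <- bn$run_mean
    st$state[[paste0(pre, ".down.bn.v")]] <- bn$run_var
    cc$down <- if (grad) dn$cache else NULL
    cc$down.bn <- bn$cache
    skip <- bn$y
  } else skip <- x
  h <- h + skip
  rl <- relu_fwd(h)
  cc$relu2 <- rl$cache
  list(y = rl$y, cache = cc, state = st$state)
}

block_bwd <- function(dy, cache, p, sname, cfg, grads) {
  pre <- sname
  g <- function(n) p[[paste0(pre, n)]]
  deform <- !is.null(p[[paste0(pre, ".off1.W")]])
  dy <- relu_bwd(cache$relu2, dy)
  dskip <- dy
  if (!is.null(cache$down.bn)) {
    bb <- bn_bwd(cache$down.bn, dskip)
    grads[[paste0(pre, ".down.bn.g")]] <- bb$dgamma
    grads[[paste0(pre, ".down.bn.b")]] <- bb$dbeta
    cb <- conv_bwd(cache$down, bb$dx)
    grads[[paste0(pre, ".down.W")]] <- cb$dW
    dx_skip <- cb$dx
  } else dx_skip <- dskip
  eb <- eca_bwd(cache$eca, dy)
  grads[[paste0(pre, ".eca.w")]] <- eb$dw
  dh <- eb$dx
  for (cv in 2:1) {
    if (cv == 1L) dh <- relu_bwd(cache$relu1, dh)
    bb <- bn_bwd(cache[[sprintf("bn%d", cv)]], dh)
    grads[[paste0(pre, sprintf(".bn%d.g", cv))]] <- bb$dgamma
    grads[[paste0(pre, sprintf(".bn%d.b", cv))]] <- bb$dbeta
    dh <- bb$dx
    if (deform) {
      db <- deform_bwd(cache[[sprintf("conv%d", cv)]], dh)
      grads[[paste0(pre, sprintf(".conv%d.W", cv))]] <- db$dW
      ob <- conv_bwd(cache[[sprintf("off%d", cv)]], db$doff)
      grads[[paste0(pre, sprintf(".off%d.W", cv))]] <- ob$dW
      grads[[paste0(pre, sprintf(".off%d.b", cv))]] <- ob$db
      dh <- db$dx + ob$dx
    } else {
      cb <- conv_bwd(cache[[sprintf("conv%d", cv)]], dh)
      grads[[paste0(pre, sprintf(".conv%d.W", cv))]] <- cb$dW
      dh <- cb$dx
    }
  }
  list(dx = dh + dx_skip, grads = grads)
}

#' Backbone forward pass: multi-scale feature maps C2..C5
#'
#' Runs the stem and the four residual stages, returning the per-stage
#' feature maps that feed the pyramid.
#'
#' @param model An [build_model()] result.
#' @param x Input batch, `N x h x w x d` (tensor layout) or `N x d x h x w`
#'   (channel-first); disambiguated against `cfg$input_shape`.
#' @param train Use batch statistics and update running statistics.
#' @return List with `C2`, `C3`, `C4`, `C5` feature maps (channel-first), the
#'   cache (when `grad = TRUE`) and updated state.
#' @param grad Keep caches for a backward pass.
#' @export
backbone_forward <- function(model, x, train = FALSE, grad = FALSE) {
  cfg <- model$cfg; p <- model$params
  x <- to_nchw(x, cfg$input_shape)
  st <- list(state = model$state)
  caches <- list()
  fc <- conv_fwd(x, p$stem.W, NULL, stride = 1L, pad = 1L)
  caches$stem.conv <- if (grad) fc$cache else NULL
  bn <- bn_fwd(fc$y, p$stem.bn.g, p$stem.bn.b, st$state$stem.bn.m,
               st$state$stem.bn.v, train)
  st$state$stem.bn.m <- bn$run_mean; st$state$stem.bn.v <- bn$run_var
  caches$stem.bn <- bn$cache
  rl <- relu_fwd(bn$y)
  caches$stem.relu <- rl$cache
  h <- rl$y
  Cs <- list()
  for (stg in 1:4) {
    for (bl in seq_len(cfg$blocks_per_stage)) {
      sname <- sprintf("s%d.b%d", stg, bl)
      stride <- if (bl == 1L) STAGE_STRIDES[stg] else 1L
      bf <- block_fwd(h, p, list(stride = stride, state = st$state),
                      sname, cfg, train, grad)
      st$state <- bf$state
      caches[[sname]] <- bf$cache
      h <- bf$y
    }
    Cs[[sprintf("C%d", stg + 1L)]] <- h
  }
  c(Cs, list(cache = caches, state = st$state))
}

#' @rdname backbone_forward
#' @param cfg A [model_config()] used to build a fresh model (convenience
#'   wrapper used in examples/tests).
#' @export
dcna_resnet18_forward <- function(x, cfg = model_config(), train = FALSE) {
  m <- build_model(cfg)
  out <- backbone_forward(m, x, train = train, grad = FALSE)
  out[c("C2", "C3", "C4", "C5")]
}

# accepts N x h x w x d (tensor layout) and converts to N x d x h x w
to_nchw <- function(x, input_shape) {
  d <- dim(x)
  if (length(d) != 4L) stop("input batch must be a 4-d array")
  if (d[2] == input_shape[3] && d[3] == input_shape[1] && d[4] == input_shape[2])
    return(x)
  if (d[2] == input_shape[1] && d[3] == input_shape[2] && d[4] == input_shape[3])
    return(aperm(x, c(1, 4, 2, 3)))
  stop(sprintf("input dims (%s) do not match the configured input shape (%s)",
               paste(d[-1], collapse = "x"),
               paste(input_shape, collapse = "x")))
}

#' Bottom-up feature-pyramid fusion
#'
#' Projects C2..C5 to a common width with 1x1 convolutions (T2..T5), then
#' repeatedly downsamples with stride-2 3x3 convolutions and adds the next
#' level (D3 = down(T2) + T3, D4 = down(D3) + T4, D5 = down(D4) + T5), and
#' applies a final 3x3 convolution to produce the fused map P5. Every
#' downsample obeys the shape law of [conv_out_size()].
#'
#' @param features List with elements `C2`..`C5` (channel-first arrays).
#' @param model A built model providing the pyramid weights.
#' @param grad Keep caches for the backward pass.
#' @return List with `P5` and (if `grad`) `cache`.
#' @export
bufpn_fuse <- function(features, model, grad = FALSE) {
  p <- model$params
  cc <- list()
  Ts <- vector("list", 4)
  for (stg in 1:4) {
    lf <- conv_fwd(features[[sprintf("C%d", stg + 1L)]],
                   p[[sprintf("fpn.lat%d.W", stg)]],
                   p[[sprintf("fpn.lat%d.b", stg)]], stride = 1L, pad = 0L)
    cc[[sprintf("lat%d", stg)]] <- if (grad) lf$cache else NULL
    Ts[[stg]] <- lf$y
  }
  Dcur <- Ts[[1]]
  for (stg in 2:4) {
    dn <- conv_fwd(Dcur, p[[sprintf("fpn.down%d.W", stg)]],
                   p[[sprintf("fpn.down%d.b", stg)]], stride = 2L, pad = 1L)
    cc[[sprintf("down%d", stg)]] <- if (grad) dn$cache else NULL
    if (!all(dim(dn$y) == dim(Ts[[stg]])))
      stop(sprintf("shape mismatch fusing level T%d: downsampled %s vs lateral %s",
                   stg + 1L, paste(dim(dn$y), collapse = "x"),
                   paste(dim(Ts[[stg]]), collapse = "x")))
    Dcur <- dn$y + Ts[[stg]]
  }
  of <- conv_fwd(Dcur, p$fpn.out.W, p$fpn.out.b, stride = 1L, pad = 1L)
  cc$out <- if (grad) of$cache else NULL
  list(P5 = of$y, cache = cc)
}

bufpn_bwd <- function(dP5, cache, grads) {
  ob <- conv_bwd(cache$out, dP5)
  grads$fpn.out.W <- ob$dW; grads$fpn.out.b <- ob$db
  dD <- ob$dx
  dTs <- vector("list", 4)
  for (stg in 4:2) {
    dTs[[stg]] <- dD
    db <- conv_bwd(cache[[sprintf("down%d", stg)]], dD)
    grads[[sprintf("fpn.down%d.W", stg)]] <- db$dW
    grads[[sprintf("fpn.down%d.b", stg)]] <- db$db
    dD <- db$dx
  }
  dTs[[1]] <- dD
  dCs <- vector("list", 4)
  for (stg in 1:4) {
    lb <- conv_bwd(cache[[sprintf("lat%d", stg)]], dTs[[stg]])
    grads[[sprintf("fpn.lat%d.W", stg)]] <- lb$dW
    grads[[sprintf("fpn.lat%d.b", stg)]] <- lb$db
    dCs[[stg]] <- lb$dx
  }
  list(dCs = dCs, grads = grads)
}

gru_params_from_flat <- function(p) {
  out <- list(fwd = list(), bwd = list())
  for (dir in c("fwd", "bwd"))
    for (nm in c("Wz", "Uz", "bz", "Wr", "Ur", "br", "Wh", "Uh", "bh"))
      out[[dir]][[nm]] <- p[[sprintf("gru.%s.%s", dir, nm)]]
  out
}

#' Full model forward pass
#'
#' Backbone, pyramid fusion, sequence head (BiGRU over the fused map), fully
#' connected layer and softmax. In `"spatial"` mode the P5 positions are
#' unrolled row-major as the BiGRU sequence; in `"temporal"` mode P5 is
#' globally average-pooled per segment and `gru_time_steps` consecutive
#' segments form the sequence (the batch size must then be a multiple of the
#' sequence length).
#'
#' @param model A built model ([build_model()]).
#' @param x Input batch (`N x 9 x 9 x 4` tensor layout, or channel-first).
#' @param train Use batch statistics (training mode).
#' @param grad Keep caches for the backward pass.
#' @return List with `probs` (`N x n_classes`, rows summing to 1), `logits`,
#'   plus `cache` and updated `state`.
#' @export
model_forward <- function(model, x, train = FALSE, grad = FALSE) {
  cfg <- model$cfg
  bb <- backbone_forward(model, x, train = train, grad = grad)
  fp <- bufpn_fuse(bb[c("C2", "C3", "C4", "C5")], model, grad = grad)
  P5 <- fp$P5
  dp <- dim(P5); N <- dp[1]; L <- dp[2]
  if (cfg$gru_sequence_mode == "spatial") {
    # unroll positions row-major: (1,1),(1,2),...,(h,w)
    Tt <- dp[3] * dp[4]
    Xs <- array(aperm(P5, c(4, 3, 1, 2)), dim = c(Tt, N, L)) # w fastest within row
    # aperm gives (w,h,n,c): flatten w,h -> T with w fastest = row-major ✓
  } else {
    Tt <- cfg$gru_time_steps
    if (N %% Tt != 0L)
      stop(sprintf("temporal mode needs batch size divisible by gru_time_steps (%d)", Tt))
    pooled <- apply(P5, c(1, 2), mean)      # N x L
    M <- N %/% Tt
    Xs <- array(0, dim = c(Tt, M, L))
    for (t in seq_len(Tt)) Xs[t, , ] <- pooled[seq.int(t, N, by = Tt), ]
  }
  gp <- gru_params_from_flat(model$params)
  bg <- bigru_fwd(Xs, list(fwd = gp$fwd, bwd = gp$bwd))
  Hmean <- matrix(0, dim(bg$H)[2], dim(bg$H)[3])
  for (t in seq_len(dim(bg$H)[1])) Hmean <- Hmean + matrix(bg$H[t, , ], dim(bg$H)[2])
  Hmean <- Hmean / dim(bg$H)[1]
  lf <- linear_fwd(Hmean, model$params$fc.W, model$params$fc.b)
  probs <- softmax(lf$y)
  list(probs = probs, logits = lf$y,
       cache = if (grad) list(bb = bb$cache, fp = fp$cache, bg = bg$cache,
                              lf = lf$cache, dimP5 = dp, Tt = dim(bg$H)[1]) else NULL,
       state = bb$state)
}

model_backward <- function(model, cache, dlogits) {
  cfg <- model$cfg
  grads <- list()
  lb <- linear_bwd(cache$lf, dlogits)
  grads$fc.W <- lb$dW; grads$fc.b <- lb$db
  Tt <- cache$Tt
  NN <- nrow(lb$dx)
  dH <- array(0, dim = c(Tt, NN, ncol(lb$dx)))
  for (t in seq_len(Tt)) dH[t, , ] <- lb$dx / Tt
  gb <- bigru_bwd(cache$bg, dH)
  for (dir in c("fwd", "bwd"))
    for (nm in names(gb$grads[[dir]]))
      grads[[sprintf("gru.%s.%s", dir, nm)]] <- gb$grads[[dir]][[nm]]
  dp <- cache$dimP5; N <- dp[1]; L <- dp[2]
  if (cfg$gru_sequence_mode == "spatial") {
    dP5 <- aperm(array(gb$dX, dim = c(dp[4], dp[3], N, L)), c(3, 4, 2, 1))
  } else {
    dpool <- matrix(0, N, L)
    M <- N %/% Tt
    for (t in seq_len(Tt)) dpool[seq.int(t, N, by = Tt), ] <- matrix(gb$dX[t, , ], M)
    dP5 <- array(rep(as.vector(dpool / (dp[3] * dp[4])), times = dp[3] * dp[4]),
                 dim = dp)
  }
  fb <- bufpn_bwd(dP5, cache$fp, grads)
  grads <- fb$grads
  # backbone backward
  p <- model$params
  dh <- NULL
  for (stg in 4:1) {
    dstage <- fb$dCs[[stg]]
    dh <- if (is.null(dh)) dstage else dh + dstage
    for (bl in rev(seq_len(cfg$blocks_per_stage))) {
      sname <- sprintf("s%d.b%d", stg, bl)
      bw <- block_bwd(dh, cache$bb[[sname]], p, sname, cfg, grads)
      grads <- bw$grads
      dh <- bw$dx
    }
  }
  dh <- relu_bwd(cache$bb$stem.relu, dh)
  bb <- bn_bwd(cache$bb$stem.bn, dh)
  grads$stem.bn.g <- bb$dgamma; grads$stem.bn.b <- bb$dbeta
  cb <- conv_bwd(cache$bb$stem.conv, bb$dx)
  grads$stem.W <- cb$dW
  grads
}

#' Standalone ECA block application
#'
#' Applies efficient channel attention with freshly initialized (or supplied)
#' 1D-convolution weights: global average pooling per channel, a size-k 1D
#' convolution across the channel axis, a sigmoid gate rescaling every
#' channel, and optionally an identity addition.
#'
#' @param x Input array `N x C x H x W`.
#' @param weights Optional length-k weight vector; defaults to small random
#'   weights with k from [eca_kernel_size()].
#' @param gamma,b Kernel-size rule constants.
#' @param residual Add the input back after gating (default `TRUE`).
#' @return Array of the same shape as `x`.
#' @export
eca_block <- function(x, weights = NULL, gamma = 2, b = 1, residual = TRUE) {
  stopifnot(length(dim(x)) == 4L)
  C <- dim(x)[2]
  if (is.null(weights)) {
    k <- eca_kernel_size(C, gamma, b)
    weights <- stats::rnorm(k, sd = 0.1)
  }
  eca_fwd(x, weights, residual = residual)$y
}
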