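# Deformable Attention Transformer (DAT) components.
#
# Stages 1-2 use (shifted-)window local self-attention; stages 3-4
# alternate window attention with deformable attention, where a light
# offset subnetwork shifts a uniform reference grid so keys/values are
# bilinearly sampled at content-dependent positions. Blocks are standard
# pre-norm transformer blocks (LN -> attention -> residual,
# LN -> MLP -> residual).

# ---- geometry helpers -----------------------------------------------------

# largest window size <= wmax dividing both extents (avoids padding)
effective_window <- function(H, W, wmax) {
  for (w in seq.int(min(wmax, H, W), 1L)) {
    if (H %% w == 0L && W %% w == 0L) return(w)
  }
  1L
}

# (2, s^2) normalized reference grid, y fastest, align-corners
reference_points_2xg <- function(s) {
  u <- if (s == 1L) 0 else seq(-1, 1, length.out = s)
  rbind(rep(u, times = s), rep(u, each = s))
}

#' Uniform reference grid for deformable sampling
#'
#' @param s sampling points per side.
#' @return an s^2 x 2 matrix of (y, x) coordinates uniformly covering
#'   [-1, 1]^2 (align-corners spacing).
#' @export
referencePoints <- function(s) {
  t(reference_points_2xg(as.integer(s)))
}

# (2, H*W) normalized positions of feature-map cells, y fastest
query_positions_2xm <- function(H, W) {
  ys <- if (H == 1L) 0 else seq(-1, 1, length.out = H)
  xs <- if (W == 1L) 0 else seq(-1, 1, length.out = W)
  rbind(rep(ys, times = W), rep(xs, each = W))
}

# ---- patch embedding ------------------------------------------------------

#' Initialize patch-embedding weights
#' @param embed_dim output channels.
#' @param seed integer seed.
#' @export
patchEmbedWeights <- function(embed_dim, seed = 1L) {
  withr::with_seed(as.integer(seed), list(
    w = matrix(he_init(48, embed_dim * 48), embed_dim, 48),
    b = rep(0, embed_dim)
  ))
}

as_3hw <- function(image) {
  d <- dim(image)
  if (length(d) == 3L && d[3] == 3L && d[1] != 3L) {
    image <- aperm(image, c(3, 1, 2)) # H x W x 3 -> 3 x H x W
  }
  image
}

#' Patch embedding: 4x4 non-overlapping convolution with stride 4
#'
#' @param image 3 x H x W (or H x W x 3) raster, H and W divisible by 4
#'   (zero-padded up otherwise).
#' @param weights a [patchEmbedWeights()] list.
#' @return a [FeatureMap-class] at stride 4 with spatial extent (H/4, W/4).
#' @export
patchEmbed <- function(image, weights) {
  x <- as_3hw(image)
  d <- dim(x)
  H <- d[2]; W <- d[3]
  padH <- (4L - H %% 4L) %% 4L
  padW <- (4L - W %% 4L) %% 4L
  if (padH > 0L || padW > 0L) {
    xp <- array(0, c(3L, H + padH, W + padW))
    xp[, seq_len(H), seq_len(W)] <- x
    x <- xp
  }
  dim(x) <- c(dim(x), 1L)
  out <- agNoGrad(agConv2d(agConst(x), weights$w, weights$b,
                           k = 4L, stride = 4L, pad = 0L))$v
  featureMap(array(out, dim(out)[1:3]), stride = 4L)
}

# ---- window attention -----------------------------------------------------

window_partition_ag <- function(t, w, H, W, C, N) {
  t <- agReshape(t, c(C, w, H %/% w, w, W %/% w, N))
  t <- agPermute(t, c(1, 2, 4, 3, 5, 6))
  agReshape(t, c(C, w * w, (H %/% w) * (W %/% w) * N))
}

window_merge_ag <- function(t, w, H, W, C, N) {
  t <- agReshape(t, c(C, w, w, H %/% w, W %/% w, N))
  t <- agPermute(t, c(1, 2, 4, 3, 5, 6))
  agReshape(t, c(C, H, W, N))
}

# Swin-style attention mask for shifted windows: (T, T, nWin*N) additive
shift_mask <- function(H, W, w, shift, N) {
  zone_of <- function(L) {
    z <- integer(L)
    if (L - w >= 1L) z[seq_len(L - w)] <- 0L
    a <- max(L - w + 1L, 1L)
    b <- max(L - shift, 0L)
    if (b >= a) z[a:b] <- 1L
    if (L - shift + 1L <= L) z[(L - shift + 1L):L] <- 2L
    z
  }
  zy <- zone_of(H)
  zx <- zone_of(W)
  zmap <- outer(zy, zx, function(a, b) a * 3L + b)
  dim(zmap) <- c(1L, H, W, 1L)
  zp <- agNoGrad(window_partition_ag(agConst(zmap), w, H, W, 1L, 1L))$v
  T <- w * w
  nWin <- (H %/% w) * (W %/% w)
  m <- array(0, c(T, T, nWin))
  for (k in seq_len(nWin)) {
    z <- zp[1, , k]
    m[, , k] <- ifelse(outer(z, z, `!=`), -1e9, 0)
  }
  array(rep(m, N), c(T, T, nWin * N))
}

# discrete relative-position bias: gather table ((heads,(2*tw-1)^2) param,
# tw = configured window) into a (T, T, heads) tensor for the effective
# window w <= tw
window_bias <- function(table, w, heads, table_w = w) {
  T <- w * w
  ty <- rep(seq_len(w), times = w)
  tx <- rep(seq_len(w), each = w)
  idx <- integer(T * T)
  p <- 0L
  for (tq in seq_len(T)) {
    for (tk in seq_len(T)) {
      p <- p + 1L
      dy <- ty[tk] - ty[tq] + table_w
      dx <- tx[tk] - tx[tq] + table_w
      idx[p] <- dy + (2L * table_w - 1L) * (dx - 1L)
    }
  }
  g <- agGatherCols(table, idx) # (heads, T*T), tk fastest
  g <- agReshape(g, c(heads, T, T))
  agPermute(g, c(2, 3, 1))
}

win_mhsa <- function(x, W, window, shift, heads, bias_table = NULL,
                     full_window_size = NULL) {
  d <- dim(x$v)
  C <- d[1]; H <- d[2]; Wd <- d[3]; N <- d[4]
  w <- effective_window(H, Wd, window)
  s <- if (shift > 0L && w > 1L) w %/% 2L else 0L
  if (s > 0L) x <- agRoll(x, -s, -s)
  q <- agLinear(x, W$wq, W$bq)
  k <- agLinear(x, W$wk, W$bk)
  v <- agLinear(x, W$wv, W$bv)
  qp <- window_partition_ag(q, w, H, Wd, C, N)
  kp <- window_partition_ag(k, w, H, Wd, C, N)
  vp <- window_partition_ag(v, w, H, Wd, C, N)
  mask <- if (s > 0L) shift_mask(H, Wd, w, s, N) else NULL
  bias <- if (!is.null(bias_table)) {
    tw <- if (is.null(full_window_size)) window else full_window_size
    window_bias(bias_table, w, heads, table_w = tw)
  } else NULL
  o <- agAttention(qp, kp, vp, heads, bias = bias, mask = mask)
  o <- window_merge_ag(o, w, H, Wd, C, N)
  if (s > 0L) o <- agRoll(o, s, s)
  agLinear(o, W$wo, W$bo)
}

qkv_weights <- function(C, seed, prefix = "") {
  withr::with_seed(as.integer(seed), list(
    wq = matrix(stats::rnorm(C * C, 0, sqrt(1 / C)), C, C), bq = rep(0, C),
    wk = matrix(stats::rnorm(C * C, 0, sqrt(1 / C)), C, C), bk = rep(0, C),
    wv = matrix(stats::rnorm(C * C, 0, sqrt(1 / C)), C, C), bv = rep(0, C),
    wo = matrix(stats::rnorm(C * C, 0, sqrt(1 / C)), C, C), bo = rep(0, C)
  ))
}

#' Initialize window-attention weights (functional form)
#' @param C channels; `heads` must divide C.
#' @param heads attention heads.
#' @param seed integer seed.
#' @export
windowAttentionWeights <- function(C, heads = 1L, seed = 1L) qkv_weights(C, seed)

#' Window (optionally shifted) local self-attention
#'
#' Multi-head self-attention inside non-overlapping window x window tiles.
#' A nonzero `shift` cyclically shifts the map by half a window before
#' tiling and masks attention across the wrap-around boundary. When the
#' window covers the whole map this reduces exactly to global
#' self-attention on the flattened map.
#'
#' @param f a [FeatureMap-class] or C x H x W array.
#' @param window window side (reduced to the largest divisor of the map
#'   extents when it does not tile them exactly).
#' @param shift 0 for plain windows, any positive value for the
#'   half-window shifted variant.
#' @param heads attention heads.
#' @param weights a [windowAttentionWeights()] list.
#' @return same type/shape as the input.
#' @export
windowAttention <- function(f, window, shift = 0L, heads = 1L,
                            weights = windowAttentionWeights(fm_channels(f), heads)) {
  x4 <- as_chw4(f)
  out <- agNoGrad(win_mhsa(agConst(x4), weights, window, shift, heads))$v
  wrap_like(f, out)
}

fm_channels <- function(f) {
  if (is(f, "FeatureMap")) dim(f@values)[1] else dim(f)[1]
}

wrap_like <- function(f, out) {
  if (is(f, "FeatureMap")) {
    featureMap(array(out, dim(out)[1:3]), f@stride)
  } else if (length(dim(f)) == 3L) {
    array(out, dim(out)[1:3])
  } else out
}

# ---- deformable attention -------------------------------------------------

#' DAT configuration
#'
#' @param embed_dim stage-1 channel count (doubles per stage).
#' @param stage_depths blocks per stage (length 4).
#' @param heads_per_stage attention heads per stage (length 4).
#' @param window_size local-attention window side.
#' @param offset_groups offset groups (must divide heads).
#' @param offset_range_factor bound on offsets, in units of reference-grid
#'   cells.
#' @param n_points sampling points per side; defaults to half the feature
#'   extent at use time when NULL.
#' @param mlp_ratio MLP expansion ratio of the transformer blocks.
#' @return config list.
#' @export
datConfig <- function(embed_dim = 32L, stage_depths = c(2L, 2L, 2L, 2L),
                      heads_per_stage = c(1L, 2L, 4L, 8L), window_size = 4L,
                      offset_groups = 1L, offset_range_factor = 2,
                      n_points = NULL, mlp_ratio = 4L) {
  stopifnot(length(stage_depths) == 4L, length(heads_per_stage) == 4L,
            offset_range_factor > 0)
  dims <- embed_dim * 2L^(0:3)
  stopifnot(all(dims %% heads_per_stage == 0L),
            all(heads_per_stage %% offset_groups == 0L))
  list(embed_dim = as.integer(embed_dim),
       stage_depths = as.integer(stage_depths),
       heads_per_stage = as.integer(heads_per_stage),
       window_size = as.integer(window_size),
       offset_groups = as.integer(offset_groups),
       offset_range_factor = offset_range_factor,
       n_points = n_points, mlp_ratio = as.integer(mlp_ratio))
}

#' Initialize deformable-attention weights (functional form)
#'
#' @param C channels.
#' @param heads attention heads.
#' @param seed integer seed.
#' @param zero_offsets zero the offset subnetwork (sampling stays on the
#'   uniform reference grid).
#' @param bias include a continuous relative-position bias table.
#' @param table_size bias table side.
#' @export
deformableAttentionWeights <- function(C, heads = 1L, seed = 1L,
                                       zero_offsets = FALSE, bias = TRUE,
                                       table_size = 15L) {
  W <- qkv_weights(C, seed)
  withr::with_seed(as.integer(seed) + 1L, {
    W$off_dw_w <- if (zero_offsets) matrix(0, 9, C) else
      matrix(he_init(9, 9 * C), 9, C)
    W$off_dw_b <- rep(0, C)
    W$off_pw_w <- if (zero_offsets) matrix(0, 2, C) else
      matrix(stats::rnorm(2 * C, 0, 0.01), 2, C)
    W$off_pw_b <- rep(0, 2)
    W$bias_table <- if (bias) {
      array(stats::rnorm(heads * table_size^2, 0, 0.02),
            c(heads, table_size, table_size))
    } else NULL
  })
  W
}

# continuous relative-position bias: sample the per-head table at the
# displacement (key point - query position)/2 in [-1,1]; positions are
# treated as constants for the bias term (gradient reaches the table only)
deform_bias <- function(table, pts_v, qpos, heads, P, M, N) {
  rel <- array(0, c(2, P * M * N, 1L))
  for (n in seq_len(N)) {
    o <- (n - 1L) * P * M
    rel[1, o + seq_len(P * M), 1] <- (rep(pts_v[1, , n], times = M) -
                                        rep(qpos[1, ], each = P)) / 2
    rel[2, o + seq_len(P * M), 1] <- (rep(pts_v[2, , n], times = M) -
                                        rep(qpos[2, ], each = P)) / 2
  }
  td <- if (inherits(table, "ag_tensor")) dim(table$v) else dim(table)
  tb <- agReshape(table, c(td, 1L))
  bv <- agBilinearSample(tb, agConst(rel)) # (heads, P*M*N, 1)
  bv <- agReshape(bv, c(heads, P, M, N))
  agPermute(bv, c(2, 3, 1, 4)) # (P, M, heads, N)
}

deform_mhsa <- function(x, W, heads, s_grid = NULL, orf = 2) {
  d <- dim(x$v)
  C <- d[1]; H <- d[2]; Wd <- d[3]; N <- d[4]
  if (is.null(s_grid)) {
    s_grid <- if (min(H, Wd) >= 2L) max(2L, min(H, Wd) %/% 2L) else 1L
  }
  P <- s_grid^2
  M <- H * Wd
  q <- agLinear(x, W$wq, W$bq)
  ref <- reference_points_2xg(s_grid)
  refN <- array(rep(ref, N), c(2L, P, N))
  # offsets from grid-sampled queries
  qg <- agBilinearSample(q, agConst(refN))
  qg4 <- agReshape(qg, c(C, s_grid, s_grid, N))
  hh <- agSilu(agDwConv2d(qg4, W$off_dw_w, W$off_dw_b, k = 3L))
  off <- agConv2d(hh, W$off_pw_w, W$off_pw_b, k = 1L)
  off <- agScale(agTanh(off), orf * 2 / max(s_grid, 2L))
  pts <- agAdd(agReshape(off, c(2L, P, N)), agConst(refN))
  sampled <- agBilinearSample(x, pts)
  k <- agLinear(sampled, W$wk, W$bk)
  v <- agLinear(sampled, W$wv, W$bv)
  qT <- agReshape(q, c(C, M, N))
  bias <- if (!is.null(W$bias_table)) {
    deform_bias(W$bias_table, pts$v, query_positions_2xm(H, Wd), heads, P, M, N)
  } else NULL
  o <- agAttention(qT, k, v, heads, bias = bias)
  o <- agReshape(o, c(C, H, Wd, N))
  out <- agLinear(o, W$wo, W$bo)
  out$aux <- c(out$aux, list(points = pts$v, offsets = off$v))
  out
}

#' Bilinear sampling of a feature map at normalized points
#'
#' The value at a point is the bilinear blend of its four integer-grid
#' neighbours; points outside the grid clamp to the border.
#'
#' @param f a [FeatureMap-class] or C x H x W array.
#' @param points P x 2 matrix of (y, x) coordinates in [-1, 1].
#' @return C x P matrix of sampled vectors.
#' @export
bilinearSample <- function(f, points) {
  x4 <- as_chw4(f)
  pts <- array(t(points), c(2L, nrow(points), 1L))
  out <- agNoGrad(agBilinearSample(agConst(x4), agConst(pts)))$v
  matrix(out, dim(x4)[1], nrow(points))
}

#' Deformable multi-head attention over a feature map
#'
#' Queries are a projection of the input; a light offset subnetwork
#' (depthwise 3x3, SiLU, pointwise 1x1) displaces a uniform reference grid
#' (tanh-squashed, bounded by `offset_range_factor` grid cells); keys and
#' values are projected from features bilinearly sampled at the displaced
#' points; scaled-dot-product attention with a continuous relative-position
#' bias completes the block. With a zeroed offset subnetwork this is dense
#' attention over grid-sampled keys/values.
#'
#' @param f a [FeatureMap-class] or C x H x W array.
#' @param cfg a [datConfig()] (uses heads of stage 3, offset_range_factor,
#'   n_points).
#' @param weights a [deformableAttentionWeights()] list.
#' @param heads attention heads (overrides cfg when given).
#' @return same type/shape as input; attributes "points" and "offsets"
#'   carry the sampling geometry.
#' @export
deformableAttention <- function(f, cfg = datConfig(), weights = NULL,
                                heads = cfg$heads_per_stage[3]) {
  x4 <- as_chw4(f)
  C <- dim(x4)[1]
  if (is.null(weights)) weights <- deformableAttentionWeights(C, heads)
  o <- agNoGrad(deform_mhsa(agConst(x4), weights, heads,
                            s_grid = cfg$n_points, orf = cfg$offset_range_factor))
  out <- wrap_like(f, o$v)
  attr(out, "points") <- o$aux$points
  attr(out, "offsets") <- o$aux$offsets
  out
}

# ---- transformer blocks (ctx-registered) ----------------------------------

nn_qkv <- function(ctx, name, C) {
  list(
    wq = ctx_param(ctx, paste0(name, ".wq"), matrix(stats::rnorm(C * C, 0, sqrt(1 / C)), C, C)),
    bq = ctx_param(ctx, paste0(name, ".bq"), rep(0, C)),
    wk = ctx_param(ctx, paste0(name, ".wk"), matrix(stats::rnorm(C * C, 0, sqrt(1 / C)), C, C)),
    bk = ctx_param(ctx, paste0(name, ".bk"), rep(0, C)),
    wv = ctx_param(ctx, paste0(name, ".wv"), matrix(stats::rnorm(C * C, 0, sqrt(1 / C)), C, C)),
    bv = ctx_param(ctx, paste0(name, ".bv"), rep(0, C)),
    wo = ctx_param(ctx, paste0(name, ".wo"), matrix(stats::rnorm(C * C, 0, sqrt(1 / C)), C, C)),
    bo = ctx_param(ctx, paste0(name, ".bo"), rep(0, C))
  )
}

nnMlp <- function(ctx, name, C, ratio = 4L) {
  hid <- C * ratio
  l1 <- nnLinear(ctx, paste0(name, ".fc1"), C, hid)
  l2 <- nnLinear(ctx, paste0(name, ".fc2"), hid, C)
  function(x, train = FALSE) l2(agSilu(l1(x)))
}

#' @keywords internal
nnWindowBlock <- function(ctx, name, C, window, shift, heads, mlp_ratio = 4L) {
  ln1 <- nnLayerNorm(ctx, paste0(name, ".ln1"), C)
  W <- nn_qkv(ctx, paste0(name, ".attn"), C)
  bias_table <- ctx_param(ctx, paste0(name, ".attn.bias"),
                          matrix(stats::rnorm(heads * (2L * window - 1L)^2, 0, 0.02),
                                 heads, (2L * window - 1L)^2))
  ln2 <- nnLayerNorm(ctx, paste0(name, ".ln2"), C)
  mlp <- nnMlp(ctx, paste0(name, ".mlp"), C, mlp_ratio)
  function(x, train = FALSE) {
    a <- win_mhsa(ln1(x), W, window, shift, heads, bias_table = bias_table)
    x <- agAdd(x, a)
    agAdd(x, mlp(ln2(x), train))
  }
}

#' @keywords internal
nnDeformBlock <- function(ctx, name, C, heads, orf = 2, mlp_ratio = 4L,
                          table_size = 15L) {
  ln1 <- nnLayerNorm(ctx, paste0(name, ".ln1"), C)
  W <- nn_qkv(ctx, paste0(name, ".attn"), C)
  W$off_dw_w <- ctx_param(ctx, paste0(name, ".attn.off_dw_w"),
                          matrix(he_init(9, 9 * C), 9, C))
  W$off_dw_b <- ctx_param(ctx, paste0(name, ".attn.off_dw_b"), rep(0, C))
  W$off_pw_w <- ctx_param(ctx, paste0(name, ".attn.off_pw_w"),
                          matrix(stats::rnorm(2 * C, 0, 1e-3), 2, C))
  W$off_pw_b <- ctx_param(ctx, paste0(name, ".attn.off_pw_b"), rep(0, 2))
  W$bias_table <- ctx_param(ctx, paste0(name, ".attn.bias"),
                            array(stats::rnorm(heads * table_size^2, 0, 0.02),
                                  c(heads, table_size, table_size)))
  ln2 <- nnLayerNorm(ctx, paste0(name, ".ln2"), C)
  mlp <- nnMlp(ctx, paste0(name, ".mlp"), C, mlp_ratio)
  function(x, train = FALSE) {
    a <- deform_mhsa(ln1(x), W, heads, orf = orf)
    x <- agAdd(x, a)
    agAdd(x, mlp(ln2(x), train))
  }
}

# ---- full 4-stage extractor -----------------------------------------------

#' Build a standalone 4-stage DAT feature extractor
#'
#' @param cfg a [datConfig()].
#' @param seed integer seed for weight initialization.
#' @return model environment with `$params` and
#'   `$forward(image3hw, train)` returning the 4-stage pyramid.
#' @export
datBuild <- function(cfg = datConfig(), seed = 1L) {
  withr::with_seed(as.integer(seed), {
    ctx <- new_ctx()
    dims <- cfg$embed_dim * 2L^(0:3)
    embed_w <- ctx_param(ctx, "backbone.embed.w",
                         matrix(he_init(48, dims[1] * 48), dims[1], 48))
    embed_b <- ctx_param(ctx, "backbone.embed.b", rep(0, dims[1]))
    stages <- list()
    downs <- list()
    for (s in 1:4) {
      blocks <- list()
      for (i in seq_len(cfg$stage_depths[s])) {
        nm <- sprintf("backbone.stage%d.block%d", s, i)
        if (s <= 2L) {
          blocks[[i]] <- nnWindowBlock(ctx, nm, dims[s], cfg$window_size,
                                       shift = (i %% 2L == 0L),
                                       heads = cfg$heads_per_stage[s],
                                       mlp_ratio = cfg$mlp_ratio)
        } else if (i %% 2L == 1L) {
          blocks[[i]] <- nnWindowBlock(ctx, nm, dims[s], cfg$window_size,
                                       shift = 0L,
                                       heads = cfg$heads_per_stage[s],
                                       mlp_ratio = cfg$mlp_ratio)
        } else {
          blocks[[i]] <- nnDeformBlock(ctx, nm, dims[s],
                                       heads = cfg$heads_per_stage[s],
                                       orf = cfg$offset_range_factor,
                                       mlp_ratio = cfg$mlp_ratio)
        }
      }
      stages[[s]] <- blocks
      if (s < 4L) {
        downs[[s]] <- nnConv(ctx, sprintf("backbone.down%d", s),
                             dims[s], dims[s + 1L], k = 2L, stride = 2L)
      }
    }
    model <- new.env(parent = emptyenv())
    model$params <- ctx$params
    model$states <- ctx$states
    model$cfg <- cfg
    model$forward <- function(image, train = FALSE) {
      x <- as_3hw(image)
      if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
      x <- agConv2d(agConst(x), embed_w, embed_b, k = 4L, stride = 4L, pad = 0L)
      out <- vector("list", 4L)
      for (s in 1:4) {
        for (blk in stages[[s]]) x <- blk(x, train)
        out[[s]] <- x
        if (s < 4L) {
          dn <- downs[[s]]
          x <- dn(x, train)
        }
      }
      out
    }
    model
  })
}

#' Run the 4-stage DAT extractor on an image
#'
#' Spatial extent is input/4 at stage 1 and halves per stage (640 input
#' gives per-side extents 160, 80, 40, 20).
#'
#' @param image 3 x H x W (or H x W x 3) raster, extents divisible by 32.
#' @param cfg a [datConfig()]; ignored when `model` is given.
#' @param model an existing [datBuild()] model (rebuilt from cfg+seed when
#'   NULL).
#' @param seed seed for a fresh build.
#' @return list of 4 [FeatureMap-class] objects (strides 4, 8, 16, 32).
#' @export
datForward <- function(image, cfg = datConfig(), model = NULL, seed = 1L) {
  if (is.null(model)) model <- datBuild(cfg, seed)
  outs <- agNoGrad(model$forward(image, train = FALSE))
  strides <- c(4L, 8L, 16L, 32L)
  lapply(seq_along(outs), function(i) {
    v <- outs[[i]]$v
    featureMap(array(v, dim(v)[1:3]), strides[i])
  })
}
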