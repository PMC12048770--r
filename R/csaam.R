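# Channel-Spatial Adaptive Attention Mechanism (CSAAM).
#
# Channel gating: global max- and average-pooled channel descriptors pass
# through one shared bottleneck MLP; the two outputs are summed and squashed
# by a sigmoid into a (C,1,1) map. Spatial gating: channel-wise max and mean
# form a 2-channel descriptor reduced by three stacked 3x3 convolutions
# (ReLU between them) to a (1,H,W) sigmoid map -- the 3x3 triple replaces a
# single 7x7 kernel at the same receptive field. The module output chains
# channel gating, then spatial gating, then an identity residual:
#   Xc = Yc(X) * X;  Xcs = Ys(Xc) * Xc;  Y = Xcs + X.

csaam_hidden <- function(C, reduction) max(ceiling(C / reduction), 1L)

#' Initialize CSAAM weights (functional form)
#'
#' @param C channel count of the feature map the module will gate.
#' @param reduction bottleneck reduction ratio of the shared channel MLP.
#' @param spatial_hidden hidden channels of the 3x3 conv stack.
#' @param seed integer seed; ignored when `zero = TRUE`.
#' @param zero all-zero weights (both attention maps become uniform 0.5).
#' @return named list of weight arrays.
#' @export
csaamWeights <- function(C, reduction = 16L, spatial_hidden = 4L, seed = 1L,
                         zero = FALSE) {
  h <- csaam_hidden(C, reduction)
  sh <- spatial_hidden
  mk <- function(nr, nc, fan) {
    if (zero) matrix(0, nr, nc) else matrix(he_init(fan, nr * nc), nr, nc)
  }
  withr::with_seed(as.integer(seed), list(
    ch_w1 = mk(h, C, C), ch_b1 = rep(0, h),
    ch_w2 = mk(C, h, h), ch_b2 = rep(0, C),
    sp_w1 = mk(sh, 2L * 9L, 18), sp_b1 = rep(0, sh),
    sp_w2 = mk(sh, sh * 9L, sh * 9), sp_b2 = rep(0, sh),
    sp_w3 = mk(1L, sh * 9L, sh * 9), sp_b3 = rep(0, 1),
    reduction = reduction
  ))
}

as_chw4 <- function(x) {
  if (is(x, "FeatureMap")) x <- x@values
  d <- dim(x)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  x
}

csaam_channel_map <- function(x, W) {
  d <- dim(x$v)
  C <- d[1]; N <- d[4]
  mx <- agGlobalMaxPool(x)
  av <- agGlobalAvgPool(x)
  mlp <- function(v) {
    m <- agReshape(v, c(C, N))
    hdn <- agRelu(agLinear(m, W$ch_w1, W$ch_b1))
    agReshape(agLinear(hdn, W$ch_w2, W$ch_b2), c(C, 1L, 1L, N))
  }
  agSigmoid(agAdd(mlp(mx), mlp(av)))
}

csaam_spatial_map <- function(x, W) {
  dsc <- agConcatC(list(agChanMax(x), agChanMean(x)))
  hdn <- agRelu(agConv2d(dsc, W$sp_w1, W$sp_b1, k = 3L))
  hdn <- agRelu(agConv2d(hdn, W$sp_w2, W$sp_b2, k = 3L))
  agSigmoid(agConv2d(hdn, W$sp_w3, W$sp_b3, k = 3L))
}

csaam_apply <- function(x, W) {
  yc <- csaam_channel_map(x, W)
  xc <- agMul(x, yc)
  ys <- csaam_spatial_map(xc, W)
  xcs <- agMul(xc, ys)
  agAdd(xcs, x)
}

#' Channel attention map
#'
#' @param x a [FeatureMap-class] or C x H x W array.
#' @param weights a [csaamWeights()] list.
#' @return C x 1 x 1 array with entries strictly in (0, 1).
#' @export
channelAttention <- function(x, weights) {
  x4 <- as_chw4(x)
  out <- agNoGrad(csaam_channel_map(agConst(x4), weights))$v
  array(out, dim(out)[1:3])
}

#' Spatial attention map
#'
#' @param x a [FeatureMap-class] or C x H x W array.
#' @param weights a [csaamWeights()] list.
#' @return 1 x H x W array with entries strictly in (0, 1).
#' @export
spatialAttention <- function(x, weights) {
  x4 <- as_chw4(x)
  out <- agNoGrad(csaam_spatial_map(agConst(x4), weights))$v
  array(out, dim(out)[1:3])
}

#' Full CSAAM forward pass
#'
#' Chains channel gating, spatial gating and the identity residual; output
#' shape equals input shape. With all-zero weights both gates are uniform
#' 0.5 and the output is exactly 1.25 times the input.
#'
#' @param x a [FeatureMap-class] or C x H x W array.
#' @param weights a [csaamWeights()] list.
#' @return same type and shape as `x`.
#' @export
csaamForward <- function(x, weights) {
  x4 <- as_chw4(x)
  out <- agNoGrad(csaam_apply(agConst(x4), weights))$v
  if (is(x, "FeatureMap")) {
    featureMap(array(out, dim(out)[1:3]), x@stride)
  } else if (length(dim(x)) == 3L) {
    array(out, dim(out)[1:3])
  } else {
    out
  }
}

#' CSAAM block registered in a model ctx
#' @keywords internal
nnCsaam <- function(ctx, name, C, reduction = 16L, spatial_hidden = 4L) {
  h <- csaam_hidden(C, reduction)
  sh <- spatial_hidden
  W <- list(
    ch_w1 = ctx_param(ctx, paste0(name, ".ch.w1"), matrix(he_init(C, h * C), h, C)),
    ch_b1 = ctx_param(ctx, paste0(name, ".ch.b1"), rep(0, h)),
    ch_w2 = ctx_param(ctx, paste0(name, ".ch.w2"), matrix(he_init(h, C * h), C, h)),
    ch_b2 = ctx_param(ctx, paste0(name, ".ch.b2"), rep(0, C)),
    sp_w1 = ctx_param(ctx, paste0(name, ".sp.w1"), matrix(he_init(18, sh * 18), sh, 18)),
    sp_b1 = ctx_param(ctx, paste0(name, ".sp.b1"), rep(0, sh)),
    sp_w2 = ctx_param(ctx, paste0(name, ".sp.w2"), matrix(he_init(sh * 9, sh * sh * 9), sh, sh * 9)),
    sp_b2 = ctx_param(ctx, paste0(name, ".sp.b2"), rep(0, sh)),
    sp_w3 = ctx_param(ctx, paste0(name, ".sp.w3"), matrix(he_init(sh * 9, sh * 9), 1, sh * 9)),
    sp_b3 = ctx_param(ctx, paste0(name, ".sp.b3"), rep(0, 1))
  )
  function(x, train = FALSE) csaam_apply(x, W)
}
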