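# Window attention, deformable attention and the 4-stage extractor, checked
# against dense-attention and loop-based oracles on small maps.

dense_attention_oracle <- function(tok, wts, heads, bias = NULL) {
  C <- nrow(tok)
  q <- wts$wq %*% tok + wts$bq
  k <- wts$wk %*% tok + wts$bk
  v <- wts$wv %*% tok + wts$bv
  dh <- C / heads
  out <- matrix(0, C, ncol(tok))
  for (h in seq_len(heads)) {
    r <- (h - 1) * dh + seq_len(dh)
    S <- t(k[r, , drop = FALSE]) %*% q[r, , drop = FALSE] / sqrt(dh)
    if (!is.null(bias)) S <- S + bias[, , h]
    A <- apply(S, 2, function(s) { e <- exp(s - max(s)); e / sum(e) })
    out[r, ] <- v[r, , drop = FALSE] %*% A
  }
  wts$wo %*% out + wts$bo
}

test_that("patch embedding is a stride-4 non-overlapping map", {
  pe <- patchEmbedWeights(6, seed = 2)
  withr::with_seed(1, img <- array(runif(3 * 64 * 64), c(3, 64, 64)))
  fm <- patchEmbed(img, pe)
  expect_s4_class(fm, "FeatureMap")
  expect_equal(dim(fm@values), c(6L, 16L, 16L))
  expect_equal(fm@stride, 4L)
  # constant input with zero bias -> identical embeddings everywhere
  pe0 <- pe
  pe0$b <- rep(0, 6)
  cfm <- patchEmbed(array(0.7, c(3, 32, 32)), pe0)
  expect_equal(max(apply(cfm@values, 1, function(p) diff(range(p)))), 0)
  # locality: one perturbed pixel changes exactly one output column
  img2 <- img
  img2[2, 17, 33] <- img2[2, 17, 33] + 5
  fm2 <- patchEmbed(img2, pe)
  changed <- which(apply(abs(fm2@values - fm@values) > 1e-12, c(2, 3), any),
                   arr.ind = TRUE)
  expect_equal(nrow(changed), 1L)
  expect_equal(unname(changed[1, ]), c(5L, 9L)) # patch (17..20, 33..36)
})

test_that("a whole-map window equals global self-attention on flattened tokens", {
  C <- 8; H <- 8; W <- 8
  withr::with_seed(4, f <- array(rnorm(C * H * W), c(C, H, W)))
  wts <- windowAttentionWeights(C, heads = 2, seed = 5)
  out <- windowAttention(f, window = 8, shift = 0, heads = 2, weights = wts)
  dense <- dense_attention_oracle(matrix(f, C, H * W), wts, heads = 2)
  expect_equal(matrix(out, C, H * W), dense, tolerance = 1e-10)
})

test_that("window attention weights are row-stochastic and windows act independently", {
  C <- 4; H <- 8; W <- 8
  withr::with_seed(6, f4 <- array(rnorm(C * H * W), c(C, H, W, 1)))
  wts <- windowAttentionWeights(C, heads = 2, seed = 7)
  # probe attention rows through the op's aux output
  q <- vegdet:::agLinear(vegdet:::agConst(f4), wts$wq, wts$bq)
  qp <- vegdet:::window_partition_ag(q, 4L, H, W, C, 1L)
  at <- vegdet:::agAttention(qp, qp, qp, heads = 2L)
  for (A in at$aux$attn) expect_equal(colSums(A[, , 1]), rep(1, 16))

  # a map tiled from identical windows gives identical per-window outputs
  tile <- array(rnorm(C * 4 * 4), c(C, 4, 4))
  big <- array(0, c(C, 8, 8))
  big[, 1:4, 1:4] <- tile; big[, 5:8, 1:4] <- tile
  big[, 1:4, 5:8] <- tile; big[, 5:8, 5:8] <- tile
  o <- windowAttention(big, window = 4, shift = 0, heads = 2, weights = wts)
  expect_equal(o[, 1:4, 1:4], o[, 5:8, 5:8], tolerance = 1e-10)
  expect_equal(o[, 5:8, 1:4], o[, 1:4, 5:8], tolerance = 1e-10)
})

test_that("shifted windows change the result but preserve shape", {
  C <- 4; withr::with_seed(8, f <- array(rnorm(C * 8 * 8), c(C, 8, 8)))
  wts <- windowAttentionWeights(C, heads = 1, seed = 9)
  plain <- windowAttention(f, window = 4, shift = 0, heads = 1, weights = wts)
  shifted <- windowAttention(f, window = 4, shift = 2, heads = 1, weights = wts)
  expect_equal(dim(shifted), dim(f))
  expect_false(isTRUE(all.equal(plain, shifted)))
})

test_that("bilinear sampling matches interpolation identities and a loop oracle", {
  C <- 3; H <- 5; W <- 4
  withr::with_seed(10, f <- array(rnorm(C * H * W), c(C, H, W)))
  # grid node
  expect_equal(as.numeric(bilinearSample(f, matrix(c(-1, -1), 1))), f[, 1, 1])
  expect_equal(as.numeric(bilinearSample(f, matrix(c(1, 1), 1))), f[, H, W])
  # midpoint of the first 2x2 cell
  mid <- matrix(c(-1 + 1 / (H - 1), -1 + 1 / (W - 1)), 1)
  expect_equal(as.numeric(bilinearSample(f, mid)),
               (f[, 1, 1] + f[, 1, 2] + f[, 2, 1] + f[, 2, 2]) / 4)
  # random points vs per-point loop oracle
  withr::with_seed(11, pts <- cbind(runif(20, -1, 1), runif(20, -1, 1)))
  got <- bilinearSample(f, pts)
  for (p in seq_len(nrow(pts))) {
    py <- (pts[p, 1] + 1) / 2 * (H - 1) + 1
    px <- (pts[p, 2] + 1) / 2 * (W - 1) + 1
    y0 <- floor(py); x0 <- floor(px)
    y0 <- min(max(y0, 1), H - 1); x0 <- min(max(x0, 1), W - 1)
    wy <- py - y0; wx <- px - x0
    ref <- (1 - wy) * (1 - wx) * f[, y0, x0] + (1 - wy) * wx * f[, y0, x0 + 1] +
      wy * (1 - wx) * f[, y0 + 1, x0] + wy * wx * f[, y0 + 1, x0 + 1]
    expect_equal(got[, p], ref, tolerance = 1e-12)
  }
  # out-of-range points clamp to the border
  expect_equal(as.numeric(bilinearSample(f, matrix(c(-5, -5), 1))), f[, 1, 1])
})

test_that("the reference grid covers [-1,1]^2 uniformly", {
  rp <- referencePoints(4)
  expect_equal(dim(rp), c(16L, 2L))
  expect_equal(sort(unique(rp[, 1])), seq(-1, 1, length.out = 4))
  expect_equal(sort(unique(rp[, 2])), seq(-1, 1, length.out = 4))
})

test_that("zero-offset deformable attention equals dense attention over the grid", {
  C <- 8; H <- 8; W <- 8; heads <- 2
  withr::with_seed(12, f <- array(rnorm(C * H * W), c(C, H, W)))
  dw <- deformableAttentionWeights(C, heads = heads, seed = 13,
                                   zero_offsets = TRUE)
  cfg <- datConfig(n_points = 4L)
  out <- deformableAttention(f, cfg, weights = dw, heads = heads)
  expect_equal(max(abs(attr(out, "offsets"))), 0)

  ref <- referencePoints(4L)
  sampled <- bilinearSample(f, ref)
  tok <- matrix(f, C, H * W)
  k <- dw$wk %*% sampled + dw$bk
  v <- dw$wv %*% sampled + dw$bv
  q <- dw$wq %*% tok + dw$bq
  bias <- vegdet:::agNoGrad(vegdet:::deform_bias(
    dw$bias_table, array(t(ref), c(2, 16, 1)),
    vegdet:::query_positions_2xm(H, W), heads, 16L, H * W, 1L
  ))$v
  dh <- C / heads
  oo <- matrix(0, C, H * W)
  for (h in seq_len(heads)) {
    r <- (h - 1) * dh + seq_len(dh)
    S <- t(k[r, , drop = FALSE]) %*% q[r, , drop = FALSE] / sqrt(dh) +
      bias[, , h, 1]
    A <- apply(S, 2, function(s) { e <- exp(s - max(s)); e / sum(e) })
    oo[r, ] <- v[r, , drop = FALSE] %*% A
  }
  dense <- dw$wo %*% oo + dw$bo
  expect_equal(matrix(out, C, H * W), dense, tolerance = 1e-10)
})

test_that("learned offsets respect the configured bound", {
  C <- 8
  withr::with_seed(14, f <- array(rnorm(C * 8 * 8) * 3, c(C, 8, 8)))
  for (orf in c(0.5, 2)) {
    dw <- deformableAttentionWeights(C, heads = 2, seed = 15)
    cfg <- datConfig(n_points = 4L, offset_range_factor = orf)
    out <- deformableAttention(f, cfg, weights = dw, heads = 2)
    expect_lte(max(abs(attr(out, "offsets"))), orf + 1e-12)
  }
})

test_that("the 4-stage extractor produces the halving pyramid and stays finite", {
  cfg <- datConfig(embed_dim = 8, stage_depths = c(1, 1, 1, 1),
                   heads_per_stage = c(1, 1, 2, 2), window_size = 4)
  model <- datBuild(cfg, seed = 1)
  withr::with_seed(2, img <- array(runif(3 * 64 * 64), c(3, 64, 64)))
  outs <- datForward(img, model = model)
  dims <- t(vapply(outs, function(o) dim(o@values), integer(3)))
  expect_equal(dims[, 2], c(16L, 8L, 4L, 2L)) # 64/4, then three 2x halvings
  expect_equal(dims[, 1], 8L * 2L^(0:3))
  expect_equal(vapply(outs, function(o) o@stride, 1L), c(4L, 8L, 16L, 32L))
  expect_true(all(vapply(outs, function(o) all(is.finite(o@values)), TRUE)))
  # doubling the input doubles every stage extent
  outs2 <- datForward(array(runif(3 * 128 * 128), c(3, 128, 128)), model = model)
  dims2 <- t(vapply(outs2, function(o) dim(o@values), integer(3)))
  expect_equal(dims2[, 2], 2L * dims[, 2])
})
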