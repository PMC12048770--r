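# Neural-network operations on the autodiff tape.
#
# Feature tensors are (C, H, W, N) column-major arrays (channel fastest),
# so a (C, M) matrix view needs no copy. Token tensors are (d, T) matrices
# or (d, T, B) arrays with B = windows x batch.

pad_chw <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1], d[2] + 2L * pad, d[3] + 2L * pad, d[4]))
  out[, pad + seq_len(d[2]), pad + seq_len(d[3]), ] <- x
  out
}

unpad_chw <- function(x, pad, H, W) {
  if (pad == 0L) return(x)
  x[, pad + seq_len(H), pad + seq_len(W), , drop = FALSE]
}

im2col <- function(xp, k, stride, Hout, Wout) {
  d <- dim(xp)
  Cin <- d[1]; N <- d[4]
  cols <- array(0, c(Cin * k * k, Hout, Wout, N))
  for (dy in seq_len(k)) {
    ys <- seq.int(dy, by = stride, length.out = Hout)
    for (dx in seq_len(k)) {
      xs <- seq.int(dx, by = stride, length.out = Wout)
      rows <- ((dy - 1L) * k + (dx - 1L)) * Cin + seq_len(Cin)
      cols[rows, , , ] <- xp[, ys, xs, , drop = FALSE]
    }
  }
  dim(cols) <- c(Cin * k * k, Hout * Wout * N)
  cols
}

col2im <- function(dcols, dxp_dims, k, stride, Hout, Wout) {
  Cin <- dxp_dims[1]; N <- dxp_dims[4]
  dim(dcols) <- c(Cin * k * k, Hout, Wout, N)
  dxp <- array(0, dxp_dims)
  for (dy in seq_len(k)) {
    ys <- seq.int(dy, by = stride, length.out = Hout)
    for (dx in seq_len(k)) {
      xs <- seq.int(dx, by = stride, length.out = Wout)
      rows <- ((dy - 1L) * k + (dx - 1L)) * Cin + seq_len(Cin)
      dxp[, ys, xs, ] <- dxp[, ys, xs, , drop = FALSE] + dcols[rows, , , , drop = FALSE]
    }
  }
  dxp
}

#' 2-D convolution (NCHW, weight as (Cout, Cin*k*k) matrix)
#' @keywords internal
agConv2d <- function(x, w, b = NULL, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  x <- as_ag(x); w <- as_ag(w)
  d <- dim(x$v)
  Cin <- d[1]; H <- d[2]; W <- d[3]; N <- d[4]
  Cout <- dim(w$v)[1]
  xp <- pad_chw(x$v, pad)
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Hout <- (Hp - k) %/% stride + 1L
  Wout <- (Wp - k) %/% stride + 1L
  cols <- im2col(xp, k, stride, Hout, Wout)
  out <- w$v %*% cols
  ag_count_macs(as.double(Cout) * nrow(cols) * ncol(cols))
  if (!is.null(b)) {
    b <- as_ag(b)
    out <- out + as.numeric(b$v)
  }
  dim(out) <- c(Cout, Hout, Wout, N)
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  agOp(out, parents, function(g) {
    dim(g) <- c(Cout, Hout * Wout * N)
    dw <- g %*% t(cols)
    db <- if (is.null(b)) NULL else rowSums(g)
    dx <- NULL
    if (x$track) {
      dcols <- crossprod(w$v, g)
      dxp <- col2im(dcols, c(Cin, Hp, Wp, N), k, stride, Hout, Wout)
      dx <- unpad_chw(dxp, pad, H, W)
    }
    if (is.null(b)) list(dx, dw) else list(dx, dw, db)
  })
}

#' Depthwise 2-D convolution; weight (k*k, C), bias length C or NULL
#' @keywords internal
agDwConv2d <- function(x, w, b = NULL, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  x <- as_ag(x); w <- as_ag(w)
  d <- dim(x$v)
  C <- d[1]; H <- d[2]; W <- d[3]; N <- d[4]
  xp <- pad_chw(x$v, pad)
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Hout <- (Hp - k) %/% stride + 1L
  Wout <- (Wp - k) %/% stride + 1L
  # per-offset accumulation: out[c,i,j] = sum_dy,dx w[(dy,dx),c] * xp[c, ...]
  out <- array(0, c(C, Hout, Wout, N))
  for (dy in seq_len(k)) {
    ys <- seq.int(dy, by = stride, length.out = Hout)
    for (dx in seq_len(k)) {
      xs <- seq.int(dx, by = stride, length.out = Wout)
      wi <- w$v[(dy - 1L) * k + dx, ]
      out <- out + xp[, ys, xs, , drop = FALSE] * wi
    }
  }
  ag_count_macs(as.double(C) * k * k * Hout * Wout * N)
  if (!is.null(b)) {
    b <- as_ag(b)
    out <- out + as.numeric(b$v)
  }
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  agOp(out, parents, function(g) {
    dw <- matrix(0, k * k, C)
    dxp <- array(0, c(C, Hp, Wp, N))
    gm <- g
    dim(gm) <- c(C, Hout * Wout * N)
    for (dy in seq_len(k)) {
      ys <- seq.int(dy, by = stride, length.out = Hout)
      for (dx in seq_len(k)) {
        xs <- seq.int(dx, by = stride, length.out = Wout)
        patch <- xp[, ys, xs, , drop = FALSE]
        dim(patch) <- c(C, Hout * Wout * N)
        dw[(dy - 1L) * k + dx, ] <- rowSums(gm * patch)
        wi <- w$v[(dy - 1L) * k + dx, ]
        dxp[, ys, xs, ] <- dxp[, ys, xs, , drop = FALSE] + g * wi
      }
    }
    db <- if (is.null(b)) NULL else rowSums(gm)
    dx <- unpad_chw(dxp, pad, H, W)
    if (is.null(b)) list(dx, dw) else list(dx, dw, db)
  })
}

#' Per-channel batch normalization over (H, W, N)
#'
#' `state` is an environment with running_mean / running_var, updated in
#' training mode.
#' @keywords internal
agBatchNorm <- function(x, gamma, beta, state, training = FALSE,
                        momentum = 0.1, eps = 1e-5) {
  x <- as_ag(x); gamma <- as_ag(gamma); beta <- as_ag(beta)
  d <- dim(x$v)
  C <- d[1]; M <- prod(d[-1])
  xm <- x$v
  dim(xm) <- c(C, M)
  if (training) {
    mu <- rowMeans(xm)
    va <- rowMeans((xm - mu)^2)
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    state$running_var <- (1 - momentum) * state$running_var + momentum * va
  } else {
    mu <- state$running_mean
    va <- state$running_var
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- (xm - mu) * istd
  y <- xhat * as.numeric(gamma$v) + as.numeric(beta$v)
  dim(y) <- d
  agOp(y, list(x, gamma, beta), function(g) {
    gm <- g
    dim(gm) <- c(C, M)
    dgamma <- rowSums(gm * xhat)
    dbeta <- rowSums(gm)
    dx <- NULL
    if (x$track) {
      dxhat <- gm * as.numeric(gamma$v)
      if (training) {
        dx <- istd / M * (M * dxhat - rowSums(dxhat) - xhat * rowSums(dxhat * xhat))
      } else {
        dx <- dxhat * istd
      }
      dim(dx) <- d
    }
    list(dx, dgamma, dbeta)
  })
}

#' Global max pool over H, W -> (C, 1, 1, N)
#' @keywords internal
agGlobalMaxPool <- function(x) {
  x <- as_ag(x)
  d <- dim(x$v)
  C <- d[1]; HW <- d[2] * d[3]; N <- d[4]
  x3 <- x$v
  dim(x3) <- c(C, HW, N)
  out <- array(0, c(C, 1L, 1L, N))
  arg <- matrix(0L, C, N)
  for (n in seq_len(N)) {
    m <- x3[, , n, drop = TRUE]
    dim(m) <- c(C, HW)
    j <- max.col(m, ties.method = "first")
    arg[, n] <- j
    out[, 1L, 1L, n] <- m[cbind(seq_len(C), j)]
  }
  agOp(out, list(x), function(g) {
    dx <- array(0, c(C, HW, N))
    for (n in seq_len(N)) {
      dx[cbind(seq_len(C), arg[, n], n)] <- g[, 1L, 1L, n]
    }
    dim(dx) <- d
    list(dx)
  })
}

#' Global average pool over H, W -> (C, 1, 1, N)
#' @keywords internal
agGlobalAvgPool <- function(x) {
  x <- as_ag(x)
  d <- dim(x$v)
  C <- d[1]; HW <- d[2] * d[3]; N <- d[4]
  x3 <- x$v
  dim(x3) <- c(C, HW, N)
  out <- apply(x3, 3L, rowMeans)
  dim(out) <- c(C, 1L, 1L, N)
  agOp(out, list(x), function(g) {
    gv <- g
    dim(gv) <- c(C, N)
    dx <- array(0, c(C, HW, N))
    for (n in seq_len(N)) dx[, , n] <- gv[, n] / HW
    dim(dx) <- d
    list(dx)
  })
}

#' Channel-wise max and mean -> (1, H, W, N) each; returns list(max, mean)
#' @keywords internal
agChanMax <- function(x) {
  x <- as_ag(x)
  d <- dim(x$v)
  C <- d[1]; M <- prod(d[-1])
  xm <- x$v
  dim(xm) <- c(C, M)
  tm <- t(xm)
  j <- max.col(tm, ties.method = "first")
  out <- tm[cbind(seq_len(M), j)]
  dim(out) <- c(1L, d[2], d[3], d[4])
  agOp(out, list(x), function(g) {
    dx <- matrix(0, C, M)
    dx[cbind(j, seq_len(M))] <- as.numeric(g)
    dim(dx) <- d
    list(dx)
  })
}

#' @keywords internal
agChanMean <- function(x) {
  x <- as_ag(x)
  d <- dim(x$v)
  C <- d[1]; M <- prod(d[-1])
  xm <- x$v
  dim(xm) <- c(C, M)
  out <- colMeans(xm)
  dim(out) <- c(1L, d[2], d[3], d[4])
  agOp(out, list(x), function(g) {
    gv <- as.numeric(g)
    dx <- matrix(rep(gv / C, each = C), C, M)
    dim(dx) <- d
    list(dx)
  })
}

#' Nearest-neighbour 2x upsampling
#' @keywords internal
agUpsample2 <- function(x) {
  x <- as_ag(x)
  d <- dim(x$v)
  H <- d[2]; W <- d[3]
  v <- x$v[, rep(seq_len(H), each = 2L), rep(seq_len(W), each = 2L), , drop = FALSE]
  agOp(v, list(x), function(g) {
    o1 <- seq.int(1L, 2L * H, 2L); o2 <- o1 + 1L
    e1 <- seq.int(1L, 2L * W, 2L); e2 <- e1 + 1L
    dx <- g[, o1, e1, , drop = FALSE] + g[, o1, e2, , drop = FALSE] +
      g[, o2, e1, , drop = FALSE] + g[, o2, e2, , drop = FALSE]
    list(dx)
  })
}

#' Strided 2x2 max pooling (downsampling path of the neck)
#' @keywords internal
agMaxPool2 <- function(x) {
  x <- as_ag(x)
  d <- dim(x$v)
  C <- d[1]; H <- d[2]; W <- d[3]; N <- d[4]
  Ho <- H %/% 2L; Wo <- W %/% 2L
  cands <- list(
    x$v[, seq.int(1L, 2L * Ho, 2L), seq.int(1L, 2L * Wo, 2L), , drop = FALSE],
    x$v[, seq.int(1L, 2L * Ho, 2L), seq.int(2L, 2L * Wo, 2L), , drop = FALSE],
    x$v[, seq.int(2L, 2L * Ho, 2L), seq.int(1L, 2L * Wo, 2L), , drop = FALSE],
    x$v[, seq.int(2L, 2L * Ho, 2L), seq.int(2L, 2L * Wo, 2L), , drop = FALSE]
  )
  v <- pmax(cands[[1]], cands[[2]], cands[[3]], cands[[4]])
  agOp(v, list(x), function(g) {
    dx <- array(0, d)
    left <- array(TRUE, dim(v))
    offs <- list(c(1L, 1L), c(1L, 2L), c(2L, 1L), c(2L, 2L))
    for (i in 1:4) {
      sel <- left & (cands[[i]] == v)
      left <- left & !sel
      oy <- seq.int(offs[[i]][1], by = 2L, length.out = Ho)
      ox <- seq.int(offs[[i]][2], by = 2L, length.out = Wo)
      dx[, oy, ox, ] <- dx[, oy, ox, , drop = FALSE] + g * sel
    }
    list(dx)
  })
}

#' Linear layer on (din, T) token matrices: W x + b
#' @keywords internal
agLinear <- function(x, w, b = NULL) {
  x <- as_ag(x); w <- as_ag(w)
  d0 <- dim(x$v)
  xm <- x$v
  dim(xm) <- c(d0[1], prod(d0[-1]))
  out <- w$v %*% xm
  ag_count_macs(as.double(nrow(w$v)) * ncol(w$v) * ncol(xm))
  if (!is.null(b)) {
    b <- as_ag(b)
    out <- out + as.numeric(b$v)
  }
  dim(out) <- c(nrow(w$v), d0[-1])
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  agOp(out, parents, function(g) {
    gm <- g
    dim(gm) <- c(nrow(w$v), prod(d0[-1]))
    dw <- tcrossprod(gm, xm)
    db <- if (is.null(b)) NULL else rowSums(gm)
    dx <- NULL
    if (x$track) {
      dx <- crossprod(w$v, gm)
      dim(dx) <- d0
    }
    if (is.null(b)) list(dx, dw) else list(dx, dw, db)
  })
}

#' Layer normalization over the feature (first) dimension per token
#' @keywords internal
agLayerNorm <- function(x, gamma, beta, eps = 1e-5) {
  x <- as_ag(x); gamma <- as_ag(gamma); beta <- as_ag(beta)
  d0 <- dim(x$v)
  dd <- d0[1]; T <- prod(d0[-1])
  xm <- x$v
  dim(xm) <- c(dd, T)
  mu <- colMeans(xm)
  xc <- xm - rep(mu, each = dd)
  va <- colMeans(xc^2)
  istd <- rep(1 / sqrt(va + eps), each = dd)
  xhat <- xc * istd
  y <- xhat * as.numeric(gamma$v) + as.numeric(beta$v)
  dim(y) <- d0
  agOp(y, list(x, gamma, beta), function(g) {
    gm <- g
    dim(gm) <- c(dd, T)
    dgamma <- rowSums(gm * xhat)
    dbeta <- rowSums(gm)
    dxhat <- gm * as.numeric(gamma$v)
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * xhat)
    dx <- istd / dd * (dd * dxhat - rep(s1, each = dd) - xhat * rep(s2, each = dd))
    dim(dx) <- d0
    list(dx, dgamma, dbeta)
  })
}

#' Multi-head scaled-dot-product attention over batched token sets
#'
#' q: (d, Tq, B); k: (d, Tk, B); v: (d, Tk, B). `bias` (optional tracked
#' tensor or array) has dim (Tk, Tq, heads) shared across B, or
#' (Tk, Tq, heads, B). `mask` is an additive plain array (Tk, Tq, B)
#' (0 / -Inf), used by shifted-window attention. Softmax is over the key
#' dimension, so each query's attention weights sum to one. Attention
#' matrices are kept in `$aux$attn` (list over B, each (Tk, Tq, heads)).
#' @keywords internal
agAttention <- function(q, k, v, heads, bias = NULL, mask = NULL) {
  q <- as_ag(q); k <- as_ag(k); v <- as_ag(v)
  dq <- dim(q$v); dk <- dim(k$v)
  d <- dq[1]; Tq <- dq[2]; B <- dq[3]; Tk <- dk[2]
  stopifnot(d %% heads == 0L)
  dh <- d %/% heads
  scale <- 1 / sqrt(dh)
  has_bias <- !is.null(bias)
  if (has_bias) bias <- as_ag(bias)
  bias_per_b <- has_bias && length(dim(bias$v)) == 4L
  slice3 <- function(a, rows, b, Tn) {
    s <- a[rows, , b, drop = FALSE]
    dim(s) <- c(length(rows), Tn)
    s
  }
  out <- array(0, c(d, Tq, B))
  attn <- vector("list", B)
  for (b in seq_len(B)) {
    Ab <- array(0, c(Tk, Tq, heads))
    for (h in seq_len(heads)) {
      rows <- (h - 1L) * dh + seq_len(dh)
      S <- crossprod(slice3(k$v, rows, b, Tk), slice3(q$v, rows, b, Tq)) * scale
      if (has_bias) S <- S + (if (bias_per_b) bias$v[, , h, b] else bias$v[, , h])
      if (!is.null(mask)) S <- S + mask[, , b]
      S <- S - rep(apply(S, 2L, max), each = Tk)
      A <- exp(S)
      A <- A / rep(colSums(A), each = Tk)
      Ab[, , h] <- A
      out[rows, , b] <- slice3(v$v, rows, b, Tk) %*% A
    }
    attn[[b]] <- Ab
  }
  ag_count_macs(2 * as.double(d) * Tq * Tk * B)
  parents <- list(q, k, v)
  if (has_bias) parents <- c(parents, list(bias))
  agOp(out, parents, function(g) {
    dqv <- zeros_like(q$v); dkv <- zeros_like(k$v); dvv <- zeros_like(v$v)
    dbias <- if (has_bias && bias$track) zeros_like(bias$v) else NULL
    for (b in seq_len(B)) {
      for (h in seq_len(heads)) {
        rows <- (h - 1L) * dh + seq_len(dh)
        A <- attn[[b]][, , h]
        dim(A) <- c(Tk, Tq)
        gO <- slice3(g, rows, b, Tq)
        Vh <- slice3(v$v, rows, b, Tk)
        dvv[rows, , b] <- dvv[rows, , b] + tcrossprod(gO, A)
        dA <- crossprod(Vh, gO)
        dS <- A * (dA - rep(colSums(A * dA), each = Tk))
        Kh <- slice3(k$v, rows, b, Tk)
        Qh <- slice3(q$v, rows, b, Tq)
        dqv[rows, , b] <- dqv[rows, , b] + (Kh %*% dS) * scale
        dkv[rows, , b] <- dkv[rows, , b] + (Qh %*% t(dS)) * scale
        if (!is.null(dbias)) {
          if (bias_per_b) dbias[, , h, b] <- dbias[, , h, b] + dS
          else dbias[, , h] <- dbias[, , h] + dS
        }
      }
    }
    res <- list(dqv, dkv, dvv)
    if (has_bias) res <- c(res, list(dbias))
    res
  }, aux = list(attn = attn))
}

#' Bilinear sampling of a feature map at normalized points
#'
#' f: (C, H, W, N); pts: (2, P, N) with row 1 = y, row 2 = x in [-1, 1]
#' (align-corners convention: -1 and 1 map to the outermost pixel centres).
#' Out-of-range points clamp to the border. Returns (C, P, N).
#' @keywords internal
agBilinearSample <- function(f, pts) {
  f <- as_ag(f); pts <- as_ag(pts)
  d <- dim(f$v)
  C <- d[1]; H <- d[2]; W <- d[3]; N <- d[4]
  dp <- dim(pts$v)
  P <- dp[2]
  out <- array(0, c(C, P, N))
  cache <- vector("list", N)
  for (n in seq_len(N)) {
    py <- (pts$v[1, , n] + 1) / 2 * (H - 1) + 1
    px <- (pts$v[2, , n] + 1) / 2 * (W - 1) + 1
    cy <- py < 1 | py > H # clamped -> zero point-gradient
    cx <- px < 1 | px > W
    py <- pmin(pmax(py, 1), H)
    px <- pmin(pmax(px, 1), W)
    y0 <- pmin(floor(py), H - 1); y0 <- pmax(y0, 1)
    x0 <- pmin(floor(px), W - 1); x0 <- pmax(x0, 1)
    wy <- py - y0
    wx <- px - x0
    fm <- f$v[, , , n]
    dim(fm) <- c(C, H * W)
    i00 <- (x0 - 1) * H + y0
    i01 <- x0 * H + y0
    i10 <- (x0 - 1) * H + y0 + 1
    i11 <- x0 * H + y0 + 1
    v00 <- fm[, i00, drop = FALSE]; v01 <- fm[, i01, drop = FALSE]
    v10 <- fm[, i10, drop = FALSE]; v11 <- fm[, i11, drop = FALSE]
    w00 <- (1 - wy) * (1 - wx); w01 <- (1 - wy) * wx
    w10 <- wy * (1 - wx); w11 <- wy * wx
    out[, , n] <- v00 * rep(w00, each = C) + v01 * rep(w01, each = C) +
      v10 * rep(w10, each = C) + v11 * rep(w11, each = C)
    cache[[n]] <- list(i = cbind(i00, i01, i10, i11), wy = wy, wx = wx,
                       cy = cy, cx = cx,
                       v = list(v00, v01, v10, v11))
  }
  agOp(out, list(f, pts), function(g) {
    df <- if (f$track) zeros_like(f$v) else NULL
    dpts <- if (pts$track) zeros_like(pts$v) else NULL
    for (n in seq_len(N)) {
      cc <- cache[[n]]
      gO <- g[, , n, drop = TRUE]
      dim(gO) <- c(C, P)
      wy <- cc$wy; wx <- cc$wx
      if (!is.null(df)) {
        dfm <- matrix(0, C, H * W)
        wts <- cbind((1 - wy) * (1 - wx), (1 - wy) * wx, wy * (1 - wx), wy * wx)
        for (corner in 1:4) {
          idx <- cc$i[, corner]
          contrib <- gO * rep(wts[, corner], each = C)
          for (j in seq_len(P)) dfm[, idx[j]] <- dfm[, idx[j]] + contrib[, j]
        }
        df[, , , n] <- df[, , , n, drop = FALSE] + array(dfm, c(C, H, W, 1L))
      }
      if (!is.null(dpts)) {
        v00 <- cc$v[[1]]; v01 <- cc$v[[2]]; v10 <- cc$v[[3]]; v11 <- cc$v[[4]]
        ddy <- (1 - wx) * colSums(gO * (v10 - v00)) + wx * colSums(gO * (v11 - v01))
        ddx <- (1 - wy) * colSums(gO * (v01 - v00)) + wy * colSums(gO * (v11 - v10))
        ddy[cc$cy] <- 0
        ddx[cc$cx] <- 0
        dpts[1, , n] <- ddy * (H - 1) / 2
        dpts[2, , n] <- ddx * (W - 1) / 2
      }
    }
    list(df, dpts)
  })
}

#' Mean binary cross-entropy with logits
#'
#' `target` and optional elementwise `weight` are plain arrays matching `x`.
#' `pos_weight` scales the positive-target term (the BCE positive-sample
#' weight hyperparameter).
#' @keywords internal
agBceLogits <- function(x, target, weight = NULL, pos_weight = 1) {
  x <- as_ag(x)
  xv <- x$v
  t <- target
  # stable: -[pw*t*log(s) + (1-t)*log(1-s)], log s(x) = min(x,0) - log1p(exp(-|x|))
  logs <- pmin(xv, 0) - log1p(exp(-abs(xv)))
  log1ms <- pmin(-xv, 0) - log1p(exp(-abs(xv)))
  l <- -(pos_weight * t * logs + (1 - t) * log1ms)
  if (!is.null(weight)) l <- l * weight
  M <- length(l)
  agOp(array(mean(l), 1L), list(x), function(g) {
    s <- stats::plogis(xv)
    dx <- (-pos_weight * t * (1 - s) + (1 - t) * s)
    if (!is.null(weight)) dx <- dx * weight
    list(dx * as.numeric(g) / M)
  })
}
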