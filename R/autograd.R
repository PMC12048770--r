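#' @name autograd
#' @title Reverse-mode automatic differentiation on dense arrays
#'
#' @description
#' A minimal tape-based autodiff engine used by every neural component in the
#' package (DAT backbone, CSAAM neck, detection head, trainer). A tensor is a
#' mutable environment holding a numeric array `v`, an accumulated gradient
#' `g`, its parent nodes and a backward closure. Operations build the tape
#' dynamically; [agBackward()] topologically sorts the tape and accumulates
#' gradients into every tracked node. Tracking starts at parameters
#' ([agParam()]) and propagates, so gradients are never computed for
#' input-only subgraphs. Arrays are plain column-major R arrays; matrix
#' products go through BLAS.
#'
#' Not exported: internal infrastructure with a stable in-package API.
#' @keywords internal
NULL

.ag <- new.env(parent = emptyenv())
.ag$id <- 0L
.ag$grad <- TRUE
.ag$macs <- NULL # when an env, ops add multiply-accumulate counts to it

ag_next_id <- function() {
  .ag$id <- .ag$id + 1L
  .ag$id
}

ag_grad_on <- function() .ag$grad

#' Evaluate an expression without recording the autodiff tape
#' @keywords internal
agNoGrad <- function(expr) {
  old <- .ag$grad
  .ag$grad <- FALSE
  on.exit(.ag$grad <- old)
  expr
}

ag_count_macs <- function(n) {
  if (!is.null(.ag$macs)) .ag$macs$total <- .ag$macs$total + as.double(n)
  invisible(NULL)
}

#' Create a tensor node
#'
#' @param v numeric array (or vector/matrix; coerced to array).
#' @param parents list of parent nodes.
#' @param bw function(g) returning a list of gradients aligned with `parents`
#'   (NULL entries allowed for untracked parents).
#' @keywords internal
agTensor <- function(v, parents = list(), bw = NULL) {
  if (is.null(dim(v))) dim(v) <- length(v)
  e <- new.env(parent = emptyenv())
  e$v <- v
  e$g <- NULL
  e$parents <- parents
  e$bw <- bw
  e$track <- length(parents) > 0L && any(vapply(parents, function(p) p$track, TRUE))
  e$param <- FALSE
  e$id <- ag_next_id()
  class(e) <- "ag_tensor"
  e
}

#' Create a trainable parameter node
#' @param v initial value array.
#' @param name dotted path name; the leading component ("backbone", "neck",
#'   "head") is the transfer-learning partition.
#' @keywords internal
agParam <- function(v, name) {
  e <- agTensor(v)
  e$track <- TRUE
  e$param <- TRUE
  e$name <- name
  e
}

#' Constant (untracked) tensor
#' @keywords internal
agConst <- function(v) agTensor(v)

as_ag <- function(x) if (inherits(x, "ag_tensor")) x else agConst(x)

#' Generic op constructor: drops the tape when gradients are off or no parent
#' is tracked.
#' @keywords internal
agOp <- function(v, parents, bw, aux = NULL) {
  if (!ag_grad_on() || !any(vapply(parents, function(p) p$track, TRUE))) {
    e <- agTensor(v)
  } else {
    e <- agTensor(v, parents, bw)
  }
  if (!is.null(aux)) e$aux <- aux
  e
}

zeros_like <- function(x) array(0, dim(x))

#' Run backpropagation from a scalar (or any) node
#'
#' Accumulates gradients into `$g` of every tracked node reachable from
#' `root`. Existing gradients on parameters are overwritten, not accumulated
#' across calls (call [agZeroGrad()] semantics are implicit).
#' @keywords internal
agBackward <- function(root, seed_grad = NULL) {
  # iterative topological sort over tracked subgraph
  topo <- vector("list", 256L)
  ntopo <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = root, stage = 1L))
  while (length(stack) > 0L) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top$node
    key <- as.character(node$id)
    if (top$stage == 1L) {
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = node, stage = 2L)
      for (p in node$parents) {
        if (p$track && is.null(seen[[as.character(p$id)]])) {
          stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
        }
      }
    } else {
      ntopo <- ntopo + 1L
      if (ntopo > length(topo)) topo <- c(topo, vector("list", length(topo)))
      topo[[ntopo]] <- node
    }
  }
  if (is.null(seed_grad)) seed_grad <- array(1, dim(root$v))
  root$g <- seed_grad
  for (i in seq_len(ntopo)) {
    node <- topo[[ntopo - i + 1L]]
    if (is.null(node$g)) node$g <- zeros_like(node$v)
    if (is.null(node$bw)) next
    gs <- node$bw(node$g)
    ps <- node$parents
    for (j in seq_along(ps)) {
      p <- ps[[j]]
      if (!p$track || is.null(gs[[j]])) next
      gj <- gs[[j]]
      if (is.null(dim(gj))) dim(gj) <- dim(p$v)
      if (is.null(p$g)) p$g <- gj else p$g <- p$g + gj
    }
    if (!node$param) {
      node$g <- NULL # free intermediate grads early
    }
  }
  invisible(root)
}

#' Clear gradients on a list of parameter nodes
#' @keywords internal
agZeroGrad <- function(params) {
  for (p in params) p$g <- NULL
  invisible(NULL)
}

# ---- broadcasting helpers ------------------------------------------------

# expand array x to target dims td (dims equal or 1)
bc_to <- function(x, td) {
  d <- dim(x)
  if (identical(as.integer(d), as.integer(td))) return(x)
  stopifnot(length(d) == length(td))
  for (k in seq_along(td)) {
    if (d[k] == td[k]) next
    stopifnot(d[k] == 1L)
    perm <- c(k, seq_along(d)[-k])
    xp <- aperm(x, perm)
    xp <- matrix(xp, nrow = 1L)
    xp <- xp[rep.int(1L, td[k]), , drop = FALSE]
    dim(xp) <- c(td[k], d[-k])
    x <- aperm(xp, order(perm))
    d <- dim(x)
  }
  x
}

# sum gradient g (dims dg) down to dims d0 (entries equal or 1)
bc_reduce <- function(g, d0) {
  dg <- dim(g)
  if (identical(as.integer(dg), as.integer(d0))) return(g)
  for (k in seq_along(d0)) {
    dg <- dim(g)
    if (d0[k] == dg[k]) next
    perm <- c(k, seq_along(dg)[-k])
    gp <- aperm(g, perm)
    dim(gp) <- c(dg[k], prod(dg[-k]))
    s <- colSums(gp)
    dim(s) <- c(1L, dg[-k])
    g <- aperm(s, order(perm))
  }
  g
}

bc_dims <- function(a, b) {
  da <- dim(a)
  db <- dim(b)
  stopifnot(length(da) == length(db))
  ifelse(da > db, da, db)
}

# ---- elementwise ops (broadcasting) --------------------------------------

agAdd <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  td <- bc_dims(a$v, b$v)
  v <- bc_to(a$v, td) + bc_to(b$v, td)
  agOp(v, list(a, b), function(g) list(bc_reduce(g, dim(a$v)), bc_reduce(g, dim(b$v))))
}

agSub <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  td <- bc_dims(a$v, b$v)
  v <- bc_to(a$v, td) - bc_to(b$v, td)
  agOp(v, list(a, b), function(g) list(bc_reduce(g, dim(a$v)), bc_reduce(-g, dim(b$v))))
}

agMul <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  td <- bc_dims(a$v, b$v)
  av <- bc_to(a$v, td); bv <- bc_to(b$v, td)
  agOp(av * bv, list(a, b), function(g) {
    list(bc_reduce(g * bv, dim(a$v)), bc_reduce(g * av, dim(b$v)))
  })
}

agDiv <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  td <- bc_dims(a$v, b$v)
  av <- bc_to(a$v, td); bv <- bc_to(b$v, td)
  agOp(av / bv, list(a, b), function(g) {
    list(bc_reduce(g / bv, dim(a$v)), bc_reduce(-g * av / (bv * bv), dim(b$v)))
  })
}

agScale <- function(a, s) {
  a <- as_ag(a)
  agOp(a$v * s, list(a), function(g) list(g * s))
}

agAddScalar <- function(a, s) {
  a <- as_ag(a)
  agOp(a$v + s, list(a), function(g) list(g))
}

agExp <- function(a) {
  a <- as_ag(a)
  v <- exp(a$v)
  agOp(v, list(a), function(g) list(g * v))
}

agLog <- function(a) {
  a <- as_ag(a)
  agOp(log(a$v), list(a), function(g) list(g / a$v))
}

agRelu <- function(a) {
  a <- as_ag(a)
  m <- a$v > 0
  agOp(a$v * m, list(a), function(g) list(g * m))
}

agSilu <- function(a) {
  a <- as_ag(a)
  s <- stats::plogis(a$v)
  v <- a$v * s
  agOp(v, list(a), function(g) list(g * (s * (1 + a$v * (1 - s)))))
}

agSigmoid <- function(a) {
  a <- as_ag(a)
  s <- stats::plogis(a$v)
  agOp(s, list(a), function(g) list(g * s * (1 - s)))
}

agTanh <- function(a) {
  a <- as_ag(a)
  t <- tanh(a$v)
  agOp(t, list(a), function(g) list(g * (1 - t * t)))
}

agPmin <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  td <- bc_dims(a$v, b$v)
  av <- bc_to(a$v, td); bv <- bc_to(b$v, td)
  m <- av <= bv
  agOp(pmin(av, bv), list(a, b), function(g) {
    list(bc_reduce(g * m, dim(a$v)), bc_reduce(g * !m, dim(b$v)))
  })
}

agPmax <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  td <- bc_dims(a$v, b$v)
  av <- bc_to(a$v, td); bv <- bc_to(b$v, td)
  m <- av >= bv
  agOp(pmax(av, bv), list(a, b), function(g) {
    list(bc_reduce(g * m, dim(a$v)), bc_reduce(g * !m, dim(b$v)))
  })
}

agSum <- function(a) {
  a <- as_ag(a)
  agOp(array(sum(a$v), 1L), list(a), function(g) list(array(as.numeric(g), dim(a$v))))
}

agMean <- function(a) {
  a <- as_ag(a)
  n <- length(a$v)
  agOp(array(mean(a$v), 1L), list(a), function(g) list(array(as.numeric(g) / n, dim(a$v))))
}

agReshape <- function(a, dims) {
  a <- as_ag(a)
  d0 <- dim(a$v)
  v <- a$v
  dim(v) <- dims
  agOp(v, list(a), function(g) {
    dim(g) <- d0
    list(g)
  })
}

agPermute <- function(a, perm) {
  a <- as_ag(a)
  agOp(aperm(a$v, perm), list(a), function(g) list(aperm(g, order(perm))))
}

# cyclic roll along spatial dims of a (C,H,W,N) tensor
agRoll <- function(a, sy, sx) {
  a <- as_ag(a)
  d <- dim(a$v)
  H <- d[2]; W <- d[3]
  iy <- ((seq_len(H) - 1L - sy) %% H) + 1L # y_out <- y_in rolled by +sy
  ix <- ((seq_len(W) - 1L - sx) %% W) + 1L
  v <- a$v[, iy, ix, , drop = FALSE]
  agOp(v, list(a), function(g) {
    ry <- ((seq_len(H) - 1L + sy) %% H) + 1L
    rx <- ((seq_len(W) - 1L + sx) %% W) + 1L
    list(g[, ry, rx, , drop = FALSE])
  })
}

# gather columns of a (K, M) matrix view; idx may not contain duplicates
agGatherCols <- function(a, idx) {
  a <- as_ag(a)
  d0 <- dim(a$v)
  K <- d0[1]
  m <- a$v
  dim(m) <- c(K, length(m) / K)
  v <- m[, idx, drop = FALSE]
  agOp(v, list(a), function(g) {
    dm <- matrix(0, K, prod(d0) / K)
    for (j in seq_along(idx)) dm[, idx[j]] <- dm[, idx[j]] + g[, j]
    dim(dm) <- d0
    list(dm)
  })
}

agConcatC <- function(xs) {
  xs <- lapply(xs, as_ag)
  ds <- lapply(xs, function(x) dim(x$v))
  Cs <- vapply(ds, function(d) d[1], 1)
  d1 <- ds[[1]]
  v <- array(0, c(sum(Cs), d1[2], d1[3], d1[4]))
  off <- 0L
  for (i in seq_along(xs)) {
    v[off + seq_len(Cs[i]), , , ] <- xs[[i]]$v
    off <- off + Cs[i]
  }
  agOp(v, xs, function(g) {
    out <- vector("list", length(xs))
    off <- 0L
    for (i in seq_along(xs)) {
      out[[i]] <- g[off + seq_len(Cs[i]), , , , drop = FALSE]
      off <- off + Cs[i]
    }
    out
  })
}
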