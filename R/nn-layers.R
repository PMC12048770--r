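# Layer constructors. A model is assembled inside a "ctx" (parameter
# registry environment); each constructor registers its parameters under a
# dotted path whose first component names the transfer-learning partition
# (backbone / neck / head) and returns a forward closure.

new_ctx <- function() {
  e <- new.env(parent = emptyenv())
  e$params <- list()
  e$states <- list()
  e
}

ctx_param <- function(ctx, name, v) {
  p <- agParam(v, name)
  ctx$params[[name]] <- p
  p
}

ctx_state <- function(ctx, name, C) {
  s <- new.env(parent = emptyenv())
  s$running_mean <- numeric(C)
  s$running_var <- rep(1, C)
  ctx$states[[name]] <- s
  s
}

he_init <- function(fan_in, n) stats::rnorm(n, 0, sqrt(2 / fan_in))

#' Convolution + batch norm + SiLU block
#' @keywords internal
nnConvBnAct <- function(ctx, name, cin, cout, k = 3L, stride = 1L,
                        act = c("silu", "relu", "none")) {
  act <- match.arg(act)
  w <- ctx_param(ctx, paste0(name, ".w"),
                 matrix(he_init(cin * k * k, cout * cin * k * k), cout, cin * k * k))
  g <- ctx_param(ctx, paste0(name, ".bn.gamma"), rep(1, cout))
  b <- ctx_param(ctx, paste0(name, ".bn.beta"), rep(0, cout))
  st <- ctx_state(ctx, paste0(name, ".bn"), cout)
  function(x, train = FALSE) {
    y <- agConv2d(x, w, NULL, k = k, stride = stride)
    y <- agBatchNorm(y, g, b, st, training = train)
    switch(act, silu = agSilu(y), relu = agRelu(y), none = y)
  }
}

#' Plain convolution with bias (used by prediction layers)
#' @keywords internal
nnConv <- function(ctx, name, cin, cout, k = 1L, stride = 1L,
                   bias_init = 0, zero_init = FALSE) {
  wv <- if (zero_init) matrix(0, cout, cin * k * k) else
    matrix(he_init(cin * k * k, cout * cin * k * k), cout, cin * k * k)
  w <- ctx_param(ctx, paste0(name, ".w"), wv)
  b <- ctx_param(ctx, paste0(name, ".b"), rep(bias_init, cout))
  function(x, train = FALSE) agConv2d(x, w, b, k = k, stride = stride)
}

#' Depthwise conv with bias
#' @keywords internal
nnDwConv <- function(ctx, name, c, k = 3L, zero_init = FALSE) {
  wv <- if (zero_init) matrix(0, k * k, c) else
    matrix(he_init(k * k, k * k * c), k * k, c)
  w <- ctx_param(ctx, paste0(name, ".w"), wv)
  b <- ctx_param(ctx, paste0(name, ".b"), rep(0, c))
  function(x, train = FALSE) agDwConv2d(x, w, b, k = k)
}

#' Linear layer on token matrices
#' @keywords internal
nnLinear <- function(ctx, name, din, dout, bias = TRUE, zero_init = FALSE) {
  wv <- if (zero_init) matrix(0, dout, din) else
    matrix(stats::rnorm(dout * din, 0, sqrt(1 / din)), dout, din)
  w <- ctx_param(ctx, paste0(name, ".w"), wv)
  b <- if (bias) ctx_param(ctx, paste0(name, ".b"), rep(0, dout)) else NULL
  function(x, train = FALSE) agLinear(x, w, b)
}

#' Layer norm over feature rows
#' @keywords internal
nnLayerNorm <- function(ctx, name, d) {
  g <- ctx_param(ctx, paste0(name, ".gamma"), rep(1, d))
  b <- ctx_param(ctx, paste0(name, ".beta"), rep(0, d))
  function(x, train = FALSE) agLayerNorm(x, g, b)
}

#' CSP-style bottleneck block: split, transform half, merge
#' @keywords internal
nnCspBlock <- function(ctx, name, c, n = 1L) {
  ch <- max(c %/% 2L, 1L)
  cv1 <- nnConvBnAct(ctx, paste0(name, ".cv1"), c, ch, k = 1L)
  cv2 <- nnConvBnAct(ctx, paste0(name, ".cv2"), c, ch, k = 1L)
  ms <- lapply(seq_len(n), function(i) {
    list(
      a = nnConvBnAct(ctx, paste0(name, ".m", i, ".a"), ch, ch, k = 3L),
      b = nnConvBnAct(ctx, paste0(name, ".m", i, ".b"), ch, ch, k = 3L)
    )
  })
  cv3 <- nnConvBnAct(ctx, paste0(name, ".cv3"), 2L * ch, c, k = 1L)
  function(x, train = FALSE) {
    y1 <- cv1(x, train)
    y2 <- cv2(x, train)
    for (m in ms) {
      y1 <- agAdd(m$b(m$a(y1, train), train), y1)
    }
    cv3(agConcatC(list(y1, y2)), train)
  }
}

# ---- parameter utilities -------------------------------------------------

#' Count trainable parameters of a model
#'
#' Exact summation of the lengths of every trainable array.
#'
#' @param model a model as returned by [buildModel()] (or any object with a
#'   `$params` named list of parameter tensors).
#' @return integer-valued numeric count.
#' @export
countParameters <- function(model) {
  sum(vapply(model$params, function(p) length(p$v), 1))
}

#' Count multiply-accumulate operations of a model forward pass
#'
#' Runs one forward pass at the given input size with an operation-level
#' MAC counter active; convolutions, linear maps and attention products
#' report their analytic MAC counts.
#'
#' @param model a model as returned by [buildModel()].
#' @param input_size spatial input size in pixels (square input).
#' @return numeric MAC count (multiply-accumulates; 1 GFLOP-MAC = 1e9).
#' @export
countFlops <- function(model, input_size = 640L) {
  ctr <- new.env(parent = emptyenv())
  ctr$total <- 0
  old <- .ag$macs
  .ag$macs <- ctr
  on.exit(.ag$macs <- old)
  x <- array(0, c(3L, input_size, input_size, 1L))
  agNoGrad(model$forward(x, train = FALSE))
  ctr$total
}

param_names <- function(model) names(model$params)

get_param_values <- function(model) lapply(model$params, function(p) p$v)

set_param_values <- function(model, values) {
  stopifnot(all(names(values) %in% names(model$params)))
  for (nm in names(values)) {
    p <- model$params[[nm]]
    stopifnot(identical(dim(p$v), dim(values[[nm]])) ||
                length(p$v) == length(values[[nm]]))
    v <- values[[nm]]
    if (is.null(dim(v))) dim(v) <- dim(p$v)
    p$v <- v
  }
  invisible(model)
}
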