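# Shared numeric helpers: stable softmax, batch normalization with the standard
# train/eval split, an offset-based "valid" convolution, and Adam.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Row-wise softmax with max-subtraction
#'
#' @param m numeric matrix.
#' @return matrix of the same shape whose rows are nonnegative and sum to 1.
#' @keywords internal
softmax_rows <- function(m) {
  m <- m - apply(m, 1L, max)
  e <- exp(m)
  e / rowSums(e)
}

## ---- batch normalization -------------------------------------------------
## X is (batch x D). Training mode uses biased batch moments; eval mode is the
## deterministic affine map through the running moments.

bn_forward_train <- function(X, gamma, beta, eps = 1e-5) {
  mu <- colMeans(X)
  xc <- sweep(X, 2L, mu)
  v <- colMeans(xc * xc)
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2L, istd, "*")
  Y <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  list(Y = Y, xhat = xhat, istd = istd, mu = mu, var = v)
}

bn_forward_eval <- function(X, gamma, beta, run_mean, run_var, eps = 1e-5) {
  xhat <- sweep(sweep(X, 2L, run_mean), 2L, sqrt(run_var + eps), "/")
  sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
}

bn_backward <- function(dY, cache, gamma) {
  B <- nrow(dY)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2L, gamma, "*")
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  dX <- sweep(
    dxhat - rep(s1 / B, each = B) - cache$xhat * rep(s2 / B, each = B),
    2L, cache$istd, "*"
  )
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

## running-moment update, momentum as in the usual BN convention
bn_update_running <- function(state, prefix, cache, momentum = 0.1) {
  state[[paste0(prefix, "_mean")]] <-
    (1 - momentum) * state[[paste0(prefix, "_mean")]] + momentum * cache$mu
  state[[paste0(prefix, "_var")]] <-
    (1 - momentum) * state[[paste0(prefix, "_var")]] + momentum * cache$var
  state
}

## ---- convolution ----------------------------------------------------------
## Images are stored as (channels x pixels) matrices in column-major pixel
## order. A "valid" strided convolution is computed as a sum over the k*k
## kernel offsets of small matrix products; the index map for each offset is
## precomputed once per image geometry.

conv_index <- function(H0, W0, k, stride) {
  oh <- (H0 - k) %/% stride + 1L
  ow <- (W0 - k) %/% stride + 1L
  r0 <- seq.int(1L, by = stride, length.out = oh)
  c0 <- seq.int(1L, by = stride, length.out = ow)
  idx <- vector("list", k * k)
  o <- 0L
  for (dx in 0:(k - 1L)) {
    for (dy in 0:(k - 1L)) {
      o <- o + 1L
      idx[[o]] <- as.integer(outer(r0 + dy, (c0 + dx - 1L) * H0, "+"))
    }
  }
  list(idx = idx, oh = oh, ow = ow, P = oh * ow, k = k, stride = stride)
}

## W: array (Cout, Cin, k*k); X: (Cin x P0); returns (Cout x P)
conv_forward <- function(X, W, b, im) {
  Cout <- dim(W)[1L]
  Y <- matrix(b, Cout, im$P)
  for (o in seq_along(im$idx)) {
    Y <- Y + matrix(W[, , o], Cout) %*% X[, im$idx[[o]], drop = FALSE]
  }
  Y
}

conv_backward <- function(dY, X, W, im) {
  Cout <- dim(W)[1L]
  dX <- matrix(0, nrow(X), ncol(X))
  dW <- array(0, dim(W))
  for (o in seq_along(im$idx)) {
    Xo <- X[, im$idx[[o]], drop = FALSE]
    dW[, , o] <- dY %*% t(Xo)
    dX[, im$idx[[o]]] <- dX[, im$idx[[o]]] +
      crossprod(matrix(W[, , o], Cout), dY)
  }
  list(dX = dX, dW = dW, db = rowSums(dY))
}

## ---- Adam -----------------------------------------------------------------

adam_init <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

adam_step <- function(params, grads, opt, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    step <- lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
    if (!is.null(dim(g)) && is.null(dim(step))) dim(step) <- dim(g)
    params[[nm]] <- params[[nm]] - step
  }
  list(params = params, opt = opt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## deterministic sub-seed derivation, kept inside 32-bit integer range
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset) %% 2147483629)
}
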