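# View-level encoding: a pluggable convolutional backbone produces a raw
# feature map F (C x H x W) per view; learned generalized-mean (GeM) pooling
# reduces each channel to a scalar, and batch normalization maps the pooled
# descriptors to a unified space.

#' Generalized-mean (GeM) pooling of a feature map
#'
#' Each channel c is reduced to the power mean
#' `f_c = (mean(x^p_c))^(1/p_c)` over its spatial positions. `p = 1`
#' reproduces average pooling and `p -> Inf` approaches max pooling. Entries
#' are clamped at a small epsilon before the fractional power, and the mean is
#' computed in a max-factored form so arbitrarily large `p` stays finite.
#'
#' @param F feature map: 3-d array `C x H x W`, or a `C x P` matrix of
#'   flattened channels. All entries must be nonnegative (post-activation).
#' @param p pooling exponent(s) > 0: a scalar shared across channels or a
#'   length-C vector.
#' @param clamp_eps lower clamp applied before the power.
#' @return numeric vector of length C.
#' @examples
#' F <- array(abs(rnorm(4 * 5 * 5)), c(4, 5, 5))
#' all.equal(gem_pool(F, p = 1), apply(F, 1, mean))
#' @export
gem_pool <- function(F, p = 3, clamp_eps = 1e-6) {
  Fm <- as_channel_matrix(F)
  if (any(Fm < 0)) stop("gem_pool requires nonnegative feature entries")
  if (any(p <= 0)) stop("GeM exponent p must be > 0")
  if (!(length(p) %in% c(1L, nrow(Fm)))) {
    stop("p must be a scalar or one value per channel")
  }
  u <- pmax(Fm, clamp_eps)
  m <- apply(u, 1L, max)
  tt <- u / m                       # in (0, 1]; exact for p = 1
  z <- tt^p                         # p recycles down columns (per channel)
  mz <- rowMeans(z)
  as.numeric(m * mz^(1 / p))
}

as_channel_matrix <- function(F) {
  if (is.matrix(F)) return(F)
  if (is.array(F) && length(dim(F)) == 3L) {
    d <- dim(F)
    return(matrix(F, d[1L], d[2L] * d[3L]))
  }
  if (is.numeric(F)) return(matrix(F, 1L))
  stop("feature map must be a C x H x W array or C x P matrix")
}

#' Normalize pooled view descriptors
#'
#' Batch normalization over descriptor rows. In training mode the batch
#' moments standardize each dimension (learned scale/shift applied); in eval
#' mode the map is the deterministic affine transform through frozen running
#' moments.
#'
#' @param X `N x C` matrix of descriptors (rows = views).
#' @param gamma,beta learned scale and shift (length C; defaults identity).
#' @param run_mean,run_var frozen running moments for eval mode.
#' @param training logical; use batch moments (requires `N >= 1`).
#' @param eps variance stabilizer.
#' @return normalized `N x C` matrix.
#' @export
normalize_descriptors <- function(X, gamma = NULL, beta = NULL,
                                  run_mean = NULL, run_var = NULL,
                                  training = is.null(run_mean), eps = 1e-5) {
  X <- as.matrix(X)
  C <- ncol(X)
  gamma <- gamma %||% rep(1, C)
  beta <- beta %||% rep(0, C)
  if (training) {
    bn_forward_train(X, gamma, beta, eps)$Y
  } else {
    bn_forward_eval(X, gamma, beta, run_mean %||% rep(0, C),
                    run_var %||% rep(1, C), eps)
  }
}

## ---- tiny convolutional backbone ------------------------------------------
## The backbone is a contract: any deterministic map from a view image to a
## C x H x W nonnegative feature map fits. The package ships a small
## two-convolution extractor (3x3 kernels, stride 2, ReLU) whose weights are
## trained jointly with the rest of the network; channel widths are
## configurable.

init_backbone_params <- function(channels = c(8L, 16L), in_channels = 1L,
                                 k = 3L) {
  c1 <- channels[1L]; c2 <- channels[2L]
  list(
    conv1_W = array(stats::rnorm(c1 * in_channels * k * k,
                                 sd = sqrt(2 / (in_channels * k * k))),
                    c(c1, in_channels, k * k)),
    conv1_b = rep(0, c1),
    conv2_W = array(stats::rnorm(c2 * c1 * k * k, sd = sqrt(2 / (c1 * k * k))),
                    c(c2, c1, k * k)),
    conv2_b = rep(0, c2)
  )
}

## forward through the two-conv backbone; X0 is (in_channels x P0)
backbone_forward <- function(X0, params, ims, cache = FALSE) {
  Z1 <- conv_forward(X0, params$conv1_W, params$conv1_b, ims$im1)
  H1 <- pmax(Z1, 0)
  Z2 <- conv_forward(H1, params$conv2_W, params$conv2_b, ims$im2)
  F <- pmax(Z2, 0)
  if (cache) list(F = F, H1 = H1, X0 = X0) else F
}

#' Encode a view stack into feature maps and pooled descriptors
#'
#' Runs every view through one shared backbone, applies GeM pooling and
#' (optionally) descriptor normalization. Intended for inspection and for the
#' desk-scale eval path; training uses the same computations internally.
#'
#' @param stack a `"view_stack"` (all views the same size).
#' @param model a fitted [mwfnet()] object, or `NULL` to use a freshly
#'   initialized backbone (seeded via `seed`).
#' @param seed seed for the fresh-backbone case.
#' @return list with `F` (list of `C x P` feature-map matrices, one per view)
#'   and `X` (`N x C` matrix of normalized pooled descriptors).
#' @export
encode_views <- function(stack, model = NULL, seed = 1L) {
  stopifnot(inherits(stack, "view_stack"))
  sizes <- vapply(stack$views, function(v) ncol(v), 0L)
  if (length(unique(sizes)) != 1L) stop("views must share one image size")
  if (is.null(model)) {
    H0 <- nrow(stack$views[[1L]])
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    params <- init_backbone_params()
    ims <- backbone_geometry(H0, H0)
    p <- 3
    bn <- NULL
  } else {
    params <- model$params
    ims <- model$dims$ims
    p <- model$params$gem_p
    bn <- list(gamma = model$params$bn1_gamma, beta = model$params$bn1_beta,
               mean = model$state$bn1_mean, var = model$state$bn1_var)
  }
  Fs <- lapply(stack$views, function(v) {
    backbone_forward(matrix(as.numeric(v), 1L), params, ims)
  })
  X <- do.call(rbind, lapply(Fs, function(F) gem_pool(F, p)))
  if (!is.null(bn)) {
    X <- normalize_descriptors(X, bn$gamma, bn$beta, bn$mean, bn$var,
                               training = FALSE)
  }
  list(F = Fs, X = X)
}

backbone_geometry <- function(H0, W0, k = 3L, stride = 2L) {
  im1 <- conv_index(H0, W0, k, stride)
  im2 <- conv_index(im1$oh, im1$ow, k, stride)
  list(im1 = im1, im2 = im2)
}
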