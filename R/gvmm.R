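# Gated View Measurement Module (GVMM): a per-view discriminability score in
# (0, 1) computed from the salient regions of the raw feature map. The map is
# normalized to [0, 1], entries below a threshold T1 are masked to zero, and a
# small learned head (1x1 convolution halving the channels, flatten, batch
# normalization, fully connected layer to a scalar s) is squashed through
# d = sigmoid(log(|s| + eps)). The absolute value and logarithm keep the
# sigmoid input away from its saturated range.

#' Mask the salient regions of a feature map
#'
#' Normalizes the map to [0, 1] (min-max, over the whole view by default or
#' per channel) and zeroes every entry strictly below `t1`; entries equal to
#' the threshold are kept.
#'
#' @param F feature map (`C x H x W` array or `C x P` matrix).
#' @param t1 salience threshold in [0, 1].
#' @param norm `"per_view"` (one min/max for the whole map) or
#'   `"per_channel"`.
#' @return masked normalized map, same shape class as the input (matrix form).
#' @export
mask_salient <- function(F, t1 = 0.9, norm = c("per_view", "per_channel")) {
  norm <- match.arg(norm)
  if (t1 < 0 || t1 > 1) stop("t1 must lie in [0, 1]")
  Fm <- as_channel_matrix(F)
  nrm <- normalize_feature_map(Fm, norm)
  Fn <- nrm$Fn
  Fn * (Fn >= t1)
}

## exact min-max normalization to [0, 1]; a flat map (zero range) maps to all
## zeros. The denominator is kept exact so threshold boundaries (F == T1 after
## normalization) behave bit-exactly.
normalize_feature_map <- function(Fm, norm = "per_view") {
  if (norm == "per_view") {
    mn <- min(Fm); mx <- max(Fm)
    den <- mx - mn
    if (den <= 0) den <- 1
  } else {
    mn <- apply(Fm, 1L, min); mx <- apply(Fm, 1L, max)
    den <- mx - mn
    den[den <= 0] <- 1
  }
  list(Fn = (Fm - mn) / den, mn = mn, mx = mx, den = den)
}

#' Discriminability gate applied to a scalar head response
#'
#' `d = sigmoid(log(|s| + eps))`, equal to `(|s|+eps) / (1 + |s| + eps)`.
#' Symmetric in the sign of `s`, strictly inside (0, 1), and unsaturated for
#' `|s|` within several orders of magnitude of 1.
#'
#' @param s numeric vector of head outputs.
#' @param eps stabilizer defining the score at `s = 0`; kept tiny so the
#'   closed forms (`d = 0.5` at `|s| = 1`) hold to well below 1e-9.
#' @return numeric vector of scores in (0, 1).
#' @examples
#' gate_score(1)        # 0.5
#' gate_score(exp(1))   # sigmoid(1)
#' @export
gate_score <- function(s, eps = 1e-12) {
  a <- abs(s) + eps
  a / (1 + a)
}

## head parameter initialization; C must be even, P = spatial positions
init_gvmm_params <- function(C, P) {
  stopifnot(C %% 2L == 0L)
  Ch <- C %/% 2L
  Dg <- Ch * P
  list(
    gvmm_W = matrix(stats::rnorm(Ch * C, sd = sqrt(2 / C)), Ch, C),
    gvmm_b = rep(0, Ch),
    gvmm_bn_gamma = rep(1, Dg),
    gvmm_bn_beta = rep(0, Dg),
    gvmm_fc_w = stats::rnorm(Dg, sd = sqrt(1 / Dg)),
    gvmm_fc_b = 0
  )
}

#' Score one masked feature map
#'
#' Applies the GVMM head in eval mode: 1x1 convolution `C -> C/2`, flatten,
#' batch normalization through the head's (frozen) running moments, fully
#' connected layer to a scalar, then [gate_score()].
#'
#' @param Fp masked feature map (`C x P` matrix or `C x H x W` array).
#' @param head list with `W` (`C/2 x C`), `b`, `bn_gamma`, `bn_beta`,
#'   `bn_mean`, `bn_var`, `fc_w`, `fc_b`.
#' @return scalar discriminability score in (0, 1).
#' @export
score_view <- function(Fp, head) {
  Fp <- as_channel_matrix(Fp)
  G <- head$W %*% Fp + head$b
  g <- as.numeric(G)
  Dg <- length(g)
  gb <- as.numeric(bn_forward_eval(matrix(g, 1L), head$bn_gamma, head$bn_beta,
                                   head$bn_mean %||% rep(0, Dg),
                                   head$bn_var %||% rep(1, Dg)))
  s <- sum(gb * head$fc_w) + head$fc_b
  gate_score(s)
}

#' Discriminability scores for a set of views
#'
#' Masks each raw feature map at `t1` and scores it with one shared head.
#'
#' @param Fs list of raw feature maps (one per view).
#' @param t1 salience threshold.
#' @param head shared head parameters, as in [score_view()]; `NULL` draws a
#'   seeded random head matching the first map (useful for inspection).
#' @param norm normalization mode for [mask_salient()].
#' @param seed seed for the random-head case.
#' @return numeric vector of length N with entries in (0, 1).
#' @export
measure_views <- function(Fs, t1 = 0.9, head = NULL,
                          norm = c("per_view", "per_channel"), seed = 1L) {
  norm <- match.arg(norm)
  stopifnot(length(Fs) >= 1L)
  Fmats <- lapply(Fs, as_channel_matrix)
  if (is.null(head)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    p <- init_gvmm_params(nrow(Fmats[[1L]]), ncol(Fmats[[1L]]))
    head <- list(W = p$gvmm_W, b = p$gvmm_b,
                 bn_gamma = p$gvmm_bn_gamma, bn_beta = p$gvmm_bn_beta,
                 fc_w = p$gvmm_fc_w, fc_b = p$gvmm_fc_b)
  }
  vapply(Fmats, function(F) score_view(mask_salient(F, t1, norm), head), 0)
}
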