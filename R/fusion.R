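# Weighted-view fusion: the instance-level descriptor is the
# discriminability-weighted sum of enhanced view descriptors,
# X_t = D X' (1xN times NxC), optionally with a residual connection from the
# mean of the raw descriptors and a batch-normalization step, followed by a
# small fully connected classifier.

#' Fuse enhanced view descriptors into an instance descriptor
#'
#' `X_t = sum_n d_n x'_n`, optionally plus the mean of the raw view
#' descriptors as a residual connection. Normalization (the residual batch
#' normalization of the full network) is applied by the model, not here.
#'
#' @param D numeric vector of view weights (length N): discriminability
#'   scores, or a manual weight assignment.
#' @param Xp `N x C` matrix of enhanced view descriptors.
#' @param X optional `N x C` matrix of raw descriptors for the residual term.
#' @param residual logical; add `colMeans(X)`.
#' @return numeric vector of length C.
#' @examples
#' fuse_descriptors(c(0.5, 0.5), rbind(c(2, 0), c(0, 2)))  # c(1, 1)
#' @export
fuse_descriptors <- function(D, Xp, X = NULL, residual = FALSE) {
  Xp <- as.matrix(Xp)
  if (length(D) != nrow(Xp)) stop("length(D) must equal nrow(Xp)")
  xt <- as.numeric(crossprod(Xp, D))
  if (residual) {
    if (is.null(X)) stop("residual fusion needs the raw descriptors X")
    xt <- xt + colMeans(as.matrix(X))
  }
  xt
}

## classifier parameter initialization: C -> hidden -> hidden -> K
init_classifier_params <- function(C, K, hidden = 200L) {
  list(
    cls_W1 = matrix(stats::rnorm(C * hidden, sd = sqrt(2 / C)), C, hidden),
    cls_b1 = rep(0, hidden),
    cls_W2 = matrix(stats::rnorm(hidden * hidden, sd = sqrt(2 / hidden)),
                    hidden, hidden),
    cls_b2 = rep(0, hidden),
    cls_Wo = matrix(stats::rnorm(hidden * K, sd = sqrt(1 / hidden)), hidden, K),
    cls_bo = rep(0, K)
  )
}

## forward through the classifier; Xt is (B x C); returns probs and caches
classifier_forward <- function(Xt, params) {
  Hc1 <- pmax(sweep(Xt %*% params$cls_W1, 2L, params$cls_b1, "+"), 0)
  Hc2 <- pmax(sweep(Hc1 %*% params$cls_W2, 2L, params$cls_b2, "+"), 0)
  logits <- sweep(Hc2 %*% params$cls_Wo, 2L, params$cls_bo, "+")
  list(prob = softmax_rows(logits), Hc1 = Hc1, Hc2 = Hc2)
}
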