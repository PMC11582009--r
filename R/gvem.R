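# Gated View Enhancement Module (GVEM): pairwise view-similarity attention
# with a threshold gate. Three transform layers L1-L3 (1x1 convolution C -> C
# plus normalization) map view descriptors to a common space; the similarity
# matrix A is a row softmax of exponentiated dot products; a threshold T2
# partitions A into a high-similarity mask M1 and its complement M2; the
# modified matrix A' down-weights redundant (highly similar) view pairs and
# amplifies dissimilar ones; the enhanced descriptors are X' = A' L3(X).

#' Pairwise view-similarity matrix
#'
#' `a_ij = softmax_j( L1(x_i) . L2(x_j) )`: dot products of transformed
#' descriptors, exponentiated and normalized over the source views j (with
#' max-subtraction for overflow safety; the result is unchanged
#' mathematically).
#'
#' @param X `N x C` matrix of view descriptors (N >= 2).
#' @param L1,L2 transform layers: functions mapping an `N x C` matrix to an
#'   `N x C` matrix (default identity).
#' @return `N x N` row-stochastic matrix with entries in [0, 1].
#' @export
pairwise_similarity <- function(X, L1 = identity, L2 = identity) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("pairwise similarity needs at least 2 views")
  H1 <- L1(X)
  H2 <- L2(X)
  softmax_rows(H1 %*% t(H2))
}

#' Threshold gate masks over a similarity matrix
#'
#' `M1 = I(A >= T2)` selects the highly similar (redundant) pairs, `M2` its
#' exact complement; the boundary `a_ij = T2` belongs to `M1`.
#'
#' @param A similarity matrix.
#' @param t2 gate threshold in [0, 1].
#' @return list with binary matrices `M1`, `M2` (`M1 + M2` is all ones).
#' @export
gate_masks <- function(A, t2 = 0.8) {
  if (t2 < 0 || t2 > 1) stop("t2 must lie in [0, 1]")
  M1 <- (A >= t2) * 1L
  list(M1 = M1, M2 = 1L - M1)
}

#' Gated modification of the similarity matrix
#'
#' Pre-softmax values are `exp(-a_ij)` where `M1` holds (suppressing
#' high-similarity pairs) and `exp(a_ij)` where `M2` holds (amplifying
#' low-similarity pairs); a row softmax then renormalizes. The
#' `"as_printed"` variant evaluates the literal composite
#' `1/exp(A o M1) + exp(A o M2)`, in which masked-off entries contribute
#' `exp(0) = 1` to the opposite branch.
#'
#' @param A row-stochastic similarity matrix.
#' @param masks gate masks from [gate_masks()].
#' @param variant `"two_branch"` (default) or `"as_printed"`.
#' @return `N x N` row-stochastic matrix with strictly positive entries.
#' @export
modify_similarity <- function(A, masks, variant = c("two_branch", "as_printed")) {
  variant <- match.arg(variant)
  M1 <- masks$M1
  if (!all(M1 + masks$M2 == 1)) stop("masks must partition (M1 + M2 = 1)")
  B <- if (variant == "two_branch") {
    ifelse(M1 == 1, exp(-A), exp(A))
  } else {
    exp(-A * M1) + exp(A * masks$M2)
  }
  softmax_rows(B)
}

#' Enhance view descriptors through the gated similarity matrix
#'
#' `X' = A' L3(X)`: each enhanced descriptor is the A'-weighted mixture of
#' the transformed descriptors of all views.
#'
#' @param X `N x C` matrix of view descriptors.
#' @param A_prime modified similarity matrix (`N x N`).
#' @param L3 transform layer (function `N x C -> N x C`, default identity).
#' @return `N x C` matrix of enhanced descriptors.
#' @export
enhance_descriptors <- function(X, A_prime, L3 = identity) {
  X <- as.matrix(X)
  A_prime <- as.matrix(A_prime)
  H3 <- L3(X)
  if (ncol(A_prime) != nrow(H3)) stop("shape mismatch between A' and L3(X)")
  A_prime %*% H3
}

## transform-layer parameter initialization (three layers l1, l2, l3)
init_gvem_params <- function(C) {
  out <- list()
  for (nm in c("l1", "l2", "l3")) {
    out[[paste0(nm, "_W")]] <- matrix(stats::rnorm(C * C, sd = sqrt(1 / C)), C, C)
    out[[paste0(nm, "_b")]] <- rep(0, C)
    out[[paste0(nm, "_bn_gamma")]] <- rep(1, C)
    out[[paste0(nm, "_bn_beta")]] <- rep(0, C)
  }
  out
}

#' Trainable-parameter count of the view enhancement module
#'
#' Three 1x1 `C -> C` transform layers, each a convolution with bias plus a
#' normalization layer with per-channel scale and shift:
#' `3 * (C^2 + C + 2C)` parameters.
#'
#' @param C channel dimension of the view descriptors.
#' @param instantiate logical; actually allocate the parameter arrays and
#'   count their elements instead of using the closed form.
#' @return integer parameter count.
#' @examples
#' gvem_parameter_count(2048) / 1e6   # ~12.6 M
#' @export
gvem_parameter_count <- function(C, instantiate = FALSE) {
  if (instantiate) {
    sum(vapply(init_gvem_params(C), length, 0L))
  } else {
    3L * (C * C + 3L * C)
  }
}
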