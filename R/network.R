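# Full network engine: parameter initialization, training-mode forward pass
# with caches, exact backward pass (validated against central finite
# differences in the test suite), eval-mode forward pass, and the Adam
# training loop. Views share one backbone; the gating modules and classifier
# operate on the pooled, batch-normalized descriptors.

#' Model and training configuration
#'
#' Defaults mirror the reference training setup of the method: 8 views
#' (phi = 45 degrees), 224-pixel views, GeM exponent initialized to 3,
#' salience threshold `t1 = 0.9`, similarity gate `t2 = 0.8`, batch size 16,
#' Adam with learning rate 0.001, 10-fold cross-validation. The backbone is a
#' contract: the packaged default is a small two-convolution extractor
#' (3x3 kernels, stride 2, ReLU) with configurable channel widths, trained
#' jointly with the rest of the network.
#'
#' @param phi_deg,image_size,margin_frac,line_thickness_px projection
#'   settings, see [projection_config()].
#' @param backbone_channels integer 2-vector: channels of the two
#'   convolutions; the second is the descriptor dimension C (must be even).
#' @param gem_p_init initial GeM exponent.
#' @param gem_per_channel logical; learn one exponent per channel.
#' @param gvmm,gvem logical module toggles (both off reproduces the plain
#'   weighted-sum baseline with unit weights and identity enhancement).
#' @param t1 GVMM salience threshold in [0, 1].
#' @param gvmm_norm feature-map normalization before `t1` masking.
#' @param t2 GVEM similarity gate threshold in [0, 1].
#' @param eq6 algebraic variant of the gated similarity modification.
#' @param residual add the mean raw descriptor to the fused descriptor.
#' @param fusion_bn batch-normalize the fused descriptor.
#' @param manual_weights optional fixed view-weight vector (length N),
#'   bypassing the GVMM (manual-assignment ablation).
#' @param hidden width of the two fully connected classifier layers.
#' @param batch_size,lr,epochs optimizer settings (Adam, cross-entropy loss).
#' @param folds default fold count for [mwfnet_cv()].
#' @return list of class `"mwfnet_config"`.
#' @export
mwfnet_config <- function(phi_deg = 45, image_size = 224L, margin_frac = 0.05,
                          line_thickness_px = 1L,
                          backbone_channels = c(8L, 16L),
                          gem_p_init = 3, gem_per_channel = FALSE,
                          gvmm = TRUE, t1 = 0.9,
                          gvmm_norm = c("per_view", "per_channel"),
                          gvem = TRUE, t2 = 0.8,
                          eq6 = c("two_branch", "as_printed"),
                          residual = TRUE, fusion_bn = TRUE,
                          manual_weights = NULL,
                          hidden = 200L,
                          batch_size = 16L, lr = 0.001, epochs = 50L,
                          folds = 10L) {
  if (backbone_channels[2L] %% 2L != 0L) {
    stop("descriptor channel count (backbone_channels[2]) must be even")
  }
  structure(list(
    phi_deg = phi_deg, image_size = as.integer(image_size),
    margin_frac = margin_frac, line_thickness_px = as.integer(line_thickness_px),
    backbone_channels = as.integer(backbone_channels),
    gem_p_init = gem_p_init, gem_per_channel = isTRUE(gem_per_channel),
    gvmm = isTRUE(gvmm), t1 = t1, gvmm_norm = match.arg(gvmm_norm),
    gvem = isTRUE(gvem), t2 = t2, eq6 = match.arg(eq6),
    residual = isTRUE(residual), fusion_bn = isTRUE(fusion_bn),
    manual_weights = manual_weights,
    hidden = as.integer(hidden),
    batch_size = as.integer(batch_size), lr = lr, epochs = as.integer(epochs),
    folds = as.integer(folds)
  ), class = "mwfnet_config")
}

## geometry + parameter/state initialization; call inside set.seed
init_mwfnet <- function(cfg, K, H0) {
  ims <- backbone_geometry(H0, H0)
  C <- cfg$backbone_channels[2L]
  P <- ims$im2$P
  Ch <- C %/% 2L
  Dg <- Ch * P
  N <- as.integer(floor(360 / cfg$phi_deg))
  if (N < 1L) stop("phi_deg yields no views")

  params <- init_backbone_params(cfg$backbone_channels)
  params$gem_p <- if (cfg$gem_per_channel) rep(cfg$gem_p_init, C) else cfg$gem_p_init
  params$bn1_gamma <- rep(1, C)
  params$bn1_beta <- rep(0, C)
  state <- list(bn1_mean = rep(0, C), bn1_var = rep(1, C))

  use_gvmm <- cfg$gvmm && is.null(cfg$manual_weights)
  if (use_gvmm) {
    params <- c(params, init_gvmm_params(C, P))
    state$gvmm_bn_mean <- rep(0, Dg)
    state$gvmm_bn_var <- rep(1, Dg)
  }
  if (cfg$gvem) {
    params <- c(params, init_gvem_params(C))
    for (nm in c("l1", "l2", "l3")) {
      state[[paste0(nm, "_bn_mean")]] <- rep(0, C)
      state[[paste0(nm, "_bn_var")]] <- rep(1, C)
    }
  }
  if (cfg$fusion_bn) {
    params$fuse_bn_gamma <- rep(1, C)
    params$fuse_bn_beta <- rep(0, C)
    state$fuse_bn_mean <- rep(0, C)
    state$fuse_bn_var <- rep(1, C)
  }
  params <- c(params, init_classifier_params(C, K, cfg$hidden))

  list(params = params, state = state,
       dims = list(ims = ims, C = C, P = P, Ch = Ch, Dg = Dg, N = N, K = K,
                   H0 = H0, use_gvmm = use_gvmm))
}

GEM_CLAMP <- 1e-6
GATE_EPS <- 1e-12

## stacked image matrices for one sample
view_input <- function(stack) {
  lapply(stack$views, function(v) matrix(as.numeric(v), 1L))
}

## ---- training-mode forward + backward -------------------------------------
## Returns loss, class probabilities, gradients for every trainable parameter
## and the updated BN running-moment state.
train_batch <- function(params, state, dims, cfg, xs, yint,
                        update_state = TRUE) {
  B <- length(xs)
  N <- dims$N
  C <- dims$C
  P <- dims$P
  BN_ <- B * N
  pgem <- as.numeric(params$gem_p)

  ## backbone + GeM forward
  bb <- vector("list", BN_)
  gemc <- vector("list", BN_)
  Xraw <- matrix(0, BN_, C)
  for (b in seq_len(B)) {
    inp <- view_input(xs[[b]])
    for (k in seq_len(N)) {
      i <- (b - 1L) * N + k
      bb[[i]] <- backbone_forward(inp[[k]], params, dims$ims, cache = TRUE)
      Fm <- bb[[i]]$F
      u <- pmax(Fm, GEM_CLAMP)
      m <- apply(u, 1L, max)
      tt <- u / m
      z <- tt^pgem
      mz <- rowMeans(z)
      gemc[[i]] <- list(tt = tt, z = z, mz = mz, m = m, keep = Fm > GEM_CLAMP)
      Xraw[i, ] <- m * mz^(1 / pgem)
    }
  }

  bn1 <- bn_forward_train(Xraw, params$bn1_gamma, params$bn1_beta)
  X <- bn1$Y

  ## GVMM forward
  if (dims$use_gvmm) {
    Hg <- matrix(0, BN_, dims$Dg)
    gvc <- vector("list", BN_)
    for (i in seq_len(BN_)) {
      nrm <- normalize_feature_map(bb[[i]]$F, cfg$gvmm_norm)
      mask <- nrm$Fn >= cfg$t1
      Fp <- nrm$Fn * mask
      G <- params$gvmm_W %*% Fp + params$gvmm_b
      Hg[i, ] <- as.vector(G)
      gvc[[i]] <- list(Fp = Fp, mask = mask, nrm = nrm)
    }
    bn2 <- bn_forward_train(Hg, params$gvmm_bn_gamma, params$gvmm_bn_beta)
    svec <- as.numeric(bn2$Y %*% params$gvmm_fc_w) + params$gvmm_fc_b
    avec <- abs(svec) + GATE_EPS
    dvec <- avec / (1 + avec)
  } else if (!is.null(cfg$manual_weights)) {
    if (length(cfg$manual_weights) != N) stop("manual_weights must have length N")
    dvec <- rep(cfg$manual_weights, times = B)
  } else {
    dvec <- rep(1, BN_)
  }

  ## GVEM forward
  if (cfg$gvem) {
    H <- list()
    bnl <- list()
    for (nm in c("l1", "l2", "l3")) {
      Pre <- sweep(X %*% params[[paste0(nm, "_W")]], 2L,
                   params[[paste0(nm, "_b")]], "+")
      bnl[[nm]] <- bn_forward_train(Pre, params[[paste0(nm, "_bn_gamma")]],
                                    params[[paste0(nm, "_bn_beta")]])
      H[[nm]] <- bnl[[nm]]$Y
    }
    att <- vector("list", B)
    Xp <- matrix(0, BN_, C)
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * N + 1L):(b * N)
      A <- softmax_rows(H$l1[rows, , drop = FALSE] %*%
                          t(H$l2[rows, , drop = FALSE]))
      M1 <- (A >= cfg$t2) * 1
      Bm <- if (cfg$eq6 == "two_branch") {
        ifelse(M1 == 1, exp(-A), exp(A))
      } else {
        exp(-A * M1) + exp(A * (1 - M1))
      }
      Ap <- softmax_rows(Bm)
      Xp[rows, ] <- Ap %*% H$l3[rows, , drop = FALSE]
      att[[b]] <- list(A = A, M1 = M1, Ap = Ap)
    }
  } else {
    Xp <- X
  }

  ## fusion + classifier forward
  Xt <- matrix(0, B, C)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * N + 1L):(b * N)
    xt <- as.numeric(crossprod(Xp[rows, , drop = FALSE], dvec[rows]))
    if (cfg$residual) xt <- xt + colMeans(X[rows, , drop = FALSE])
    Xt[b, ] <- xt
  }
  if (cfg$fusion_bn) {
    bn3 <- bn_forward_train(Xt, params$fuse_bn_gamma, params$fuse_bn_beta)
    Xtn <- bn3$Y
  } else {
    Xtn <- Xt
  }
  cf <- classifier_forward(Xtn, params)
  prob <- cf$prob
  loss <- -mean(log(prob[cbind(seq_len(B), yint)] + 1e-12))

  ## ---- backward ----
  G <- list()
  Y1 <- matrix(0, B, dims$K)
  Y1[cbind(seq_len(B), yint)] <- 1
  dlogits <- (prob - Y1) / B

  G$cls_Wo <- crossprod(cf$Hc2, dlogits)
  G$cls_bo <- colSums(dlogits)
  dHc2 <- tcrossprod(dlogits, params$cls_Wo) * (cf$Hc2 > 0)
  G$cls_W2 <- crossprod(cf$Hc1, dHc2)
  G$cls_b2 <- colSums(dHc2)
  dHc1 <- tcrossprod(dHc2, params$cls_W2) * (cf$Hc1 > 0)
  G$cls_W1 <- crossprod(Xtn, dHc1)
  G$cls_b1 <- colSums(dHc1)
  dXtn <- tcrossprod(dHc1, params$cls_W1)

  if (cfg$fusion_bn) {
    bb3 <- bn_backward(dXtn, bn3, params$fuse_bn_gamma)
    dXt <- bb3$dX
    G$fuse_bn_gamma <- bb3$dgamma
    G$fuse_bn_beta <- bb3$dbeta
  } else {
    dXt <- dXtn
  }

  dX <- matrix(0, BN_, C)
  dXp <- matrix(0, BN_, C)
  ddvec <- numeric(BN_)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * N + 1L):(b * N)
    dxt <- dXt[b, ]
    ddvec[rows] <- Xp[rows, , drop = FALSE] %*% dxt
    dXp[rows, ] <- outer(dvec[rows], dxt)
    if (cfg$residual) {
      dX[rows, ] <- dX[rows, ] + matrix(dxt / N, N, C, byrow = TRUE)
    }
  }

  if (cfg$gvem) {
    dH <- list(l1 = matrix(0, BN_, C), l2 = matrix(0, BN_, C),
               l3 = matrix(0, BN_, C))
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * N + 1L):(b * N)
      at <- att[[b]]
      dXp_b <- dXp[rows, , drop = FALSE]
      H3b <- H$l3[rows, , drop = FALSE]
      dAp <- tcrossprod(dXp_b, H3b)
      dH$l3[rows, ] <- dH$l3[rows, ] + crossprod(at$Ap, dXp_b)
      dBm <- at$Ap * (dAp - rowSums(dAp * at$Ap))
      dA <- if (cfg$eq6 == "two_branch") {
        dBm * ifelse(at$M1 == 1, -exp(-at$A), exp(at$A))
      } else {
        dBm * (-at$M1 * exp(-at$A * at$M1) +
                 (1 - at$M1) * exp(at$A * (1 - at$M1)))
      }
      dS <- at$A * (dA - rowSums(dA * at$A))
      dH$l1[rows, ] <- dH$l1[rows, ] + dS %*% H$l2[rows, , drop = FALSE]
      dH$l2[rows, ] <- dH$l2[rows, ] + crossprod(dS, H$l1[rows, , drop = FALSE])
    }
    for (nm in c("l1", "l2", "l3")) {
      bbk <- bn_backward(dH[[nm]], bnl[[nm]], params[[paste0(nm, "_bn_gamma")]])
      G[[paste0(nm, "_bn_gamma")]] <- bbk$dgamma
      G[[paste0(nm, "_bn_beta")]] <- bbk$dbeta
      G[[paste0(nm, "_W")]] <- crossprod(X, bbk$dX)
      G[[paste0(nm, "_b")]] <- colSums(bbk$dX)
      dX <- dX + tcrossprod(bbk$dX, params[[paste0(nm, "_W")]])
    }
  } else {
    dX <- dX + dXp
  }

  dF_extra <- vector("list", BN_)
  if (dims$use_gvmm) {
    dsvec <- ddvec * dvec * (1 - dvec) / avec * sign(svec)
    G$gvmm_fc_w <- as.numeric(crossprod(bn2$Y, dsvec))
    G$gvmm_fc_b <- sum(dsvec)
    dHgbn <- outer(dsvec, params$gvmm_fc_w)
    bb2 <- bn_backward(dHgbn, bn2, params$gvmm_bn_gamma)
    G$gvmm_bn_gamma <- bb2$dgamma
    G$gvmm_bn_beta <- bb2$dbeta
    G$gvmm_W <- matrix(0, dims$Ch, C)
    G$gvmm_b <- rep(0, dims$Ch)
    for (i in seq_len(BN_)) {
      dG_i <- matrix(bb2$dX[i, ], dims$Ch, P)
      gv <- gvc[[i]]
      G$gvmm_W <- G$gvmm_W + tcrossprod(dG_i, gv$Fp)
      G$gvmm_b <- G$gvmm_b + rowSums(dG_i)
      dFn <- crossprod(params$gvmm_W, dG_i) * gv$mask
      nrm <- gv$nrm
      if (cfg$gvmm_norm == "per_view") {
        dF_i <- dFn / nrm$den
        if (nrm$mn > 0) {
          imin <- which.min(bb[[i]]$F)
          dF_i[imin] <- dF_i[imin] + sum(dFn * (nrm$Fn - 1)) / nrm$den
        }
        imax <- which.max(bb[[i]]$F)
        dF_i[imax] <- dF_i[imax] - sum(dFn * nrm$Fn) / nrm$den
      } else {
        dF_i <- dFn / nrm$den
        dmn <- rowSums(dFn * (nrm$Fn - 1)) / nrm$den
        dmx <- -rowSums(dFn * nrm$Fn) / nrm$den
        imin <- max.col(-bb[[i]]$F, ties.method = "first")
        imax <- max.col(bb[[i]]$F, ties.method = "first")
        sel <- nrm$mn > 0
        idx <- cbind(seq_len(C), imin)[sel, , drop = FALSE]
        dF_i[idx] <- dF_i[idx] + dmn[sel]
        dF_i[cbind(seq_len(C), imax)] <- dF_i[cbind(seq_len(C), imax)] + dmx
      }
      dF_extra[[i]] <- dF_i
    }
  }

  bbk1 <- bn_backward(dX, bn1, params$bn1_gamma)
  G$bn1_gamma <- bbk1$dgamma
  G$bn1_beta <- bbk1$dbeta
  dXraw <- bbk1$dX

  ## GeM + backbone backward
  G$gem_p <- if (length(pgem) > 1L) rep(0, C) else 0
  G$conv1_W <- array(0, dim(params$conv1_W))
  G$conv1_b <- rep(0, length(params$conv1_b))
  G$conv2_W <- array(0, dim(params$conv2_W))
  G$conv2_b <- rep(0, length(params$conv2_b))
  for (i in seq_len(BN_)) {
    gc_ <- gemc[[i]]
    dx <- dXraw[i, ]
    f <- Xraw[i, ]
    mzfac <- gc_$mz^((1 / pgem) - 1)
    dU <- (dx * mzfac / P) * (gc_$z / gc_$tt)
    dF_i <- dU * gc_$keep
    logt <- log(gc_$tt)
    wzl <- gc_$z * logt
    dfdp <- f * (rowMeans(wzl) / (pgem * gc_$mz) - log(gc_$mz) / pgem^2)
    if (length(pgem) > 1L) {
      G$gem_p <- G$gem_p + dx * dfdp
    } else {
      G$gem_p <- G$gem_p + sum(dx * dfdp)
    }
    if (!is.null(dF_extra[[i]])) dF_i <- dF_i + dF_extra[[i]]

    Fm <- bb[[i]]$F
    dZ2 <- dF_i * (Fm > 0)
    cb2 <- conv_backward(dZ2, bb[[i]]$H1, params$conv2_W, dims$ims$im2)
    G$conv2_W <- G$conv2_W + cb2$dW
    G$conv2_b <- G$conv2_b + cb2$db
    dZ1 <- cb2$dX * (bb[[i]]$H1 > 0)
    cb1 <- conv_backward(dZ1, bb[[i]]$X0, params$conv1_W, dims$ims$im1)
    G$conv1_W <- G$conv1_W + cb1$dW
    G$conv1_b <- G$conv1_b + cb1$db
  }

  if (update_state) {
    state <- bn_update_running(state, "bn1", bn1)
    if (dims$use_gvmm) state <- bn_update_running(state, "gvmm_bn", bn2)
    if (cfg$gvem) {
      for (nm in c("l1", "l2", "l3")) {
        state <- bn_update_running(state, paste0(nm, "_bn"), bnl[[nm]])
      }
    }
    if (cfg$fusion_bn) state <- bn_update_running(state, "fuse_bn", bn3)
  }

  list(loss = loss, prob = prob, grads = G, state = state)
}

## ---- eval-mode forward -----------------------------------------------------
forward_eval <- function(params, state, dims, cfg, xs) {
  B <- length(xs)
  N <- dims$N
  C <- dims$C
  BN_ <- B * N
  pgem <- as.numeric(params$gem_p)

  Fmaps <- vector("list", BN_)
  Xraw <- matrix(0, BN_, C)
  for (b in seq_len(B)) {
    if (xs[[b]]$n != N) {
      stop("view count of input (", xs[[b]]$n,
           ") differs from the model's (", N, ")")
    }
    inp <- view_input(xs[[b]])
    for (k in seq_len(N)) {
      i <- (b - 1L) * N + k
      Fmaps[[i]] <- backbone_forward(inp[[k]], params, dims$ims)
      Xraw[i, ] <- gem_pool(Fmaps[[i]], pgem, GEM_CLAMP)
    }
  }
  X <- bn_forward_eval(Xraw, params$bn1_gamma, params$bn1_beta,
                       state$bn1_mean, state$bn1_var)

  if (dims$use_gvmm) {
    head <- list(W = params$gvmm_W, b = params$gvmm_b,
                 bn_gamma = params$gvmm_bn_gamma,
                 bn_beta = params$gvmm_bn_beta,
                 bn_mean = state$gvmm_bn_mean, bn_var = state$gvmm_bn_var,
                 fc_w = params$gvmm_fc_w, fc_b = params$gvmm_fc_b)
    dvec <- vapply(Fmaps, function(F) {
      score_view(mask_salient(F, cfg$t1, cfg$gvmm_norm), head)
    }, 0)
  } else if (!is.null(cfg$manual_weights)) {
    dvec <- rep(cfg$manual_weights, times = B)
  } else {
    dvec <- rep(1, BN_)
  }

  if (cfg$gvem) {
    H <- list()
    for (nm in c("l1", "l2", "l3")) {
      Pre <- sweep(X %*% params[[paste0(nm, "_W")]], 2L,
                   params[[paste0(nm, "_b")]], "+")
      H[[nm]] <- bn_forward_eval(Pre, params[[paste0(nm, "_bn_gamma")]],
                                 params[[paste0(nm, "_bn_beta")]],
                                 state[[paste0(nm, "_bn_mean")]],
                                 state[[paste0(nm, "_bn_var")]])
    }
    Xp <- matrix(0, BN_, C)
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * N + 1L):(b * N)
      A <- pairwise_similarity(H$l1[rows, , drop = FALSE],
                               L2 = function(z) H$l2[rows, , drop = FALSE])
      Ap <- modify_similarity(A, gate_masks(A, cfg$t2), cfg$eq6)
      Xp[rows, ] <- enhance_descriptors(H$l3[rows, , drop = FALSE], Ap)
    }
  } else {
    Xp <- X
  }

  Xt <- matrix(0, B, C)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * N + 1L):(b * N)
    Xt[b, ] <- fuse_descriptors(dvec[rows], Xp[rows, , drop = FALSE],
                                X = X[rows, , drop = FALSE],
                                residual = cfg$residual)
  }
  if (cfg$fusion_bn) {
    Xt <- bn_forward_eval(Xt, params$fuse_bn_gamma, params$fuse_bn_beta,
                          state$fuse_bn_mean, state$fuse_bn_var)
  }
  classifier_forward(Xt, params)$prob
}
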