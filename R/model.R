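# User-facing model: mwfnet() fits the multi-view gated fusion classifier on
# a list of projected view stacks; the fitted object carries parameters,
# batch-normalization running moments, the configuration and the training
# loss history, with the usual print/summary/coef/predict/plot methods.

#' Project a set of morphologies into view stacks
#'
#' @param morphologies list of [neuron()] objects (or a
#'   `"synthetic_dataset"`).
#' @param cfg a [projection_config()] or [mwfnet_config()] (projection fields
#'   are taken from it).
#' @return list of `"view_stack"` objects.
#' @export
project_dataset <- function(morphologies, cfg = projection_config()) {
  if (inherits(morphologies, "synthetic_dataset")) {
    morphologies <- morphologies$morphologies
  }
  if (inherits(cfg, "mwfnet_config")) {
    cfg <- projection_config(cfg$phi_deg, cfg$image_size, cfg$margin_frac,
                             cfg$line_thickness_px)
  }
  lapply(morphologies, project_views, cfg = cfg)
}

#' Fit the multi-view gated fusion classifier
#'
#' Trains the full network (shared backbone, learned GeM exponent,
#' discriminability scoring, gated view enhancement, weighted fusion,
#' classifier) with Adam on the cross-entropy loss. All computation is
#' deterministic given `(x, y, config, seed)`.
#'
#' @param x list of `"view_stack"` objects (see [project_dataset()]), all with
#'   the model's view count and image size.
#' @param y class labels (factor or character), one per element of `x`.
#' @param config a [mwfnet_config()].
#' @param seed integer seed controlling initialization and batch shuffling.
#' @param verbose print the per-epoch training loss.
#' @return object of class `"mwfnet"`.
#' @examples
#' \donttest{
#' ds <- make_dataset(preset_morph_specs("separable-3"), per_class = 5, seed = 1)
#' cfg <- mwfnet_config(image_size = 48, epochs = 3, batch_size = 8)
#' vs <- project_dataset(ds, cfg)
#' fit <- mwfnet(vs, ds$labels, cfg, seed = 1)
#' predict(fit, vs[1:2])
#' }
#' @export
mwfnet <- function(x, y, config = mwfnet_config(), seed = 1L,
                   verbose = FALSE) {
  stopifnot(is.list(x), length(x) >= 2L)
  y <- factor(y)
  if (length(y) != length(x)) stop("length(y) must equal length(x)")
  classes <- levels(y)
  yint <- as.integer(y)
  n <- length(x)
  H0 <- nrow(x[[1L]]$views[[1L]])
  Nexp <- as.integer(floor(360 / config$phi_deg))
  if (x[[1L]]$n != Nexp) {
    stop("view stacks carry ", x[[1L]]$n, " views but the config implies ",
         Nexp)
  }

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(derive_seed(seed, 0L))

  mdl <- init_mwfnet(config, K = length(classes), H0 = H0)
  params <- mdl$params
  state <- mdl$state
  opt <- adam_init(params)
  bs <- min(config$batch_size, n)
  history <- numeric(config$epochs)

  for (ep in seq_len(config$epochs)) {
    perm <- sample.int(n)
    ep_loss <- 0
    nb <- 0L
    for (start in seq(1L, n, by = bs)) {
      idx <- perm[start:min(start + bs - 1L, n)]
      tb <- train_batch(params, state, mdl$dims, config, x[idx], yint[idx])
      if (!is.finite(tb$loss)) {
        stop("non-finite training loss at epoch ", ep,
             " (learning rate too high or degenerate batch)")
      }
      state <- tb$state
      upd <- adam_step(params, tb$grads, opt, config$lr)
      params <- upd$params
      opt <- upd$opt
      params$gem_p <- pmax(params$gem_p, 0.1)   # keep the power mean defined
      ep_loss <- ep_loss + tb$loss
      nb <- nb + 1L
    }
    history[ep] <- ep_loss / nb
    if (verbose) message(sprintf("epoch %3d  loss %.4f", ep, history[ep]))
  }

  structure(list(params = params, state = state, dims = mdl$dims,
                 config = config, classes = classes, loss = history,
                 seed = seed, n_train = n, call = match.call()),
            class = "mwfnet")
}

#' Predict from a fitted mwfnet model
#'
#' Deterministic eval-mode forward pass (frozen batch-normalization moments).
#'
#' @param object a fitted `"mwfnet"`.
#' @param newdata a `"view_stack"` or a list of them.
#' @param type `"class"` (factor of predicted labels) or `"prob"` (matrix of
#'   class probabilities, rows summing to 1).
#' @param ... unused.
#' @return factor or probability matrix.
#' @export
predict.mwfnet <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "view_stack")) newdata <- list(newdata)
  prob <- forward_eval(object$params, object$state, object$dims,
                       object$config, newdata)
  colnames(prob) <- object$classes
  if (type == "prob") return(prob)
  factor(object$classes[max.col(prob, ties.method = "first")],
         levels = object$classes)
}

#' Forward pass for a single view stack
#'
#' @param stack a `"view_stack"`.
#' @param model a fitted `"mwfnet"`.
#' @return named probability vector over the model's classes.
#' @export
mwfnet_forward <- function(stack, model) {
  drop(predict(model, stack, type = "prob"))
}

#' @export
print.mwfnet <- function(x, ...) {
  cat("Multi-view gated fusion neuron classifier (mwfnet)\n")
  cat(sprintf("  views: %d (phi = %g deg), descriptor channels: %d\n",
              x$dims$N, x$config$phi_deg, x$dims$C))
  cat(sprintf("  modules: GVMM %s, GVEM %s, residual %s\n",
              if (x$dims$use_gvmm) "on" else "off",
              if (x$config$gvem) "on" else "off",
              if (x$config$residual) "on" else "off"))
  cat(sprintf("  classes: %s\n", paste(x$classes, collapse = ", ")))
  cat(sprintf("  trainable parameters: %s\n",
              format(count_parameters(x), big.mark = ",")))
  cat(sprintf("  final training loss: %.4f (%d epochs)\n",
              x$loss[length(x$loss)], length(x$loss)))
  invisible(x)
}

#' @export
summary.mwfnet <- function(object, ...) {
  counts <- module_parameter_counts(object)
  structure(list(fit = object, module_params = counts), class = "summary.mwfnet")
}

#' @export
print.summary.mwfnet <- function(x, ...) {
  print(x$fit)
  cat("  parameters by module:\n")
  for (nm in names(x$module_params)) {
    cat(sprintf("    %-12s %s\n", nm,
                format(x$module_params[[nm]], big.mark = ",")))
  }
  cat(sprintf("  learned GeM exponent p: %s\n",
              paste(signif(x$fit$params$gem_p, 4), collapse = ", ")))
  invisible(x)
}

#' @export
coef.mwfnet <- function(object, ...) object$params

#' @export
plot.mwfnet <- function(x, ...) {
  graphics::plot(seq_along(x$loss), x$loss, type = "l",
                 xlab = "epoch", ylab = "training cross-entropy", ...)
  invisible(x)
}

#' Count trainable parameters
#'
#' @param object a fitted `"mwfnet"` (or its parameter list).
#' @return total number of trainable scalars.
#' @export
count_parameters <- function(object) {
  params <- if (inherits(object, "mwfnet")) object$params else object
  sum(vapply(params, length, 0L))
}

#' Per-module trainable-parameter counts
#'
#' @param object a fitted `"mwfnet"`.
#' @return named list: backbone, gem, bn, gvmm, gvem, fusion, classifier.
#' @export
module_parameter_counts <- function(object) {
  p <- object$params
  pick <- function(prefixes) {
    nm <- names(p)[Reduce(`|`, lapply(prefixes, function(pre) {
      startsWith(names(p), pre)
    }))]
    sum(vapply(p[nm], length, 0L))
  }
  list(
    backbone = pick("conv"),
    gem = length(p$gem_p),
    descriptor_bn = pick("bn1"),
    gvmm = pick("gvmm"),
    gvem = pick(c("l1_", "l2_", "l3_")),
    fusion = pick("fuse"),
    classifier = pick("cls")
  )
}
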