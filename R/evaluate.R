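# Cross-validation and evaluation: stratified k-fold splitting, accuracy /
# per-class F1 / macro-F1 / confusion-matrix reports, a CV driver and an
# ablation helper over the module toggles.

#' Stratified k-fold split
#'
#' Folds are disjoint, cover all samples, differ in size by at most one, and
#' are stratified by label: within each class the shuffled indices are dealt
#' round-robin across folds (fold offsets rotated between classes to balance
#' sizes). Deterministic given `seed`.
#'
#' @param labels vector of class labels.
#' @param folds number of folds (>= 2, <= number of samples).
#' @param seed integer seed.
#' @return list of `folds` integer vectors (the test indices of each fold).
#' @export
kfold_split <- function(labels, folds = 10L, seed = 1L) {
  n <- length(labels)
  if (folds < 2L) stop("folds must be >= 2")
  if (n < folds) stop("need at least as many samples as folds")
  labels <- factor(labels)
  if (any(table(labels) < folds)) {
    warning("some class has fewer samples than folds; ",
            "stratification is degenerate for it")
  }
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(derive_seed(seed, 1L))
  assignment <- integer(n)
  offset <- 0L
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    assignment[idx] <- ((seq_along(idx) - 1L + offset) %% folds) + 1L
    offset <- offset + length(idx)
  }
  lapply(seq_len(folds), function(f) which(assignment == f))
}

#' Evaluation report: accuracy, per-class F1, macro-F1, confusion matrix
#'
#' @param truth true labels.
#' @param pred predicted labels.
#' @param levels class levels; defaults to the union of both.
#' @return list of class `"mwfnet_report"`: `accuracy`, `per_class_f1`
#'   (named), `macro_f1`, `confusion` (rows = truth, columns = prediction),
#'   `n`.
#' @export
evaluation_report <- function(truth, pred, levels = NULL) {
  if (length(truth) == 0L) stop("empty test set")
  if (length(truth) != length(pred)) stop("truth/pred length mismatch")
  if (is.null(levels)) levels <- sort(unique(c(as.character(truth),
                                               as.character(pred))))
  truth <- factor(truth, levels = levels)
  pred <- factor(pred, levels = levels)
  cm <- table(truth = truth, predicted = pred)
  n <- sum(cm)
  acc <- sum(diag(cm)) / n
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  names(f1) <- levels
  structure(list(accuracy = acc, per_class_f1 = f1,
                 macro_f1 = mean(f1), confusion = cm, n = n),
            class = "mwfnet_report")
}

#' @export
print.mwfnet_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f   macro-F1 %.4f   (n = %d)\n",
              x$accuracy, x$macro_f1, x$n))
  cat("per-class F1:\n")
  print(round(x$per_class_f1, 4))
  cat("confusion matrix (rows = truth):\n")
  print(x$confusion)
  invisible(x)
}

#' Evaluate a fitted model on a labeled test set
#'
#' @param fit a fitted `"mwfnet"`.
#' @param x list of view stacks.
#' @param y true labels.
#' @return an [evaluation_report()].
#' @export
evaluate_mwfnet <- function(fit, x, y) {
  if (length(x) == 0L) stop("empty test set")
  pred <- predict(fit, x, type = "class")
  evaluation_report(factor(y, levels = fit$classes), pred,
                    levels = fit$classes)
}

#' k-fold cross-validation of the full pipeline
#'
#' Splits with [kfold_split()], fits one model per fold on the remaining
#' samples and evaluates on the held-out fold; reports the per-fold metrics
#' and their means.
#'
#' @param x list of view stacks.
#' @param y class labels.
#' @param config a [mwfnet_config()]; `config$folds` is the default fold
#'   count.
#' @param folds number of folds.
#' @param seed integer seed (splits, initialization and shuffling derive from
#'   it).
#' @param verbose print per-fold results.
#' @return list of class `"mwfnet_cv"`: `accuracy` and `macro_f1` (means),
#'   `fold_table` (data frame), `reports`, `folds`.
#' @export
mwfnet_cv <- function(x, y, config = mwfnet_config(), folds = config$folds,
                      seed = 1L, verbose = FALSE) {
  y <- factor(y)
  splits <- kfold_split(y, folds = folds, seed = seed)
  reports <- vector("list", folds)
  for (f in seq_len(folds)) {
    test <- splits[[f]]
    train <- setdiff(seq_along(x), test)
    fit <- mwfnet(x[train], y[train], config, seed = derive_seed(seed, 100L + f))
    reports[[f]] <- evaluate_mwfnet(fit, x[test], y[test])
    if (verbose) {
      message(sprintf("fold %2d: accuracy %.3f macro-F1 %.3f", f,
                      reports[[f]]$accuracy, reports[[f]]$macro_f1))
    }
  }
  tab <- data.frame(
    fold = seq_len(folds),
    n_test = vapply(reports, function(r) r$n, 0),
    accuracy = vapply(reports, function(r) r$accuracy, 0),
    macro_f1 = vapply(reports, function(r) r$macro_f1, 0)
  )
  structure(list(accuracy = mean(tab$accuracy), macro_f1 = mean(tab$macro_f1),
                 fold_table = tab, reports = reports, folds = folds,
                 seed = seed),
            class = "mwfnet_cv")
}

#' @export
print.mwfnet_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation: mean accuracy %.4f, mean macro-F1 %.4f\n",
              x$folds, x$accuracy, x$macro_f1))
  print(x$fold_table, row.names = FALSE)
  invisible(x)
}

#' Ablation over module toggles
#'
#' Fits and evaluates one model per grid row on a fixed stratified
#' train/test split, reporting accuracy, macro-F1 and the trainable-parameter
#' count of each variant.
#'
#' @param x list of view stacks.
#' @param y class labels.
#' @param grid data frame with logical columns `gvmm` and `gvem` (optional
#'   numeric `t1`, `t2` columns override the config per row).
#' @param config base [mwfnet_config()].
#' @param seed integer seed (shared split; per-row fits derive from it).
#' @param test_frac held-out fraction.
#' @return data frame: grid columns plus `params`, `accuracy`, `macro_f1`.
#' @export
ablate_mwfnet <- function(x, y,
                          grid = expand.grid(gvmm = c(FALSE, TRUE),
                                             gvem = c(FALSE, TRUE)),
                          config = mwfnet_config(), seed = 1L,
                          test_frac = 0.3) {
  y <- factor(y)
  nfold <- max(2L, round(1 / test_frac))
  test <- kfold_split(y, folds = nfold, seed = seed)[[1L]]
  train <- setdiff(seq_along(x), test)
  out <- grid
  out$params <- NA_integer_
  out$accuracy <- NA_real_
  out$macro_f1 <- NA_real_
  for (r in seq_len(nrow(grid))) {
    cfg <- config
    cfg$gvmm <- isTRUE(grid$gvmm[r])
    cfg$gvem <- isTRUE(grid$gvem[r])
    if (!is.null(grid$t1)) cfg$t1 <- grid$t1[r]
    if (!is.null(grid$t2)) cfg$t2 <- grid$t2[r]
    fit <- mwfnet(x[train], y[train], cfg, seed = derive_seed(seed, 500L + r))
    rep <- evaluate_mwfnet(fit, x[test], y[test])
    out$params[r] <- count_parameters(fit)
    out$accuracy[r] <- rep$accuracy
    out$macro_f1[r] <- rep$macro_f1
  }
  out
}
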