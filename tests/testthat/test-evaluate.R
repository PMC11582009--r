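# Stratified k-fold splitting, metric computation and the CV/ablation
# drivers.

test_that("k-fold splits are disjoint, covering, balanced and stratified", {
  labels <- rep(c("a", "b"), each = 50)
  sp <- kfold_split(labels, folds = 10L, seed = 1L)
  expect_length(sp, 10L)
  expect_equal(sort(unlist(sp)), 1:100)
  expect_true(all(lengths(sp) == 10L))
  ## stratification: every fold holds 5 of each class
  for (f in sp) expect_equal(as.integer(table(labels[f])), c(5L, 5L))
  ## balanced 3-class n = 30, folds = 10: exactly one of each class per fold
  lab3 <- rep(c("x", "y", "z"), each = 10)
  sp3 <- kfold_split(lab3, folds = 10L, seed = 2L)
  for (f in sp3) expect_equal(as.integer(table(lab3[f])), c(1L, 1L, 1L))
  ## unbalanced: fold sizes differ by at most one
  lab <- c(rep("a", 13), rep("b", 8))
  spu <- kfold_split(lab, folds = 4L, seed = 3L)
  expect_lte(diff(range(lengths(spu))), 1L)
  expect_equal(sort(unlist(spu)), seq_along(lab))
})

test_that("k-fold splitting is deterministic and warns on tiny classes", {
  labels <- rep(c("a", "b", "c"), times = c(12, 9, 2))
  suppressWarnings({
    expect_identical(kfold_split(labels, 3L, seed = 9L),
                     kfold_split(labels, 3L, seed = 9L))
    expect_false(identical(kfold_split(labels, 3L, seed = 9L),
                           kfold_split(labels, 3L, seed = 10L)))
  })
  expect_warning(kfold_split(labels, 5L, seed = 1L), "fewer samples")
  expect_error(kfold_split(labels, 1L), "folds")
  expect_error(kfold_split(c("a", "b"), 5L), "at least as many samples")
})

test_that("evaluation metrics match closed forms and an independent oracle", {
  ## perfect predictions
  r <- evaluation_report(c("a", "b", "a"), c("a", "b", "a"))
  expect_equal(r$accuracy, 1)
  expect_equal(r$macro_f1, 1)
  expect_true(all(diag(r$confusion) == c(2, 1)))
  ## constant predictor on balanced two classes: accuracy 1/2, F1 = 2/3 and 0
  truth <- rep(c("a", "b"), each = 10)
  pred <- rep("a", 20)
  r2 <- evaluation_report(truth, pred, levels = c("a", "b"))
  expect_equal(r2$accuracy, 0.5)
  expect_equal(unname(r2$per_class_f1), c(2 / 3, 0))
  expect_equal(r2$macro_f1, 1 / 3)
  ## random predictions vs a loop-based oracle
  set.seed(13)
  for (trial in 1:20) {
    K <- sample(2:5, 1)
    lv <- letters[1:K]
    n <- 40L
    truth <- sample(lv, n, replace = TRUE)
    pred <- sample(lv, n, replace = TRUE)
    r <- evaluation_report(truth, pred, levels = lv)
    ## oracle: explicit per-class precision/recall loops
    f1o <- numeric(K)
    for (k in seq_len(K)) {
      tp <- sum(truth == lv[k] & pred == lv[k])
      fp <- sum(truth != lv[k] & pred == lv[k])
      fn <- sum(truth == lv[k] & pred != lv[k])
      prec <- if (tp + fp > 0) tp / (tp + fp) else 0
      rec <- if (tp + fn > 0) tp / (tp + fn) else 0
      f1o[k] <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    }
    expect_equal(r$accuracy, mean(truth == pred))
    expect_equal(unname(r$per_class_f1), f1o)
    expect_equal(r$macro_f1, mean(f1o))
    ## confusion-matrix invariants
    expect_equal(unname(rowSums(r$confusion)),
                 unname(as.vector(table(factor(truth, lv)))))
    expect_equal(sum(diag(r$confusion)) / r$n, r$accuracy)
  }
  expect_error(evaluation_report(character(0), character(0)), "empty")
})

test_that("cross-validation evaluates each sample exactly once and is deterministic", {
  ds <- tiny_dataset()
  vs <- tiny_views()
  cfg <- tiny_config(epochs = 2L)
  cv1 <- mwfnet_cv(vs, ds$labels, cfg, folds = 3L, seed = 5L)
  expect_equal(sum(cv1$fold_table$n_test), length(vs))
  expect_equal(cv1$accuracy, mean(cv1$fold_table$accuracy))
  cv2 <- mwfnet_cv(vs, ds$labels, cfg, folds = 3L, seed = 5L)
  expect_identical(cv1$fold_table, cv2$fold_table)
})

test_that("the ablation grid reports one row per variant with parameter counts", {
  ds <- tiny_dataset()
  vs <- tiny_views()
  cfg <- tiny_config(epochs = 2L)
  grid <- expand.grid(gvmm = c(FALSE, TRUE), gvem = c(FALSE, TRUE))
  tab <- ablate_mwfnet(vs, ds$labels, grid, config = cfg, seed = 4L)
  expect_equal(nrow(tab), 4L)
  expect_true(all(is.finite(tab$accuracy)))
  ## enabling a module strictly increases the parameter count, by exactly the
  ## closed-form GVEM amount for the GVEM toggle
  expect_equal(tab$params[grid$gvem] - tab$params[!grid$gvem],
               rep(gvem_parameter_count(6L), 2L))
  ## rows are (F,F), (T,F), (F,T), (T,T): the GVMM toggle adds its head
  expect_gt(tab$params[2L], tab$params[1L])
  expect_gt(tab$params[4L], tab$params[3L])
})
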