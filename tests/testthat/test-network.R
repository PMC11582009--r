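# Network engine: exact gradients, gradient flow, determinism, learnability
# and the module-toggle contract.

test_that("analytic gradients match central finite differences", {
  cfg <- tiny_config(gvmm = TRUE, gvem = TRUE, residual = TRUE,
                     fusion_bn = TRUE)
  vs <- tiny_views()
  ds <- tiny_dataset()
  withr::local_seed(21)
  mdl <- mwfnet:::init_mwfnet(cfg, K = 2L, H0 = 16L)
  params <- mdl$params
  ## generic parameter values so no gate sits on a decision boundary
  for (nm in names(params)) {
    params[[nm]] <- params[[nm]] + rnorm(length(params[[nm]]), sd = 0.05)
  }
  params$gem_p <- abs(params$gem_p) + 2
  xs <- vs[c(1L, 8L)]
  yint <- c(1L, 2L)
  tb <- mwfnet:::train_batch(params, mdl$state, mdl$dims, cfg, xs, yint,
                             update_state = FALSE)
  lossfn <- function(p) {
    mwfnet:::train_batch(p, mdl$state, mdl$dims, cfg, xs, yint,
                         update_state = FALSE)$loss
  }
  h <- 1e-5
  for (nm in names(params)) {
    np <- length(params[[nm]])
    pick <- if (np <= 2L) seq_len(np) else sort(sample.int(np, 2L))
    for (j in pick) {
      pp <- params; pp[[nm]][j] <- pp[[nm]][j] + h
      pm <- params; pm[[nm]][j] <- pm[[nm]][j] - h
      num <- (lossfn(pp) - lossfn(pm)) / (2 * h)
      ana <- tb$grads[[nm]][j]
      if (abs(num) < 1e-10 && abs(ana) < 1e-10) next
      expect_lt(abs(num - ana) / max(1e-6, abs(num), abs(ana)), 1e-3,
                label = sprintf("gradient mismatch in %s[%d]", nm, j))
    }
  }
})

test_that("alternative configurations also backpropagate exactly", {
  ## per-channel feature normalization, per-channel GeM exponents and the
  ## literal printed similarity-modification variant share little code with
  ## the defaults, so each gets its own finite-difference spot check
  cfg <- tiny_config(gvmm_norm = "per_channel", gem_per_channel = TRUE,
                     eq6 = "as_printed")
  vs <- tiny_views()
  withr::local_seed(33)
  mdl <- mwfnet:::init_mwfnet(cfg, K = 2L, H0 = 16L)
  params <- mdl$params
  for (nm in names(params)) {
    params[[nm]] <- params[[nm]] + rnorm(length(params[[nm]]), sd = 0.05)
  }
  params$gem_p <- abs(params$gem_p) + 2
  xs <- vs[c(3L, 10L)]
  tb <- mwfnet:::train_batch(params, mdl$state, mdl$dims, cfg, xs, c(1L, 2L),
                             update_state = FALSE)
  lossfn <- function(p) {
    mwfnet:::train_batch(p, mdl$state, mdl$dims, cfg, xs, c(1L, 2L),
                         update_state = FALSE)$loss
  }
  h <- 1e-5
  for (nm in c("conv1_W", "conv2_W", "gem_p", "gvmm_W", "l1_W", "l3_W")) {
    np <- length(params[[nm]])
    for (j in sort(sample.int(np, min(3L, np)))) {
      pp <- params; pp[[nm]][j] <- pp[[nm]][j] + h
      pm <- params; pm[[nm]][j] <- pm[[nm]][j] - h
      num <- (lossfn(pp) - lossfn(pm)) / (2 * h)
      ana <- tb$grads[[nm]][j]
      if (abs(num) < 1e-10 && abs(ana) < 1e-10) next
      expect_lt(abs(num - ana) / max(1e-6, abs(num), abs(ana)), 1e-3,
                label = sprintf("gradient mismatch in %s[%d]", nm, j))
    }
  }
})

test_that("every parameter group receives gradient on a generic batch", {
  ## biases feeding directly into a normalization layer are provably
  ## gradient-free (the batch mean removes them), so they are exempt
  cfg <- tiny_config()
  vs <- tiny_views()
  withr::local_seed(22)
  mdl <- mwfnet:::init_mwfnet(cfg, K = 2L, H0 = 16L)
  params <- mdl$params
  for (nm in names(params)) {
    params[[nm]] <- params[[nm]] + rnorm(length(params[[nm]]), sd = 0.05)
  }
  params$gem_p <- abs(params$gem_p) + 2
  tb <- mwfnet:::train_batch(params, mdl$state, mdl$dims, cfg,
                             vs[c(2L, 9L)], c(1L, 2L), update_state = FALSE)
  pre_norm_bias <- c("gvmm_b", "l1_b", "l2_b", "l3_b")
  for (nm in setdiff(names(tb$grads), pre_norm_bias)) {
    expect_gt(max(abs(tb$grads[[nm]])), 0, label = paste("gradient of", nm))
  }
})

test_that("training reduces the loss and is bit-reproducible", {
  ds <- tiny_dataset()
  vs <- tiny_views()
  cfg <- tiny_config(epochs = 6L)
  f1 <- mwfnet(vs, ds$labels, cfg, seed = 3L)
  expect_lt(f1$loss[length(f1$loss)], f1$loss[1L])
  f2 <- mwfnet(vs, ds$labels, cfg, seed = 3L)
  expect_identical(f1$params, f2$params)
  p1 <- predict(f1, vs, type = "prob")
  p2 <- predict(f2, vs, type = "prob")
  expect_identical(p1, p2)
  expect_equal(rowSums(p1), rep(1, length(vs)), tolerance = 1e-6)
  ## a different seed gives different weights
  f3 <- mwfnet(vs, ds$labels, cfg, seed = 4L)
  expect_false(identical(f1$params, f3$params))
})

test_that("view-count mismatch between model and input is rejected", {
  ds <- tiny_dataset()
  vs <- tiny_views()
  fit <- fixture("tiny_fit", function() {
    mwfnet(tiny_views(), tiny_dataset()$labels, tiny_config(epochs = 2L),
           seed = 1L)
  })
  other <- project_views(ds$morphologies[[1L]],
                         projection_config(90, 16L))
  expect_error(predict(fit, other), "view count")
})

test_that("with both modules disabled the model is the plain fusion baseline", {
  ds <- tiny_dataset()
  vs <- tiny_views()
  cfg <- tiny_config(gvmm = FALSE, gvem = FALSE, epochs = 2L)
  fit <- mwfnet(vs, ds$labels, cfg, seed = 7L)
  ## no gating parameters exist in the baseline
  expect_false(any(grepl("^(gvmm|l1_|l2_|l3_)", names(fit$params))))
  ## hand composition from the exported operations reproduces predict():
  ## encode -> unit-weight fusion with residual -> eval BN -> classifier
  stack <- vs[[5L]]
  enc <- encode_views(stack, model = fit)
  xt <- fuse_descriptors(rep(1, stack$n), enc$X, X = enc$X, residual = TRUE)
  xt <- as.numeric(normalize_descriptors(matrix(xt, 1L),
                                         fit$params$fuse_bn_gamma,
                                         fit$params$fuse_bn_beta,
                                         fit$state$fuse_bn_mean,
                                         fit$state$fuse_bn_var,
                                         training = FALSE))
  pr <- mwfnet:::classifier_forward(matrix(xt, 1L), fit$params)$prob
  expect_equal(drop(pr), unname(mwfnet_forward(stack, fit)), tolerance = 1e-10)
})

test_that("manual view weights bypass the measurement module", {
  ds <- tiny_dataset()
  vs <- tiny_views()
  cfg <- tiny_config(manual_weights = c(1, 1, 1), epochs = 2L)
  fit <- mwfnet(vs, ds$labels, cfg, seed = 2L)
  expect_false(fit$dims$use_gvmm)
  expect_false(any(grepl("^gvmm", names(fit$params))))
  ## a model with unequal manual weights differs from the equal-weight one
  cfg2 <- tiny_config(manual_weights = c(1, 0, 0), epochs = 2L)
  fit2 <- mwfnet(vs, ds$labels, cfg2, seed = 2L)
  expect_false(identical(predict(fit, vs[1:2], type = "prob"),
                         predict(fit2, vs[1:2], type = "prob")))
})

test_that("parameter accounting is consistent across modules", {
  fit <- fixture("tiny_fit", function() {
    mwfnet(tiny_views(), tiny_dataset()$labels, tiny_config(epochs = 2L),
           seed = 1L)
  })
  counts <- module_parameter_counts(fit)
  expect_equal(Reduce(`+`, counts), count_parameters(fit))
  expect_equal(counts$gvem, gvem_parameter_count(fit$dims$C))
})
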