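# PCA alignment, view rotation and binary rasterization.

test_that("pca_align centers and orients a cloud already spread along x", {
  xyz <- cbind(seq(-5, 5, length.out = 11), rnorm(11, sd = 1e-3),
               rnorm(11, sd = 1e-6))
  m <- pca_align(path_neuron(xyz))
  P <- as.matrix(m$nodes[c("x", "y", "z")])
  expect_equal(colMeans(P), c(x = 0, y = 0, z = 0), tolerance = 1e-8)
  ## dominant axis stays x up to sign
  expect_gt(abs(stats::cor(P[, 1], xyz[, 1] - mean(xyz[, 1]))), 0.999)
})

test_that("pca_align is invariant to a random prior rotation (eigen oracle)", {
  withr::local_seed(42)
  m0 <- random_neuron(3L)
  a0 <- pca_align(m0)
  ## random rotation from QR of a Gaussian matrix
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  m1 <- m0
  m1$nodes[c("x", "y", "z")] <-
    as.matrix(m0$nodes[c("x", "y", "z")]) %*% t(Q)
  a1 <- pca_align(m1)
  P0 <- as.matrix(a0$nodes[c("x", "y", "z")])
  P1 <- as.matrix(a1$nodes[c("x", "y", "z")])
  ## agreement up to per-axis sign; the skewness convention fixes signs for a
  ## generic cloud, so expect exact agreement column by column
  for (j in 1:3) {
    expect_true(isTRUE(all.equal(P0[, j], P1[, j], tolerance = 1e-6)) ||
                  isTRUE(all.equal(P0[, j], -P1[, j], tolerance = 1e-6)))
  }
  ## oracle: aligned variances are the covariance eigenvalues, descending
  ev <- eigen(stats::cov(P0) * (nrow(P0) - 1) / nrow(P0),
              symmetric = TRUE, only.values = TRUE)$values
  expect_equal(apply(P0, 2, function(v) mean(v^2)), ev,
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("pca_align maps a single node to the origin", {
  m <- pca_align(path_neuron(matrix(c(3, -2, 7), 1)))
  expect_equal(unlist(m$nodes[c("x", "y", "z")]), c(x = 0, y = 0, z = 0))
})

test_that("view rotation matches hand-evaluated matrices and its identities", {
  m <- path_neuron(rbind(c(1, 0, 0), c(0, 2, -1)))
  expect_equal(rotate_neuron(m, 0)$nodes, m$nodes)
  r360 <- rotate_neuron(m, 360)
  expect_equal(as.matrix(r360$nodes[c("x", "y", "z")]),
               as.matrix(m$nodes[c("x", "y", "z")]), tolerance = 1e-12)
  ## point (1,0,0), theta 90: R_y(90) -> (0,0,-1); R_z(90) leaves it there
  r90 <- rotate_neuron(path_neuron(matrix(c(1, 0, 0), 1)), 90)
  expect_equal(unlist(r90$nodes[c("x", "y", "z")]), c(x = 0, y = 0, z = -1),
               tolerance = 1e-12)
  ## y-rotation is applied first: (0,0,1) -> R_y(90) -> (1,0,0) -> R_z(90) -> (0,1,0)
  rz <- rotate_neuron(path_neuron(matrix(c(0, 0, 1), 1)), 90)
  expect_equal(unlist(rz$nodes[c("x", "y", "z")]), c(x = 0, y = 1, z = 0),
               tolerance = 1e-12)
})

test_that("rasterization draws nodes and connected segments", {
  cfg <- projection_config(image_size = 33L, margin_frac = 0)
  ## single node: one foreground pixel at the center
  img1 <- rasterize(path_neuron(matrix(c(5, 5, 0), 1)), cfg)
  expect_equal(sum(img1), 1L)
  expect_equal(which(img1 == 1L, arr.ind = TRUE)[1, ],
               c(row = 17L, col = 17L))
  ## two connected nodes at opposite corners: an 8-connected path at least as
  ## long as the Chebyshev distance between the endpoints
  img2 <- rasterize(path_neuron(rbind(c(0, 0, 0), c(10, 7, 0))), cfg)
  fg <- which(img2 == 1L, arr.ind = TRUE)
  expect_gte(nrow(fg), 33L)   # Chebyshev distance spans the full image side
  ## the digital line itself is 8-connected: consecutive pixels differ by at
  ## most one in each coordinate, and endpoints are exact
  px <- mwfnet:::line_pixels(28L, 1L, 6L, 33L)
  expect_true(all(abs(diff(px[, 1])) <= 1 & abs(diff(px[, 2])) <= 1))
  expect_equal(px[1, ], c(28L, 1L), ignore_attr = TRUE)
  expect_equal(px[nrow(px), ], c(6L, 33L), ignore_attr = TRUE)
  ## strictly binary output
  expect_true(all(img2 %in% c(0L, 1L)))
  expect_equal(count_components8(img2), 1L)  # one connected stroke
})

test_that("a two-root forest renders two connected components", {
  nodes <- data.frame(
    id = 1:4, type = 3L,
    x = c(0, 1, 10, 11), y = c(0, 0.5, 10, 10.5), z = 0,
    radius = 1, parent = c(-1L, 1L, -1L, 3L))
  suppressWarnings(m <- neuron(nodes))
  img <- rasterize(m, projection_config(image_size = 64L))
  expect_equal(count_components8(img), 2L)
})

test_that("project_views yields floor(360/phi) views at theta = k*phi", {
  m <- random_neuron(4L)
  vs8 <- project_views(m, projection_config(45, 32L))
  expect_equal(vs8$n, 8L)
  vs4 <- project_views(m, projection_config(90, 32L))
  expect_equal(vs4$n, 4L)
  vs3 <- project_views(m, projection_config(120, 32L))
  expect_equal(vs3$n, 3L)
  expect_equal(vs3$theta_deg, c(0, 120, 240))
  ## non-divisor interval is legal
  expect_equal(project_views(m, projection_config(100, 32L))$n, 3L)
  expect_error(projection_config(0, 32L), "phi_deg")
  expect_error(projection_config(360, 32L), "phi_deg")
  ## view 0 equals the plain x-y orthographic projection of the aligned neuron
  plain <- rasterize(pca_align(m), projection_config(45, 32L))
  expect_equal(vs8$views[[1]], plain, ignore_attr = TRUE)
  ## all views strictly binary with nonempty foreground
  expect_true(all(vapply(vs8$views, function(v) all(v %in% 0:1), TRUE)))
  expect_true(all(vapply(vs8$views, sum, 0L) > 0L))
})

test_that("view PNGs are written with stem, index and angle in the name", {
  m <- random_neuron(6L)
  vs <- project_views(m, projection_config(120, 32L))
  d <- withr::local_tempdir()
  write_views(vs, d, stem = "n1")
  files <- list.files(d)
  expect_setequal(files, c("n1_view0_theta0.png", "n1_view1_theta120.png",
                           "n1_view2_theta240.png"))
  back <- png::readPNG(file.path(d, "n1_view0_theta0.png"))
  expect_equal(back, vs$views[[1]] * 1.0, ignore_attr = TRUE)
})
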