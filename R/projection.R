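# PCA alignment and rotational 2D binary projection of neuron morphologies.
#
# A morphology is first aligned to its principal axes (largest variance -> x),
# then, for each view k, rotated about the y-axis by theta_k = k*phi and about
# the z-axis by the same angle, and orthographically projected onto the x-y
# plane as a binary raster in which every node and every child-parent segment
# is drawn.

#' Projection configuration
#'
#' @param phi_deg rotation interval phi in degrees; `floor(360/phi)` views are
#'   generated at theta = 0, phi, 2*phi, ...
#' @param image_size side length of the square output raster in pixels.
#' @param margin_frac fraction of the image left blank on each side; the
#'   morphology is min-max scaled isotropically into the remaining area.
#' @param line_thickness_px stroke thickness of drawn segments, in pixels.
#' @return list of class `"projection_config"`.
#' @export
projection_config <- function(phi_deg = 45, image_size = 224L,
                              margin_frac = 0.05, line_thickness_px = 1L) {
  if (phi_deg <= 0 || phi_deg >= 360) {
    stop("phi_deg must lie strictly between 0 and 360")
  }
  if (image_size < 16L) stop("image_size must be >= 16")
  if (margin_frac < 0 || margin_frac >= 0.5) {
    stop("margin_frac must lie in [0, 0.5)")
  }
  if (line_thickness_px < 1L) stop("line_thickness_px must be >= 1")
  structure(list(phi_deg = phi_deg, image_size = as.integer(image_size),
                 margin_frac = margin_frac,
                 line_thickness_px = as.integer(line_thickness_px)),
            class = "projection_config")
}

#' Align a morphology to its principal axes
#'
#' Centers the coordinates and replaces them by their projections onto the
#' eigenvectors of the 3x3 coordinate covariance, sorted by descending
#' eigenvalue (first -> x, second -> y, third -> z). The sign of each axis is
#' fixed deterministically: the axis is oriented so the third central moment
#' (skewness) of the projected coordinates is nonnegative; when the skewness
#' is numerically zero the largest-magnitude loading is made positive. This
#' canonical frame makes similar neurons produce similar view images
#' regardless of their original orientation.
#'
#' @param m a `"neuron"` object.
#' @return the morphology with transformed coordinates.
#' @export
pca_align <- function(m) {
  nd <- m$nodes
  P <- as.matrix(nd[, c("x", "y", "z")])
  ctr <- colMeans(P)
  P <- sweep(P, 2L, ctr)
  if (nrow(P) == 1L) {
    nd[, c("x", "y", "z")] <- P
    m$nodes <- nd
    return(m)
  }
  cv <- crossprod(P) / nrow(P)
  eg <- eigen(cv, symmetric = TRUE)   # eigenvalues in decreasing order
  V <- eg$vectors
  S <- P %*% V
  for (j in 1:3) {
    sk <- mean(S[, j]^3)
    if (abs(sk) < 1e-9) {
      if (V[which.max(abs(V[, j])), j] < 0) {
        V[, j] <- -V[, j]
        S[, j] <- -S[, j]
      }
    } else if (sk < 0) {
      V[, j] <- -V[, j]
      S[, j] <- -S[, j]
    }
  }
  nd[, c("x", "y", "z")] <- S
  m$nodes <- nd
  m
}

## right-handed active rotation matrices, column-vector convention
rot_y <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3L, 3L)
}
rot_z <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3L, 3L)
}

#' Rotate a morphology for view generation
#'
#' Applies the view rotation of the projection scheme: rotation about the
#' y-axis by `theta_deg` followed by rotation about the z-axis by the same
#' angle (right-handed, active). The z coordinate is retained; projection
#' later uses the x-y plane.
#'
#' @param m a `"neuron"` object (normally PCA-aligned).
#' @param theta_deg rotation angle in degrees.
#' @return rotated morphology.
#' @export
rotate_neuron <- function(m, theta_deg) {
  th <- theta_deg * pi / 180
  R <- rot_z(th) %*% rot_y(th)
  P <- as.matrix(m$nodes[, c("x", "y", "z")])
  m$nodes[, c("x", "y", "z")] <- P %*% t(R)
  m
}

## integer 8-connected digital line (Bresenham-style symmetric rounding)
line_pixels <- function(r0, c0, r1, c1) {
  nsteps <- max(abs(r1 - r0), abs(c1 - c0))
  if (nsteps == 0L) return(cbind(r0, c0))
  t <- 0:nsteps
  cbind(r0 + round(t * (r1 - r0) / nsteps),
        c0 + round(t * (c1 - c0) / nsteps))
}

#' Rasterize a morphology into a binary view image
#'
#' Projects the (x, y) coordinates orthographically, min-max scales them
#' isotropically (aspect ratio preserved) into the image with the configured
#' margin, and draws every node plus an 8-connected digital line for every
#' child-parent segment. A zero-extent morphology (single point) renders one
#' foreground blob at the image center.
#'
#' @param m a `"neuron"` object with finite coordinates.
#' @param cfg a [projection_config()].
#' @param theta_deg rotation angle recorded on the output (metadata only).
#' @return integer matrix `image_size x image_size` with values in \{0, 1\};
#'   attribute `theta_deg` carries the angle.
#' @export
rasterize <- function(m, cfg = projection_config(), theta_deg = 0) {
  nd <- m$nodes
  size <- cfg$image_size
  x <- nd$x
  y <- nd$y
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("non-finite projected coordinates")
  }
  rngx <- range(x); rngy <- range(y)
  ext <- max(rngx[2] - rngx[1], rngy[2] - rngy[1])
  avail <- (1 - 2 * cfg$margin_frac) * (size - 1)
  scale <- if (ext > 0) avail / ext else 0
  cx <- mean(rngx); cy <- mean(rngy)
  mid <- (size + 1) / 2
  col <- as.integer(round((x - cx) * scale + mid))
  row <- as.integer(round(-(y - cy) * scale + mid))   # image rows grow downward
  col <- pmin(pmax(col, 1L), size)
  row <- pmin(pmax(row, 1L), size)
  img <- matrix(0L, size, size)
  img[cbind(row, col)] <- 1L
  seg <- neuron_segments(m)
  if (nrow(seg)) {
    for (i in seq_len(nrow(seg))) {
      px <- line_pixels(row[seg[i, 1L]], col[seg[i, 1L]],
                        row[seg[i, 2L]], col[seg[i, 2L]])
      img[px] <- 1L
    }
  }
  t <- cfg$line_thickness_px
  if (t > 1L) {
    rad <- t %/% 2L
    fg <- which(img == 1L, arr.ind = TRUE)
    for (dr in -rad:rad) {
      for (dc in -rad:rad) {
        rr <- pmin(pmax(fg[, 1L] + dr, 1L), size)
        cc <- pmin(pmax(fg[, 2L] + dc, 1L), size)
        img[cbind(rr, cc)] <- 1L
      }
    }
  }
  attr(img, "theta_deg") <- theta_deg
  img
}

#' Project a morphology into a stack of rotational binary views
#'
#' PCA-aligns the morphology once, then renders `N = floor(360/phi)` views at
#' theta = 0, phi, 2*phi, ...: each view rotates the aligned coordinates about
#' the y- then the z-axis by theta and rasterizes the x-y projection.
#'
#' @param m a `"neuron"` object.
#' @param cfg a [projection_config()].
#' @return object of class `"view_stack"`: list with `views` (list of binary
#'   matrices), `theta_deg`, `config` and `n`.
#' @examples
#' m <- grow_neuron(morph_class_spec("demo"), seed = 1)
#' vs <- project_views(m, projection_config(phi_deg = 90, image_size = 64))
#' vs$n  # 4 views
#' @export
project_views <- function(m, cfg = projection_config()) {
  if (!inherits(cfg, "projection_config")) cfg <- do.call(projection_config, cfg)
  aligned <- pca_align(m)
  N <- as.integer(floor(360 / cfg$phi_deg))
  thetas <- (seq_len(N) - 1L) * cfg$phi_deg
  views <- lapply(thetas, function(th) {
    rasterize(rotate_neuron(aligned, th), cfg, theta_deg = th)
  })
  structure(list(views = views, theta_deg = thetas, config = cfg, n = N),
            class = "view_stack")
}

#' @export
print.view_stack <- function(x, ...) {
  cat("view stack: ", x$n, " binary views of ",
      x$config$image_size, "x", x$config$image_size,
      " px (phi = ", x$config$phi_deg, " deg)\n", sep = "")
  invisible(x)
}

#' Write a view stack to PNG files
#'
#' One 8-bit grayscale PNG per view, named
#' `<stem>_view<k>_theta<deg>.png` (foreground white).
#'
#' @param stack a `"view_stack"`.
#' @param dir output directory (created if missing).
#' @param stem file-name stem.
#' @return character vector of the written paths, invisibly.
#' @export
write_views <- function(stack, dir, stem = "neuron") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(stack$n)
  for (k in seq_len(stack$n)) {
    paths[k] <- file.path(dir, sprintf("%s_view%d_theta%g.png",
                                       stem, k - 1L, stack$theta_deg[k]))
    png::writePNG(stack$views[[k]] * 1.0, paths[k])
  }
  invisible(paths)
}
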