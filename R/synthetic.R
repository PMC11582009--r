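# Synthetic labeled neuron morphologies.
#
# Classes are defined by branching statistics: at each elongation step a tip
# advances by a jittered step length along a direction blending its previous
# heading, a class-level trunk bias and isotropic noise; after each step it
# may bifurcate (probability branch_prob) until max_depth bifurcation levels.
# The generator is deterministic given (spec, seed), which makes the whole
# pipeline trainable and testable at desk scale with no downloads. It is not a
# biophysical simulator: no soma geometry, diameter taper, spines or tortuous
# branch-path statistics of real reconstructions.

#' Specification of a synthetic morphology class
#'
#' @param class_name class label attached to generated morphologies.
#' @param branch_prob probability of bifurcating after each elongation step.
#' @param segment_length_mean,segment_length_sd step length (um), Gaussian
#'   jitter; lengths are floored at 20% of the mean.
#' @param max_depth maximum number of bifurcation levels.
#' @param n_steps elongation steps per branch section before it terminates.
#' @param n_stems first-order branches leaving the soma.
#' @param trunk_bias 3-vector growth-direction bias (normalized internally;
#'   zero vector means unbiased growth).
#' @param apical_trunk logical; give the first stem a strong straight trunk
#'   along the bias direction, as in pyramidal-like arbors.
#' @param branch_angle_deg mean opening half-angle at bifurcations.
#' @return list of class `"morph_class_spec"`.
#' @export
morph_class_spec <- function(class_name,
                             branch_prob = 0.25,
                             segment_length_mean = 18,
                             segment_length_sd = 4,
                             max_depth = 4L,
                             n_steps = 6L,
                             n_stems = 4L,
                             trunk_bias = c(0, 1, 0),
                             apical_trunk = FALSE,
                             branch_angle_deg = 40) {
  stopifnot(branch_prob >= 0, branch_prob <= 1,
            max_depth >= 1L, n_stems >= 1L, n_steps >= 1L,
            segment_length_mean > 0, length(trunk_bias) == 3L)
  nb <- sqrt(sum(trunk_bias^2))
  if (nb > 0) trunk_bias <- trunk_bias / nb
  structure(list(class_name = class_name, branch_prob = branch_prob,
                 segment_length_mean = segment_length_mean,
                 segment_length_sd = segment_length_sd,
                 max_depth = as.integer(max_depth),
                 n_steps = as.integer(n_steps),
                 n_stems = as.integer(n_stems),
                 trunk_bias = trunk_bias,
                 apical_trunk = isTRUE(apical_trunk),
                 branch_angle_deg = branch_angle_deg),
            class = "morph_class_spec")
}

#' Preset class specifications
#'
#' `"separable-3"`: three classes with strongly different branching
#' probability, stem count and growth bias, visually and statistically
#' distinct (a depth-1 decision stump on branch count separates them well).
#' `"confusable-2"`: two near-identical classes for robustness checks.
#'
#' @param name preset name.
#' @return list of [morph_class_spec()] objects.
#' @export
preset_morph_specs <- function(name = c("separable-3", "confusable-2")) {
  name <- match.arg(name)
  if (name == "separable-3") {
    list(
      morph_class_spec("sparse", branch_prob = 0.04,
                       segment_length_mean = 24, segment_length_sd = 5,
                       max_depth = 3L, n_steps = 8L, n_stems = 3L,
                       trunk_bias = c(0, 1, 0), apical_trunk = TRUE),
      morph_class_spec("tufted", branch_prob = 0.25,
                       segment_length_mean = 18, segment_length_sd = 4,
                       max_depth = 4L, n_steps = 6L, n_stems = 4L,
                       trunk_bias = c(0.2, 0.6, 0.6), apical_trunk = FALSE),
      morph_class_spec("bushy", branch_prob = 0.60,
                       segment_length_mean = 12, segment_length_sd = 3,
                       max_depth = 5L, n_steps = 5L, n_stems = 5L,
                       trunk_bias = c(0, 0, 0), apical_trunk = FALSE)
    )
  } else {
    list(
      morph_class_spec("typeA", branch_prob = 0.30),
      morph_class_spec("typeB", branch_prob = 0.33)
    )
  }
}

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) c(0, 0, 1) else v / n
}

## a random unit vector roughly perpendicular to d
rand_perp <- function(d) {
  r <- unit3(stats::rnorm(3))
  unit3(r - sum(r * d) * d)
}

#' Grow one synthetic neuron
#'
#' Deterministic given `(spec, seed)`. The soma is node 1 (type 1, parent -1)
#' at the origin; each stem grows recursively by `n_steps`-step sections with
#' stochastic bifurcation after each step, up to `max_depth` bifurcation
#' levels.
#'
#' @param spec a [morph_class_spec()].
#' @param seed integer random seed.
#' @return a [neuron()] carrying `spec$class_name` as label.
#' @export
grow_neuron <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "morph_class_spec"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)

  ids <- integer(0); types <- integer(0); parents <- integer(0)
  xyz <- matrix(0, 0L, 3L); radii <- numeric(0)
  add_node <- function(pos, type, parent, radius) {
    id <- length(ids) + 1L
    ids[[id]] <<- id
    types[[id]] <<- type
    parents[[id]] <<- parent
    xyz <<- rbind(xyz, pos)
    radii[[id]] <<- radius
    id
  }
  soma <- add_node(c(0, 0, 0), 1L, -1L, 6)

  step_len <- function(scale = 1) {
    max(stats::rnorm(1, spec$segment_length_mean, spec$segment_length_sd),
        0.2 * spec$segment_length_mean) * scale
  }

  grow_branch <- function(parent, pos, dir, depth, straight = FALSE) {
    for (s in seq_len(spec$n_steps)) {
      dir <- if (straight) {
        unit3(0.9 * dir + 0.1 * unit3(stats::rnorm(3)))
      } else {
        unit3(0.7 * dir + 0.15 * spec$trunk_bias + 0.3 * unit3(stats::rnorm(3)))
      }
      pos <- pos + step_len(if (straight) 1.5 else 1) * dir
      parent <- add_node(pos, 3L, parent, 0.5)
      if (depth < spec$max_depth && stats::runif(1) < spec$branch_prob) {
        ang <- (spec$branch_angle_deg * pi / 180) * stats::runif(1, 0.6, 1.4)
        perp <- rand_perp(dir)
        d1 <- unit3(cos(ang) * dir + sin(ang) * perp)
        d2 <- unit3(cos(ang) * dir - sin(ang) * perp)
        grow_branch(parent, pos, d1, depth + 1L)
        grow_branch(parent, pos, d2, depth + 1L)
        return(invisible(NULL))
      }
    }
    invisible(NULL)
  }

  for (stem in seq_len(spec$n_stems)) {
    if (spec$apical_trunk && stem == 1L) {
      d0 <- unit3(spec$trunk_bias + 0.05 * stats::rnorm(3))
      grow_branch(soma, c(0, 0, 0), d0, 0L, straight = TRUE)
    } else {
      bias <- if (sum(spec$trunk_bias^2) > 0) spec$trunk_bias else c(0, 0, 0)
      d0 <- unit3(unit3(stats::rnorm(3)) + 0.8 * bias)
      grow_branch(soma, c(0, 0, 0), d0, 0L)
    }
  }

  nodes <- data.frame(id = ids, type = types,
                      x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                      radius = radii, parent = parents)
  neuron(nodes, label = spec$class_name,
         source = sprintf("synthetic:%s:seed%d", spec$class_name, seed))
}

#' Generate a balanced labeled synthetic dataset
#'
#' Grows `per_class` morphologies per specification. When `dir` is given, the
#' morphologies are written as SWC files next to a `manifest.csv`
#' (columns path, label, seed); in-memory morphologies are always returned.
#'
#' @param specs list of [morph_class_spec()] (or a preset name for
#'   [preset_morph_specs()]).
#' @param per_class morphologies per class (>= 1).
#' @param seed master seed; per-morphology seeds are derived from it and
#'   recorded in the manifest.
#' @param dir optional output directory for SWC files and the manifest.
#' @return list of class `"synthetic_dataset"`: `morphologies` (list of
#'   neurons), `labels` (character), `manifest` (data frame).
#' @export
make_dataset <- function(specs, per_class, seed = 1L, dir = NULL) {
  if (is.character(specs) && length(specs) == 1L) {
    specs <- preset_morph_specs(specs)
  }
  if (per_class < 1L) stop("per_class must be >= 1")
  n <- length(specs) * per_class
  morphs <- vector("list", n)
  labels <- character(n)
  seeds <- integer(n)
  paths <- rep(NA_character_, n)
  i <- 0L
  for (ci in seq_along(specs)) {
    for (r in seq_len(per_class)) {
      i <- i + 1L
      seeds[i] <- derive_seed(seed, 1000L * ci + r)
      morphs[[i]] <- grow_neuron(specs[[ci]], seed = seeds[i])
      labels[i] <- specs[[ci]]$class_name
    }
  }
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_len(n)) {
      paths[i] <- file.path(dir, sprintf("%s_%03d.swc", labels[i],
                                         ((i - 1L) %% per_class) + 1L))
      write_swc(morphs[[i]], paths[i])
    }
  }
  manifest <- data.frame(path = paths, label = labels, seed = seeds,
                         stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  structure(list(morphologies = morphs, labels = labels, manifest = manifest),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic morphology dataset: ", length(x$morphologies),
      " neurons, classes: ", paste(unique(x$labels), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Branch statistics of a morphology
#'
#' @param m a `"neuron"` object.
#' @return named numeric vector: `n_nodes`, `n_branch_points` (nodes with >= 2
#'   children), `n_tips`, `total_length` (um of cable).
#' @export
branch_stats <- function(m) {
  nd <- m$nodes
  seg <- neuron_segments(m)
  kids <- tabulate(seg[, "parent"], nbins = nrow(nd))
  len <- if (nrow(seg)) {
    d <- as.matrix(nd[seg[, "child"], c("x", "y", "z")]) -
      as.matrix(nd[seg[, "parent"], c("x", "y", "z")])
    sum(sqrt(rowSums(d * d)))
  } else 0
  c(n_nodes = nrow(nd),
    n_branch_points = sum(kids >= 2L),
    n_tips = sum(kids == 0L & nd$parent != -1),
    total_length = len)
}
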