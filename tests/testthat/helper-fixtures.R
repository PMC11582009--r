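# Shared fixtures: a tiny model configuration whose network runs in
# milliseconds, a small two-class synthetic dataset, and a cache so expensive
# objects are built once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, .fixture_env)) assign(name, build(), .fixture_env)
  get(name, .fixture_env)
}

tiny_config <- function(epochs = 4L, ...) {
  mwfnet_config(phi_deg = 120, image_size = 16L,
                backbone_channels = c(4L, 6L), hidden = 10L,
                batch_size = 4L, epochs = epochs, ...)
}

## independent connected-component oracle (8-connectivity, BFS flood fill)
count_components8 <- function(img) {
  H <- nrow(img); W <- ncol(img)
  lab <- matrix(0L, H, W)
  k <- 0L
  for (start in which(img != 0)) {
    if (lab[start]) next
    k <- k + 1L
    stack <- start
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (lab[cur]) next
      lab[cur] <- k
      r <- (cur - 1L) %% H + 1L
      cc <- (cur - 1L) %/% H + 1L
      for (dr in -1:1) {
        for (dc in -1:1) {
          rr <- r + dr; c2 <- cc + dc
          if (rr >= 1L && rr <= H && c2 >= 1L && c2 <= W) {
            id <- rr + (c2 - 1L) * H
            if (img[id] != 0 && !lab[id]) stack <- c(stack, id)
          }
        }
      }
    }
  }
  k
}

tiny_specs <- function() {
  list(
    morph_class_spec("thin", branch_prob = 0.05, max_depth = 2L,
                     n_steps = 5L, n_stems = 2L, trunk_bias = c(0, 1, 0)),
    morph_class_spec("full", branch_prob = 0.7, max_depth = 3L,
                     n_steps = 3L, n_stems = 3L, trunk_bias = c(0, 0, 0))
  )
}

tiny_dataset <- function() {
  fixture("tiny_dataset", function() make_dataset(tiny_specs(), 6L, seed = 5L))
}

tiny_views <- function() {
  fixture("tiny_views", function() {
    project_dataset(tiny_dataset(), tiny_config())
  })
}

## a deterministic random morphology for projection tests
random_neuron <- function(seed = 1L) {
  grow_neuron(morph_class_spec("rand", branch_prob = 0.3, max_depth = 3L,
                               n_steps = 4L, n_stems = 3L), seed = seed)
}

## neuron from bare coordinates, chained as a path
path_neuron <- function(xyz) {
  n <- nrow(xyz)
  neuron(data.frame(id = seq_len(n), type = 3L,
                    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                    radius = 1, parent = c(-1L, seq_len(n - 1L))))
}
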