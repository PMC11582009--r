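# Reading, validating and writing SWC neuron reconstructions.
#
# The SWC format is the de-facto standard for digitally reconstructed neurons:
# one whitespace-separated record per node with seven columns
# (id, structure type, x, y, z, radius, parent id), '#' starting a comment,
# parent id -1 marking a root. A morphology is held as a plain data frame of
# nodes wrapped in a light "neuron" S3 class.

#' Construct a neuron morphology from a node table
#'
#' @param nodes data frame with columns `id`, `type`, `x`, `y`, `z`, `radius`,
#'   `parent` (one row per SWC node, in file order).
#' @param label optional class label attached to the morphology.
#' @param source optional character, provenance of the reconstruction.
#' @param validate logical; check the structural invariants (unique ids,
#'   existing parents, acyclicity, at least one root).
#' @return object of class `"neuron"`: a list with elements `nodes`, `label`
#'   and `source`.
#' @export
neuron <- function(nodes, label = NULL, source = NULL, validate = TRUE) {
  stopifnot(is.data.frame(nodes))
  required <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!all(required %in% names(nodes))) {
    stop("node table must have columns: ", paste(required, collapse = ", "))
  }
  nodes <- nodes[required]
  obj <- structure(list(nodes = nodes, label = label, source = source),
                   class = "neuron")
  if (validate) validate_neuron(obj)
  obj
}

#' Validate the structural invariants of a neuron morphology
#'
#' Checks: at least one node; node ids unique and >= 1; radii nonnegative;
#' every non-root parent id present in the node set; no node its own parent;
#' the parent relation acyclic. Multiple roots (a forest) are accepted with a
#' warning, since repository SWC files of variable reconstruction quality
#' frequently contain disconnected arbors.
#'
#' @param m a `"neuron"` object.
#' @return `m`, invisibly; errors on violation.
#' @export
validate_neuron <- function(m) {
  nd <- m$nodes
  n <- nrow(nd)
  if (n < 1L) stop("morphology must contain at least one node")
  if (anyDuplicated(nd$id)) stop("duplicate node ids in morphology")
  if (any(nd$id < 1)) stop("node ids must be >= 1")
  if (any(nd$radius < 0)) stop("negative radius in morphology")
  if (any(nd$parent == nd$id)) stop("node listed as its own parent")
  roots <- nd$parent == -1
  dangling <- !roots & !(nd$parent %in% nd$id)
  if (any(dangling)) {
    stop("dangling parent id(s): ",
         paste(unique(nd$parent[dangling]), collapse = ", "))
  }
  if (!any(roots)) stop("morphology has no root (parent id -1)")
  if (sum(roots) > 1L) {
    warning("morphology has ", sum(roots), " roots (forest); accepting")
  }
  ## acyclicity: BFS from the roots over the child adjacency; with single
  ## parents and no dangling references, any unreached node lies on a cycle
  pos <- match(nd$parent, nd$id)        # NA for roots
  children <- split(seq_len(n), pos)
  visited <- rep(FALSE, n)
  queue <- which(roots)
  while (length(queue)) {
    visited[queue] <- TRUE
    queue <- unlist(children[as.character(queue)], use.names = FALSE)
    queue <- queue[!visited[queue]]
  }
  if (!all(visited)) stop("cycle detected in parent relation")
  invisible(m)
}

#' Read an SWC reconstruction
#'
#' Parses the 7-column whitespace-separated SWC format. Lines starting with
#' `#` and blank lines are ignored; Windows line endings and arbitrary
#' whitespace are tolerated. Node order is preserved as read.
#'
#' @param file path to an SWC file (ignored when `text` is given).
#' @param text optional character scalar holding SWC content directly.
#' @param label optional class label to attach.
#' @return a [neuron()] object.
#' @examples
#' read_swc(text = "1 1 0 0 0 1 -1\n2 3 0 10 0 0.5 1")
#' @export
read_swc <- function(file = NULL, text = NULL, label = NULL) {
  if (is.null(text)) {
    if (is.null(file)) stop("either 'file' or 'text' must be given")
    lines <- readLines(file, warn = FALSE)
    src <- file
  } else {
    lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
    src <- NULL
  }
  lines <- sub("\r$", "", lines)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("SWC input contains no node records")
  toks <- strsplit(trimws(lines), "\\s+")
  ncols <- lengths(toks)
  if (any(ncols != 7L)) {
    bad <- which(ncols != 7L)[1L]
    stop("malformed SWC line ", lineno[bad], ": expected 7 columns, found ",
         ncols[bad])
  }
  vals <- suppressWarnings(
    matrix(as.numeric(unlist(toks)), ncol = 7L, byrow = TRUE)
  )
  if (anyNA(vals)) {
    bad <- which(apply(is.na(vals), 1L, any))[1L]
    stop("malformed SWC line ", lineno[bad], ": non-numeric field")
  }
  nodes <- data.frame(
    id = as.integer(vals[, 1L]),
    type = as.integer(vals[, 2L]),
    x = vals[, 3L], y = vals[, 4L], z = vals[, 5L],
    radius = vals[, 6L],
    parent = as.integer(vals[, 7L])
  )
  neuron(nodes, label = label, source = src)
}

#' Write a neuron morphology to an SWC file
#'
#' Coordinates and radii are printed with six decimals; reading the file back
#' reproduces the node table at that precision.
#'
#' @param m a `"neuron"` object.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_swc <- function(m, file) {
  validate_neuron(m)
  nd <- m$nodes
  rec <- sprintf("%d %d %.6f %.6f %.6f %.6f %d",
                 nd$id, nd$type, nd$x, nd$y, nd$z, nd$radius, nd$parent)
  writeLines(c("# id type x y z radius parent", rec), con = file)
  invisible(file)
}

#' @export
print.neuron <- function(x, ...) {
  nd <- x$nodes
  cat("SWC neuron morphology: ", nrow(nd), " nodes, ",
      sum(nd$parent == -1), " root(s)", sep = "")
  if (!is.null(x$label)) cat(", label '", x$label, "'", sep = "")
  cat("\n")
  ext <- vapply(nd[c("x", "y", "z")], function(v) diff(range(v)), 0)
  cat(sprintf("  extent (um): x %.1f  y %.1f  z %.1f\n",
              ext[1], ext[2], ext[3]))
  invisible(x)
}

## segment list: matrix with one row per child-parent edge (child, parent row)
neuron_segments <- function(m) {
  nd <- m$nodes
  child <- which(nd$parent != -1)
  cbind(child = child, parent = match(nd$parent[child], nd$id))
}
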