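#' Read a neuron skeleton from an SWC file
#'
#' Parses the standard 7-column SWC dialect (node id, structure tag, x, y,
#' z, radius, parent id; `#` comments; whitespace separated). Coordinates
#' are in micrometres. A parent id of -1 marks the root (soma). Missing
#' radius values (encoded as negative or NA) are kept as `NA`, not zero.
#'
#' @param path path to an SWC file.
#' @return A `neuron_skeleton` object: a list with `nodes` (data.frame
#'   with columns `id`, `type`, `x`, `y`, `z`, `radius`, `parent`) and
#'   `soma` (the root node id).
#' @export
read_swc <- function(path) {
  if (!file.exists(path)) stop("SWC file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("empty SWC file: ", path)
  fields <- strsplit(lines, "[[:space:]]+")
  bad <- which(vapply(fields, length, 1L) < 7L)
  if (length(bad)) stop("malformed SWC line ", bad[1], " in ", path)
  m <- matrix(as.numeric(unlist(lapply(fields, `[`, 1:7))),
              ncol = 7L, byrow = TRUE)
  nodes <- data.frame(id = as.integer(m[, 1]), type = as.integer(m[, 2]),
                      x = m[, 3], y = m[, 4], z = m[, 5],
                      radius = m[, 6], parent = as.integer(m[, 7]))
  nodes$radius[!is.na(nodes$radius) & nodes$radius < 0] <- NA_real_
  neuron_skeleton(nodes)
}

#' Construct and validate a neuron skeleton
#'
#' Checks the tree invariants: exactly one root (parent -1), every
#' referenced parent exists and precedes no cycle, positions finite.
#'
#' @param nodes data.frame with columns `id`, `type`, `x`, `y`, `z`,
#'   `radius`, `parent`.
#' @return A validated `neuron_skeleton` object.
#' @export
neuron_skeleton <- function(nodes) {
  stopifnot(is.data.frame(nodes),
            all(c("id", "x", "y", "z", "parent") %in% names(nodes)))
  if (!"type" %in% names(nodes)) nodes$type <- 0L
  if (!"radius" %in% names(nodes)) nodes$radius <- NA_real_
  if (anyDuplicated(nodes$id))
    stop("duplicated node id: ", nodes$id[anyDuplicated(nodes$id)])
  if (!all(is.finite(as.matrix(nodes[, c("x", "y", "z")]))))
    stop("non-finite node coordinates")
  roots <- nodes$id[nodes$parent == -1L]
  if (length(roots) != 1L)
    stop("skeleton must have exactly one root, found ", length(roots))
  idx <- match(nodes$parent, nodes$id)
  dangling <- which(nodes$parent != -1L & is.na(idx))
  if (length(dangling))
    stop("node ", nodes$id[dangling[1]], " references missing parent ",
         nodes$parent[dangling[1]])
  # cycle check: follow parents from every node; depth bounded by n
  n <- nrow(nodes)
  depth <- rep.int(NA_integer_, n)
  depth[nodes$parent == -1L] <- 0L
  for (pass in seq_len(n)) {
    todo <- which(is.na(depth))
    if (!length(todo)) break
    p <- idx[todo]
    ready <- !is.na(depth[p])
    depth[todo[ready]] <- depth[p[ready]] + 1L
    if (!any(ready))
      stop("cycle detected involving node ", nodes$id[todo[1]])
  }
  structure(list(nodes = nodes, soma = roots), class = "neuron_skeleton")
}

#' Write a skeleton to an SWC file
#'
#' @param skeleton a `neuron_skeleton`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(skeleton, path) {
  nd <- skeleton$nodes
  r <- ifelse(is.na(nd$radius), -1, nd$radius)
  lines <- sprintf("%d %d %.9g %.9g %.9g %.9g %d",
                   nd$id, nd$type, nd$x, nd$y, nd$z, r, nd$parent)
  writeLines(c("# SWC written by flybrainsim", lines), path)
  invisible(path)
}

#' @export
print.neuron_skeleton <- function(x, ...) {
  cat("<neuron_skeleton> ", nrow(x$nodes), " nodes, soma id ", x$soma,
      ", total length ", format(total_skeleton_length(x), digits = 6),
      " um\n", sep = "")
  invisible(x)
}

#' Total skeleton length
#'
#' Sum of Euclidean lengths of all parent-child segments, in
#' micrometres. The root contributes no segment.
#'
#' @param skeleton a `neuron_skeleton`.
#' @return Numeric scalar (um), >= 0.
#' @export
total_skeleton_length <- function(skeleton) {
  sum(segment_lengths(skeleton))
}

# Euclidean length of the segment ending at each node (0 for the root).
segment_lengths <- function(skeleton) {
  nd <- skeleton$nodes
  pidx <- match(nd$parent, nd$id)
  has <- !is.na(pidx)
  len <- numeric(nrow(nd))
  len[has] <- sqrt((nd$x[has] - nd$x[pidx[has]])^2 +
                   (nd$y[has] - nd$y[pidx[has]])^2 +
                   (nd$z[has] - nd$z[pidx[has]])^2)
  len
}

# Geodesic (along-skeleton) distance from every node to the soma.
path_dist_to_soma <- function(skeleton) {
  nd <- skeleton$nodes
  len <- segment_lengths(skeleton)
  pidx <- match(nd$parent, nd$id)
  d <- rep.int(NA_real_, nrow(nd))
  d[nd$parent == -1L] <- 0
  # nodes were validated acyclic; resolve in topological passes
  while (anyNA(d)) {
    todo <- which(is.na(d))
    ready <- todo[!is.na(d[pidx[todo]])]
    d[ready] <- d[pidx[ready]] + len[ready]
  }
  d
}

# Number of children per node (named by node id).
n_children <- function(skeleton) {
  nd <- skeleton$nodes
  cnt <- table(factor(nd$parent[nd$parent != -1L], levels = nd$id))
  as.integer(cnt)
}

#' Terminal (leaf) node ids of a skeleton
#' @param skeleton a `neuron_skeleton`.
#' @return Integer vector of node ids with no children.
#' @export
terminal_ids <- function(skeleton) {
  skeleton$nodes$id[n_children(skeleton) == 0L & skeleton$nodes$parent != -1L]
}

# Branch order of every node: number of branch points (>=2 children,
# soma excluded) on the path from the soma to the node (exclusive).
branch_orders <- function(skeleton) {
  nd <- skeleton$nodes
  pidx <- match(nd$parent, nd$id)
  is_bp <- n_children(skeleton) >= 2L
  ord <- rep.int(NA_integer_, nrow(nd))
  ord[nd$parent == -1L] <- 0L
  while (anyNA(ord)) {
    todo <- which(is.na(ord))
    ready <- todo[!is.na(ord[pidx[todo]])]
    ord[ready] <- ord[pidx[ready]] + as.integer(is_bp[pidx[ready]])
  }
  ord
}

# All node ids in the subtree rooted at `root_id` (inclusive).
subtree_ids <- function(skeleton, root_id) {
  nd <- skeleton$nodes
  kids <- split(nd$id, factor(nd$parent, levels = nd$id))
  out <- integer(0)
  stack <- root_id
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    out <- c(out, v)
    ch <- kids[[as.character(v)]]
    if (length(ch)) stack <- c(stack, ch)
  }
  out
}
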