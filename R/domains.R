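#' Split a skeleton into arbor domains
#'
#' Domains are candidate axonal/dendritic territories classified
#' independently by the polarity classifier. Each primary neurite (child
#' subtree of the soma) starts as one domain; a domain is then
#' recursively split at its first branch point whenever its sibling
#' subtrees' terminal centroids are further apart than a gap threshold.
#' The `granularity` knob is dimensionless and maps to the gap threshold
#' as `gap_threshold = gap_scale / granularity` micrometres, so a
#' *smaller* granularity yields *fewer, coarser* domains. The domain
#' count is a non-increasing function of the gap threshold.
#'
#' @param skeleton a `neuron_skeleton`.
#' @param granularity dimensionless granularity (default 0.001).
#' @param gap_scale scale factor, um (default 1).
#' @param gap_threshold explicit centroid-gap threshold in um; overrides
#'   `granularity` when given.
#' @return A list of `arbor_domain` objects, each a list with
#'   `member_node_ids`, `terminal_ids` and `label` (initially
#'   "unassigned"). The union of domains covers all terminals and the
#'   domains are disjoint.
#' @export
split_arbor_domains <- function(skeleton, granularity = 0.001,
                                gap_scale = 1, gap_threshold = NULL) {
  if (is.null(gap_threshold)) {
    stopifnot(granularity > 0)
    gap_threshold <- gap_scale / granularity
  }
  nd <- skeleton$nodes
  kids <- split(nd$id, factor(nd$parent, levels = nd$id))
  primaries <- kids[[as.character(skeleton$soma)]]
  if (is.null(primaries) || length(primaries) == 0L) {
    return(list(new_domain(skeleton, skeleton$soma)))
  }
  terms <- terminal_ids(skeleton)
  pos <- nd[, c("x", "y", "z")]
  rownames(pos) <- nd$id

  centroid <- function(ids) {
    t_ids <- intersect(ids, terms)
    if (!length(t_ids)) t_ids <- ids
    colMeans(pos[as.character(t_ids), , drop = FALSE])
  }

  # descend from `root_id`: follow the unbranched chain to the first
  # branch point; split there if the sibling centroids are far apart
  split_rec <- function(root_id, chain = integer(0)) {
    v <- root_id
    repeat {
      chain <- c(chain, v)
      ch <- kids[[as.character(v)]]
      if (is.null(ch) || length(ch) == 0L)
        return(list(chain))                      # pure chain, one domain
      if (length(ch) >= 2L) break
      v <- ch
    }
    subtrees <- lapply(ch, function(c0) subtree_ids(skeleton, c0))
    cents <- vapply(subtrees, centroid, numeric(3))
    gap <- 0
    for (i in seq_along(ch)) for (j in seq_len(i - 1L))
      gap <- max(gap, sqrt(sum((cents[, i] - cents[, j])^2)))
    if (gap > gap_threshold) {
      out <- list()
      for (i in seq_along(ch)) {
        sub <- split_rec(ch[i], if (i == 1L) chain else integer(0))
        out <- c(out, sub)
      }
      out
    } else {
      list(c(chain, unlist(subtrees)))
    }
  }

  groups <- list()
  for (p in primaries) groups <- c(groups, split_rec(p))
  lapply(groups, function(ids) new_domain(skeleton, ids))
}

new_domain <- function(skeleton, ids) {
  structure(list(member_node_ids = ids,
                 terminal_ids = intersect(ids, terminal_ids(skeleton)),
                 label = "unassigned"),
            class = "arbor_domain")
}
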