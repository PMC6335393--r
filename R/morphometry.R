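#' Morphometric features of an arbor domain
#'
#' Computes the 11 skeleton features used by the linear polarity
#' classifier, either for a whole skeleton or for a subset of its nodes
#' (an arbor domain). Conventions:
#'
#' * path lengths are geodesic distances along the skeleton to the soma;
#' * branch order of a node is the number of branch points (nodes with
#'   two or more children) on the path from the soma to that node;
#' * terminal statistics (`path_length_to_soma`, `mean_branch_order`,
#'   `max_path_length`, `max_branch_order`) are taken over the domain's
#'   terminal nodes; `mean_path_length` is taken over all domain nodes;
#' * `mean_voronoi_volume` is the mean volume of the Voronoi cells of the
#'   domain's terminal points clipped to the domain's convex hull; since
#'   those cells tile the hull, it equals `convex_hull_volume` divided by
#'   the number of terminals;
#' * `mean_branch_angle` (radians) averages, over branch points, the
#'   angle between the two daughter segment directions;
#' * statistics over empty sets (e.g. no branch points) are 0, not NaN.
#'
#' @param skeleton a `neuron_skeleton`.
#' @param node_ids node ids of the domain; `NULL` means all nodes.
#' @return Named numeric vector of length 11 (see
#'   [morphometry_feature_names()]).
#' @export
compute_morphometry <- function(skeleton, node_ids = NULL) {
  nd <- skeleton$nodes
  if (is.null(node_ids)) node_ids <- nd$id
  if (length(node_ids) == 0L) stop("empty domain")
  if (!all(node_ids %in% nd$id)) stop("domain nodes not in skeleton")
  in_dom <- nd$id %in% node_ids

  dist_soma <- path_dist_to_soma(skeleton)
  bord <- branch_orders(skeleton)
  seglen <- segment_lengths(skeleton)
  pidx <- match(nd$parent, nd$id)

  # children counts restricted to the domain
  par_in <- nd$parent[in_dom & nd$parent != -1L]
  par_in <- par_in[par_in %in% node_ids]
  kid_cnt <- table(factor(par_in, levels = nd$id[in_dom]))
  term <- in_dom & nd$id %in% names(kid_cnt)[kid_cnt == 0L]
  bp <- in_dom & nd$id %in% names(kid_cnt)[kid_cnt >= 2L]
  n_term <- sum(term)
  n_bp <- sum(bp)

  mean0 <- function(x) if (length(x)) mean(x) else 0
  max0 <- function(x) if (length(x)) max(x) else 0

  hull_vol <- if (sum(in_dom) >= 4L)
    .convex_hull_volume_cpp(as.matrix(nd[in_dom, c("x", "y", "z")])) else 0

  # segments fully inside the domain
  seg_in <- in_dom & !is.na(pidx) & nd$parent %in% node_ids
  sum_seg <- sum(seglen[seg_in])

  # branch angle between the first two in-domain daughters
  angles <- numeric(0)
  if (n_bp) {
    for (b in which(bp)) {
      ch <- which(seg_in & pidx == b)
      if (length(ch) >= 2L) {
        v1 <- c(nd$x[ch[1]] - nd$x[b], nd$y[ch[1]] - nd$y[b], nd$z[ch[1]] - nd$z[b])
        v2 <- c(nd$x[ch[2]] - nd$x[b], nd$y[ch[2]] - nd$y[b], nd$z[ch[2]] - nd$z[b])
        den <- sqrt(sum(v1^2)) * sqrt(sum(v2^2))
        if (den > 0)
          angles <- c(angles, acos(pmin(1, pmax(-1, sum(v1 * v2) / den))))
      }
    }
  }

  # branches = maximal unbranched paths; each ends at exactly one
  # terminal or branch point, except that the domain's local root(s)
  # (nodes whose parent lies outside the domain) end none
  local_root <- in_dom & (nd$parent == -1L | !(nd$parent %in% node_ids))
  n_branches <- max(1L, n_term + n_bp - sum(local_root & (term | bp)))

  c(path_length_to_soma = mean0(dist_soma[term]),
    mean_branch_order = mean0(bord[term]),
    max_path_length = max0(dist_soma[term]),
    max_branch_order = max0(bord[term]),
    convex_hull_volume = hull_vol,
    n_branch_points = as.numeric(n_bp),
    mean_path_length = mean0(dist_soma[in_dom]),
    sum_segment_lengths = sum_seg,
    mean_voronoi_volume = if (n_term) hull_vol / n_term else 0,
    mean_branch_angle = mean0(angles),
    mean_branch_length = sum_seg / n_branches)
}

#' Names of the morphometric features, in canonical order
#' @return Character vector of length 11.
#' @export
morphometry_feature_names <- function() {
  c("path_length_to_soma", "mean_branch_order", "max_path_length",
    "max_branch_order", "convex_hull_volume", "n_branch_points",
    "mean_path_length", "sum_segment_lengths", "mean_voronoi_volume",
    "mean_branch_angle", "mean_branch_length")
}
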