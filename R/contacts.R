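#' Count axo-dendritic contact points between two neurons
#'
#' A contact point is a pair (axonal segment of neuron `i`, dendritic
#' segment of neuron `k`) whose minimum segment-to-segment Euclidean
#' distance is at most `max_distance`. Segments are the straight lines
#' between consecutive skeleton nodes; each segment carries the polarity
#' label of its child node. The count is directional: `N_ik` (axons of
#' `i` vs dendrites of `k`) is computed independently of `N_ki`.
#'
#' @param neuron_i,neuron_k `neuron_skeleton` objects.
#' @param labels_i,labels_k named character vectors of node polarity
#'   labels ("axon"/"dendrite"), as produced by
#'   [classify_skeleton_polarity()] (`node_labels`).
#' @param max_distance distance criterion in um (default 13).
#' @param per_branch if `TRUE`, aggregate to branch pairs: each pair of
#'   (axonal branch, dendritic branch) with at least one segment pair in
#'   range counts once.
#' @return Integer count `N_ik`.
#' @export
pairwise_contact_points <- function(neuron_i, neuron_k, labels_i, labels_k,
                                    max_distance = 13, per_branch = FALSE) {
  stopifnot(max_distance > 0)
  a <- polarity_segments(neuron_i, labels_i, "axon")
  d <- polarity_segments(neuron_k, labels_k, "dendrite")
  if (nrow(a$p0) == 0L || nrow(d$p0) == 0L) return(0L)
  .count_contacts_cpp(a$p0, a$p1, d$p0, d$p1, max_distance,
                      a$branch, d$branch, per_branch)
}

# Extract segments of one polarity as start/end matrices plus branch ids
# (branch id = nearest upstream branch point / local root of the child
# node). Errors if the skeleton has no labelled nodes of either class.
polarity_segments <- function(skeleton, labels, which_label) {
  nd <- skeleton$nodes
  if (is.null(labels) || !any(labels %in% c("axon", "dendrite")))
    stop("skeleton is not polarity-labelled")
  lab <- labels[as.character(nd$id)]
  pidx <- match(nd$parent, nd$id)
  sel <- which(!is.na(pidx) & !is.na(lab) & lab == which_label)
  # branch id: index of the nearest ancestor that is a branch point
  bord <- branch_orders(skeleton)
  is_bp <- n_children(skeleton) >= 2L
  branch_of <- integer(nrow(nd))
  ord <- order(path_dist_to_soma(skeleton))   # parents before children
  for (v in ord) {
    p <- pidx[v]
    branch_of[v] <- if (is.na(p)) v else if (is_bp[p]) p else branch_of[p]
  }
  list(p0 = as.matrix(nd[pidx[sel], c("x", "y", "z")]),
       p1 = as.matrix(nd[sel, c("x", "y", "z")]),
       branch = branch_of[sel])
}

#' Contact matrix for a set of polarity-labelled skeletons
#'
#' Computes `N_ik` for every ordered pair of distinct neurons. Self
#' pairs are never counted.
#'
#' @param skeletons named list of `neuron_skeleton` objects.
#' @param node_labels named list (same names) of node label vectors.
#' @param max_distance distance criterion, um.
#' @param per_branch see [pairwise_contact_points()].
#' @return A contact data.frame with columns `pre`, `post`, `n`
#'   (non-zero entries only).
#' @export
contact_matrix <- function(skeletons, node_labels, max_distance = 13,
                           per_branch = FALSE) {
  ids <- names(skeletons)
  stopifnot(!is.null(ids), setequal(ids, names(node_labels)))
  rows <- list()
  for (i in ids) for (k in ids) {
    if (i == k) next
    n <- pairwise_contact_points(skeletons[[i]], skeletons[[k]],
                                 node_labels[[i]], node_labels[[k]],
                                 max_distance, per_branch)
    if (n > 0)
      rows[[length(rows) + 1L]] <- data.frame(pre = i, post = k, n = n)
  }
  if (!length(rows)) return(data.frame(pre = character(0),
                                       post = character(0), n = integer(0)))
  do.call(rbind, rows)
}

#' Per-neuron input and output contact totals
#'
#' `input_contacts(i)` is the column total over presynaptic partners
#' (all contacts arriving on `i`'s dendrites); `output_contacts(i)` the
#' row total.
#'
#' @param contacts contact data.frame (`pre`, `post`, `n`).
#' @param neuron_ids optional full id set (ids without contacts get 0).
#' @return data.frame: `neuron_id`, `input_contacts`, `output_contacts`.
#' @export
contact_totals <- function(contacts, neuron_ids = NULL) {
  contacts <- merge_duplicate_contacts(contacts)
  if (is.null(neuron_ids))
    neuron_ids <- sort(unique(c(contacts$pre, contacts$post)))
  inp <- tapply(contacts$n, factor(contacts$post, levels = neuron_ids), sum)
  out <- tapply(contacts$n, factor(contacts$pre, levels = neuron_ids), sum)
  data.frame(neuron_id = neuron_ids,
             input_contacts = as.numeric(ifelse(is.na(inp), 0, inp)),
             output_contacts = as.numeric(ifelse(is.na(out), 0, out)))
}

# Directed pairs counted from several domain combinations are summed
# into one N_ik before any thresholding.
merge_duplicate_contacts <- function(contacts) {
  stopifnot(all(c("pre", "post", "n") %in% names(contacts)))
  if (any(contacts$n < 0)) stop("negative contact counts")
  if (nrow(contacts) == 0L) return(contacts)
  key <- paste(contacts$pre, contacts$post, sep = "\r")
  if (!anyDuplicated(key)) return(contacts)
  agg <- rowsum(contacts$n, key)
  parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
  data.frame(pre = vapply(parts, `[`, "", 1),
             post = vapply(parts, `[`, "", 2), n = agg[, 1],
             row.names = NULL)
}

#' Read/write a contact matrix as TSV
#'
#' Dialect: three columns `pre_id`, `post_id`, `n_contacts`.
#' @param contacts contact data.frame.
#' @param path file path.
#' @return The contact data.frame (read) or `path` invisibly (write).
#' @export
write_contacts_tsv <- function(contacts, path) {
  out <- data.frame(pre_id = contacts$pre, post_id = contacts$post,
                    n_contacts = contacts$n)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contacts_tsv
#' @export
read_contacts_tsv <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t",
                  colClasses = c("character", "character", "numeric"))
  data.frame(pre = x[[1]], post = x[[2]], n = x[[3]])
}
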