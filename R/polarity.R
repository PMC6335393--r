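#' Linear polarity classifier
#'
#' A linear classifier over the 11 morphometric features. The score is
#' `sum(weights * (features - center) / scale) + bias`; a positive score
#' labels the domain as axon, otherwise dendrite (ties at exactly 0 go
#' to dendrite: arbors carry more dendritic than axonal terminals, so
#' the conservative default minimizes expected terminal error).
#'
#' @param weights named numeric vector over the features of
#'   [morphometry_feature_names()].
#' @param bias intercept (default 0).
#' @param center,scale per-feature standardization (defaults: identity).
#' @return A `polarity_classifier` object.
#' @export
polarity_classifier <- function(weights, bias = 0, center = NULL, scale = NULL) {
  fn <- morphometry_feature_names()
  stopifnot(all(names(weights) %in% fn), length(weights) == length(fn))
  weights <- weights[fn]
  if (is.null(center)) center <- setNames(rep(0, length(fn)), fn)
  if (is.null(scale)) scale <- setNames(rep(1, length(fn)), fn)
  stopifnot(all(scale != 0))
  structure(list(weights = weights, bias = bias,
                 center = center[fn], scale = scale[fn]),
            class = "polarity_classifier")
}

#' Default polarity classifier
#'
#' The published feature weights of the linear axon/dendrite classifier,
#' with identity standardization and zero bias. Positive weights
#' correlate with axonal identity (e.g. path length to soma, 0.599);
#' negative weights with dendritic identity (e.g. mean branch order,
#' -0.413). Because the feature standardization used in training is not
#' published, scores from this default are meaningful up to monotone
#' ordering; supply `center`/`scale` fitted to your own data for
#' calibrated decisions.
#'
#' @return A `polarity_classifier`.
#' @export
default_polarity_classifier <- function() {
  polarity_classifier(c(
    path_length_to_soma = 0.599,
    mean_branch_order = -0.413,
    max_path_length = 0.402,
    max_branch_order = 0.303,
    convex_hull_volume = -0.291,
    n_branch_points = -0.285,
    mean_path_length = 0.215,
    sum_segment_lengths = 0.054,
    mean_voronoi_volume = 0.023,
    mean_branch_angle = 0.012,
    mean_branch_length = -0.003))
}

#' Classify one feature vector as axon or dendrite
#'
#' @param features named numeric vector of the 11 morphometric features.
#' @param classifier a `polarity_classifier`.
#' @return List with `label` ("axon" or "dendrite") and `score`.
#' @export
classify_polarity <- function(features, classifier = default_polarity_classifier()) {
  fn <- morphometry_feature_names()
  stopifnot(all(fn %in% names(features)))
  f <- features[fn]
  if (any(!is.finite(f))) stop("non-finite feature value")
  z <- (f - classifier$center) / classifier$scale
  score <- sum(classifier$weights * z) + classifier$bias
  list(label = if (score > 0) "axon" else "dendrite", score = unname(score))
}

#' Classify the polarity of every terminal of a skeleton
#'
#' Splits the skeleton into arbor domains, classifies each domain with
#' the linear classifier, and propagates the domain label to its
#' terminals and member nodes.
#'
#' @param skeleton a `neuron_skeleton`.
#' @param classifier a `polarity_classifier`.
#' @param ... passed to [split_arbor_domains()] (e.g. `granularity`).
#' @param domains optional precomputed list of domains (labels are
#'   recomputed unless a domain's label is already "axon"/"dendrite").
#' @return List with `terminals` (data.frame: `terminal_id`, `label`,
#'   `score`), `node_labels` (named character over all domain member
#'   nodes) and `domains` (labelled domain list).
#' @export
classify_skeleton_polarity <- function(skeleton,
                                       classifier = default_polarity_classifier(),
                                       ..., domains = NULL) {
  if (is.null(domains)) domains <- split_arbor_domains(skeleton, ...)
  node_labels <- character(0)
  rows <- list()
  for (i in seq_along(domains)) {
    d <- domains[[i]]
    if (!d$label %in% c("axon", "dendrite")) {
      feats <- compute_morphometry(skeleton, d$member_node_ids)
      cl <- classify_polarity(feats, classifier)
      d$label <- cl$label
      d$score <- cl$score
    } else if (is.null(d$score)) d$score <- NA_real_
    domains[[i]] <- d
    node_labels[as.character(d$member_node_ids)] <- d$label
    if (length(d$terminal_ids))
      rows[[length(rows) + 1L]] <- data.frame(
        terminal_id = d$terminal_ids, label = d$label, score = d$score)
  }
  terminals <- do.call(rbind, rows)
  list(terminals = terminals[order(terminals$terminal_id), ],
       node_labels = node_labels, domains = domains)
}

#' Classify polarity across a set of skeletons with shared standardization
#'
#' Computes the morphometric features of every arbor domain of every
#' skeleton and, when the classifier carries identity standardization
#' (as the shipped default does, since the training-time feature
#' scaling is unpublished), z-scores the features across the dataset
#' before applying the weights. This makes the published weight signs
#' directly usable on a new dataset: scores are comparable across
#' domains and the axon/dendrite decision becomes a relative one.
#'
#' @param skeletons named list of `neuron_skeleton` objects.
#' @param classifier a `polarity_classifier`.
#' @param granularity passed to [split_arbor_domains()].
#' @param standardize z-score features across the dataset when the
#'   classifier has no standardization of its own (default `TRUE`).
#' @return Named list (per neuron) of [classify_skeleton_polarity()]
#'   results.
#' @export
classify_polarity_batch <- function(skeletons,
                                    classifier = default_polarity_classifier(),
                                    granularity = 0.001,
                                    standardize = TRUE) {
  stopifnot(!is.null(names(skeletons)))
  doms <- lapply(skeletons, split_arbor_domains, granularity = granularity)
  feats <- list()
  for (id in names(skeletons))
    for (d in doms[[id]])
      feats[[length(feats) + 1L]] <-
        compute_morphometry(skeletons[[id]], d$member_node_ids)
  F <- do.call(rbind, feats)
  cl <- classifier
  if (standardize && all(cl$center == 0) && all(cl$scale == 1)) {
    ctr <- colMeans(F)
    scl <- apply(F, 2, sd)
    scl[!is.finite(scl) | scl == 0] <- 1
    cl <- polarity_classifier(classifier$weights, classifier$bias, ctr, scl)
  }
  idx <- 0L
  out <- list()
  for (id in names(skeletons)) {
    ds <- doms[[id]]
    for (j in seq_along(ds)) {
      idx <- idx + 1L
      r <- classify_polarity(F[idx, ], cl)
      ds[[j]]$label <- r$label
      ds[[j]]$score <- r$score
    }
    out[[id]] <- classify_skeleton_polarity(skeletons[[id]], cl,
                                            domains = ds)
  }
  out
}

#' Terminal-level polarity accuracy
#'
#' For each neuron, the fraction of terminals whose predicted label
#' matches the reference; the summary statistic is the unweighted mean
#' of the per-neuron fractions ("terminal-level accuracy").
#'
#' @param predicted,truth named lists keyed by neuron id; each element a
#'   named character vector of terminal labels (names = terminal ids).
#' @return List with `per_neuron` (named numeric fractions in `[0, 1]`)
#'   and `mean` (mean over neurons).
#' @export
polarity_accuracy <- function(predicted, truth) {
  stopifnot(setequal(names(predicted), names(truth)))
  per <- vapply(names(truth), function(id) {
    p <- predicted[[id]]
    t <- truth[[id]]
    if (!setequal(names(p), names(t)))
      stop("terminal sets differ for neuron ", id)
    mean(p[names(t)] == t)
  }, numeric(1))
  list(per_neuron = per, mean = mean(per))
}

#' Read or write a polarity classifier as JSON
#'
#' Weights, bias and standardization are stored keyed by feature name.
#'
#' @param classifier a `polarity_classifier`.
#' @param path file path.
#' @return `read_classifier_json` returns a `polarity_classifier`;
#'   `write_classifier_json` returns `path` invisibly.
#' @export
write_classifier_json <- function(classifier, path) {
  jsonlite::write_json(list(weights = as.list(classifier$weights),
                            bias = classifier$bias,
                            center = as.list(classifier$center),
                            scale = as.list(classifier$scale)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_classifier_json
#' @export
read_classifier_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  polarity_classifier(unlist(x$weights), bias = x$bias,
                      center = unlist(x$center), scale = unlist(x$scale))
}

#' Write terminal polarity labels as TSV
#'
#' Columns: `neuron_id`, `terminal_node_id`, `label`, `score`.
#'
#' @param results named list (by neuron id) of results from
#'   [classify_skeleton_polarity()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_polarity_tsv <- function(results, path) {
  tab <- do.call(rbind, lapply(names(results), function(id) {
    t <- results[[id]]$terminals
    data.frame(neuron_id = id, terminal_node_id = t$terminal_id,
               label = t$label, score = t$score)
  }))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
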