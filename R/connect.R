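#' Connection criteria
#'
#' The two tunable criteria of connection inference: the distance
#' criterion (maximum axon-dendrite segment distance forming a contact
#' point, um) and the relative contact-point criterion `R`. Two presets
#' are documented in the source material: `R = 0.01` ("contact points =
#' 1%", the default) and `R = 0.001` ("> 0.1%"); both are plain config
#' constants.
#'
#' @param max_distance distance criterion, um (> 0; default 13).
#' @param min_relative_contacts `R`, a fraction in `[0, 1)` (default 0.01).
#' @return A `connection_criteria` object.
#' @export
connection_criteria <- function(max_distance = 13, min_relative_contacts = 0.01) {
  stopifnot(max_distance > 0,
            min_relative_contacts >= 0, min_relative_contacts < 1)
  structure(list(max_distance = max_distance,
                 min_relative_contacts = min_relative_contacts),
            class = "connection_criteria")
}

#' Infer directed connections from a contact matrix
#'
#' Neuron `i` connects to neuron `k` iff
#' `N_ik / input_contacts(i) > R`, where `input_contacts(i)` is the
#' total number of contact points arriving on `i`'s dendrites. The
#' *input* total is used as the denominator deliberately: an output
#' denominator would cap the number of downstream partners at
#' `floor(1/R)`, whereas the input denominator does not (input and
#' output contact totals are roughly proportional). Neurons with zero
#' input contacts have an undefined ratio; they emit no outgoing edges
#' and a warning is raised.
#'
#' @param contacts contact data.frame (`pre`, `post`, `n`); duplicate
#'   directed pairs are summed first.
#' @param criteria a [connection_criteria()].
#' @param neuron_ids optional id universe (for totals of contact-less
#'   neurons).
#' @return data.frame of edges: `pre`, `post`, `n` (the contact count
#'   backing each retained edge).
#' @export
infer_connections <- function(contacts, criteria = connection_criteria(),
                              neuron_ids = NULL) {
  contacts <- merge_duplicate_contacts(contacts)
  tot <- contact_totals(contacts, neuron_ids)
  inp <- setNames(tot$input_contacts, tot$neuron_id)
  zero_in <- unique(contacts$pre[inp[contacts$pre] == 0])
  if (length(zero_in))
    warning(length(zero_in),
            " presynaptic neuron(s) with zero input contacts emit no edges")
  denom <- inp[contacts$pre]
  keep <- denom > 0 & contacts$n / denom > criteria$min_relative_contacts
  out <- contacts[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' ROC scan over connection criteria
#'
#' Evaluates every (distance, R) pair against a reference adjacency
#' over ordered neuron pairs: TPR = TP / (TP + FN), FPR = FP / (FP +
#' TN). The best pair is chosen by the configured rule: maximize TPR
#' subject to `FPR <= fpr_cap` (default), or Youden's J = TPR - FPR.
#' Ties prefer lower FPR, then larger R (sparser criteria).
#'
#' @param contacts_by_distance named list of contact data.frames, one
#'   per candidate distance criterion (names = distances, um).
#' @param r_grid candidate values of the relative contact criterion R.
#' @param reference data.frame of reference edges (`pre`, `post`).
#' @param neuron_ids id universe defining the set of ordered pairs.
#' @param rule "tpr_at_fpr" or "youden".
#' @param fpr_cap FPR ceiling for the default rule (default 0.06).
#' @return List with `table` (data.frame: `distance`, `r`, `tp`, `fp`,
#'   `fn`, `tn`, `tpr`, `fpr`) and `best` (one row of `table`).
#' @export
roc_scan <- function(contacts_by_distance, r_grid, reference, neuron_ids,
                     rule = c("tpr_at_fpr", "youden"), fpr_cap = 0.06) {
  rule <- match.arg(rule)
  if (nrow(reference) == 0L) stop("empty reference adjacency")
  n <- length(neuron_ids)
  npairs <- n * (n - 1)
  ref_key <- unique(paste(reference$pre, reference$post, sep = "\r"))
  npos <- length(ref_key)
  rows <- list()
  for (dname in names(contacts_by_distance)) {
    contacts <- contacts_by_distance[[dname]]
    for (r in r_grid) {
      edges <- suppressWarnings(
        infer_connections(contacts, connection_criteria(
          max_distance = as.numeric(dname), min_relative_contacts = r),
          neuron_ids = neuron_ids))
      key <- paste(edges$pre, edges$post, sep = "\r")
      tp <- sum(key %in% ref_key)
      fp <- length(key) - tp
      fn <- npos - tp
      tn <- npairs - npos - fp
      rows[[length(rows) + 1L]] <- data.frame(
        distance = as.numeric(dname), r = r, tp = tp, fp = fp,
        fn = fn, tn = tn, tpr = tp / (tp + fn), fpr = fp / (fp + tn))
    }
  }
  tab <- do.call(rbind, rows)
  cand <- if (rule == "tpr_at_fpr") {
    ok <- tab[tab$fpr <= fpr_cap, , drop = FALSE]
    if (nrow(ok) == 0L) ok <- tab  # nothing under the cap: fall back
    ok[order(-ok$tpr, ok$fpr, -ok$r), , drop = FALSE]
  } else {
    tab[order(-(tab$tpr - tab$fpr), tab$fpr, -tab$r), , drop = FALSE]
  }
  list(table = tab, best = cand[1, , drop = FALSE])
}
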