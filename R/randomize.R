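#' Randomize a network by presynaptic-preserving rewiring
#'
#' Every synapse keeps its presynaptic neuron and its contact count
#' (hence its conductance); the postsynaptic endpoint is redrawn
#' uniformly from the eligible target set. The rewired network
#' therefore preserves exactly: the synapse count, the conductance
#' multiset and every presynaptic out-degree. Previously isolated
#' neurons (passed via `extra_targets`) become eligible targets, so the
#' randomized network may hold slightly more neurons than the original.
#'
#' @param model a `network_model`.
#' @param seed integer seed.
#' @param allow_self_loops default `FALSE`.
#' @param duplicate_policy "resample" (redraw until the directed pair is
#'   unique, preserving the edge count as distinct pairs; default) or
#'   "merge_sum" (collide and sum contact counts).
#' @param extra_targets data.frame like `model$neurons` (at least `id`,
#'   `name`, `length`) of additional eligible postsynaptic neurons.
#' @return A rewired `network_model`.
#' @export
rewire_network <- function(model, seed = 1, allow_self_loops = FALSE,
                           duplicate_policy = c("resample", "merge_sum"),
                           extra_targets = NULL) {
  duplicate_policy <- match.arg(duplicate_policy)
  neurons <- model$neurons
  if (!is.null(extra_targets)) {
    extra_targets <- extra_targets[!extra_targets$id %in% neurons$id, ,
                                   drop = FALSE]
    if (nrow(extra_targets)) {
      if (!"transmitter" %in% names(extra_targets))
        extra_targets$transmitter <- assign_transmitter(extra_targets$name)
      mem <- estimate_membrane_params(extra_targets$length)
      extra <- cbind(extra_targets[, c("id", "name", "transmitter", "length")],
                     mem[, setdiff(names(mem), "l")])
      neurons <- rbind(neurons, extra)
    }
  }
  targets <- neurons$id
  s <- model$synapses
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  s$post <- withr_seed({
    post <- sample(targets, nrow(s), replace = TRUE)
    bad <- rep(TRUE, length(post))
    for (iter in 1:1000) {
      key <- paste(s$pre, post, sep = "\r")
      bad <- (!allow_self_loops & post == s$pre)
      if (duplicate_policy == "resample") bad <- bad | duplicated(key)
      if (!any(bad)) break
      post[bad] <- sample(targets, sum(bad), replace = TRUE)
    }
    if (any(bad)) stop("rewiring failed to resolve collisions")
    post
  })
  if (duplicate_policy == "merge_sum") s <- merge_duplicate_contacts(s)
  rownames(s) <- NULL
  structure(list(neurons = neurons, synapses = s,
                 scaling = model$scaling, criteria = model$criteria),
            class = "network_model")
}

#' Parametric random reference network
#'
#' An Erdos-Renyi-style directed network: neurons per transmitter class,
#' each ordered pair connected independently with probability
#' `connectivity`, contact counts drawn from the configured law. Serves
#' as the random control for E-I index comparisons and for the
#' subsampling-artifact check.
#'
#' @param n_per_class named integer vector, e.g.
#'   `c(Cha = 300, VGlut = 500, Gad = 700)`.
#' @param connectivity edge probability (default 0.003).
#' @param seed integer seed.
#' @param contact_law function(n) drawing contact counts (default:
#'   all 1, i.e. unweighted).
#' @param scaling a [synaptic_scaling()].
#' @param mean_length mean skeleton length for membrane parameters, um.
#' @return A `network_model`.
#' @export
make_random_reference <- function(n_per_class = c(Cha = 350, VGlut = 600,
                                                  Gad = 800),
                                  connectivity = 0.003, seed = 1,
                                  contact_law = NULL,
                                  scaling = synaptic_scaling(),
                                  mean_length = 1200) {
  stopifnot(connectivity >= 0, connectivity <= 1)
  set.seed(seed)
  n <- sum(n_per_class)
  cls <- rep(names(n_per_class), n_per_class)
  ids <- sprintf("%s-R-%06d", cls, seq_len(n))
  n_edges <- stats::rbinom(1, n * (n - 1), connectivity)
  if (n_edges > 0) {
    # sample ordered pairs without replacement via linear indices
    pair_idx <- sample(n * (n - 1), n_edges)
    pre_i <- (pair_idx - 1) %/% (n - 1) + 1
    off <- (pair_idx - 1) %% (n - 1) + 1
    post_i <- ifelse(off >= pre_i, off + 1, off)
    cnt <- if (is.null(contact_law)) rep(1, n_edges) else contact_law(n_edges)
    synapses <- data.frame(pre = ids[pre_i], post = ids[post_i], n = cnt)
  } else {
    synapses <- data.frame(pre = character(0), post = character(0),
                           n = numeric(0))
  }
  mem <- estimate_membrane_params(rep(mean_length, n))
  neurons <- cbind(data.frame(id = ids, name = ids, transmitter = cls,
                              length = mean_length),
                   mem[, setdiff(names(mem), "l")])
  structure(list(neurons = neurons, synapses = synapses,
                 scaling = scaling, criteria = connection_criteria()),
            class = "network_model")
}

#' Subsample neurons from a model
#'
#' Selects a random subset of neurons per transmitter class. Input
#' statistics such as the E-I index are evaluated on the *full* input
#' sets of the selected neurons (as when a random subset of a larger
#' brain is scored), so pass the returned ids to [ei_index()] on the
#' full model.
#'
#' @param model a `network_model`.
#' @param fraction fraction of each class to keep (default 0.15).
#' @param seed integer seed.
#' @return Character vector of selected neuron ids.
#' @export
subsample_neurons <- function(model, fraction = 0.15, seed = 1) {
  stopifnot(fraction > 0, fraction <= 1)
  set.seed(seed)
  unlist(lapply(split(model$neurons$id, model$neurons$transmitter),
                function(ids) sample(ids, max(1L, round(fraction * length(ids))))),
         use.names = FALSE)
}
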