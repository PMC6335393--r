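#' Generate synthetic neuron skeletons with ground-truth polarity
#'
#' Each neuron has a soma with two primary neurites: an axonal subtree
#' (a long, sparsely branching cable ending in a small terminal tuft —
#' long path length to soma, few branch points) and a dendritic subtree
#' (short, densely branching — many branch points, short paths). The
#' construction mirrors the sign structure of the polarity-classifier
#' weights, so the planted labels are recoverable from morphometry.
#' Ground-truth node and terminal labels are attached to each skeleton.
#'
#' @param n number of neurons.
#' @param seed integer seed (generation is deterministic given it).
#' @param axon_length mean axon cable length, um.
#' @param dend_depth dendritic branching depth (0 gives a single
#'   unbranched segment per neurite).
#' @param seg_len mean segment length, um.
#' @param box half-width of the cube in which somata are placed, um.
#' @return List of `neuron_skeleton` objects; each carries attributes
#'   `truth_nodes` (named character vector of node labels) and
#'   `truth_terminals` (named character vector over terminal ids).
#' @export
synth_skeletons <- function(n, seed = 1, axon_length = 300, dend_depth = 3,
                            seg_len = 15, box = 150) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    soma <- runif(3, -box, box)
    nodes <- data.frame(id = 1L, type = 1L, x = soma[1], y = soma[2],
                        z = soma[3], radius = NA_real_, parent = -1L)
    next_id <- 2L
    add_node <- function(parent_id, pos) {
      nodes[nrow(nodes) + 1L, ] <<- list(next_id, 0L, pos[1], pos[2],
                                         pos[3], NA_real_, parent_id)
      next_id <<- next_id + 1L
      next_id - 1L
    }
    rand_dir <- function(bias = NULL, wobble = 0.5) {
      v <- rnorm(3)
      if (!is.null(bias)) v <- bias / sqrt(sum(bias^2)) + wobble * v
      v / sqrt(sum(v^2))
    }
    labels <- c("1" = "soma")
    # axon: straight-ish cable then a small tuft
    dir_a <- rand_dir()
    pos <- soma
    parent <- 1L
    n_seg <- max(3L, round(axon_length / seg_len))
    for (s in seq_len(n_seg)) {
      dir_a <- rand_dir(dir_a, wobble = 0.2)
      pos <- pos + dir_a * seg_len * runif(1, 0.8, 1.2)
      parent <- add_node(parent, pos)
      labels[as.character(parent)] <- "axon"
    }
    for (t in 1:2) {  # terminal tuft
      tip <- pos + rand_dir(dir_a, wobble = 1) * seg_len * runif(1, 0.5, 1)
      id <- add_node(parent, tip)
      labels[as.character(id)] <- "axon"
    }
    # dendrite: recursive binary tree, short segments
    grow <- function(parent_id, pos, dir, depth) {
      dir <- rand_dir(dir, wobble = 0.6)
      npos <- pos + dir * seg_len * runif(1, 0.5, 0.9)
      id <- add_node(parent_id, npos)
      labels[as.character(id)] <<- "dendrite"
      if (depth > 0) for (b in 1:2) grow(id, npos, dir, depth - 1L)
    }
    grow(1L, soma, rand_dir(), dend_depth)
    sk <- neuron_skeleton(nodes)
    terms <- terminal_ids(sk)
    attr(sk, "truth_nodes") <- labels
    attr(sk, "truth_terminals") <- labels[as.character(terms)]
    sk
  })
}

#' Generate a synthetic connectome (neuron table + contact matrix)
#'
#' Emulates the defining structure of a reconstructed brain sample:
#' transmitter classes in configurable proportions (defaults follow the
#' reconstructed-brain shares: roughly 17% cholinergic, 30%
#' glutamatergic, 40% GABAergic, 14% other), a bimodal (projection vs
#' local) log-normal skeleton-length distribution, broad in/out degree
#' distributions (per-neuron exponential connection propensities), a
#' wide U-shaped excitation-inhibition input mix (many neurons with
#' nearly pure excitatory or inhibitory input), and heavy-tailed
#' contact counts (log-normal body with a Pareto tail, so per-neuron
#' contact totals follow a power-law-tailed distribution).
#'
#' The defaults target the *dynamical regime* of a reconstructed brain
#' at a test-bench population size (thousands of neurons, ~10x fewer
#' than a brain sample): after the relative-contact criterion the
#' retained connection count per neuron is a few tens, and contact
#' weights are scaled so the recurrent synaptic gain supports a
#' self-sustained hyperactive state at I/E factor 1 that persists under
#' strong inhibitory scaling (wide E-I mix) and is quenched by strong
#' short-term depression. At a reduced population size this requires
#' heavier per-synapse weights than a full-size reconstruction, a
#' deliberate scale-down compensation.
#'
#' @param n number of neurons.
#' @param mean_degree mean number of generated incoming contact pairs
#'   per neuron (default 95, leaving a few tens of connections per
#'   neuron after the relative-contact criterion); ignored when
#'   `connectivity` is given.
#' @param connectivity optional edge probability per ordered pair;
#'   overrides `mean_degree` (`mean_degree = connectivity * (n - 1)`).
#' @param degree_dispersion 0 gives near-Poisson degrees; 1 (default)
#'   draws per-neuron exponential propensities, giving the broad,
#'   exponential-tailed degree distributions of reconstructed brains.
#' @param ei_concentration concentration of the per-neuron Beta law
#'   governing the excitatory share of each neuron's inputs. Small
#'   values (default 0.8) give the wide, U-shaped E-I index
#'   distribution characteristic of reconstructed brains (many neurons
#'   with almost purely excitatory or purely inhibitory input); large
#'   values give the narrow distribution of a class-blind random
#'   network.
#' @param seed integer seed.
#' @param class_fractions named fractions over
#'   `c("Cha", "VGlut", "Gad", "other")`.
#' @param contact_meanlog,contact_sdlog log-normal body of the
#'   contact-count law.
#' @param pareto_alpha tail index of the Pareto tail (default 1.3).
#' @param pareto_frac fraction of counts drawn from the tail.
#' @param criteria generating [connection_criteria()] used for the
#'   ground-truth adjacency.
#' @return List with `neurons` (data.frame `id`, `name`, `length`,
#'   `transmitter`), `contacts` (data.frame `pre`, `post`, `n`) and
#'   `adjacency` (ground truth: `infer_connections` on the emitted
#'   contacts at `criteria`).
#' @export
synth_connectome <- function(n, mean_degree = 95, connectivity = NULL,
                             degree_dispersion = 1, ei_concentration = 0.5,
                             seed = 1,
                             class_fractions = c(Cha = 0.17, VGlut = 0.30,
                                                 Gad = 0.39, other = 0.14),
                             contact_meanlog = log(120), contact_sdlog = 1,
                             pareto_alpha = 1.3, pareto_frac = 0.08,
                             criteria = connection_criteria()) {
  stopifnot(abs(sum(class_fractions) - 1) < 1e-6)
  if (!is.null(connectivity)) {
    stopifnot(connectivity >= 0, connectivity <= 1)
    mean_degree <- connectivity * (n - 1)
  }
  set.seed(seed)
  cls <- sample(names(class_fractions), n, replace = TRUE,
                prob = class_fractions)
  ids <- sprintf("%s-F-%06d", cls, seq_len(n))
  # bimodal sizes: projection neurons (mean ~1750 um) vs local (~1000 um)
  proj <- runif(n) < 0.45
  len <- ifelse(proj, rlnorm(n, log(1753), 0.35), rlnorm(n, log(1000), 0.45))
  neurons <- data.frame(id = ids, name = ids, length = len,
                        transmitter = cls)
  # per-neuron source/target propensities broaden both degree tails
  w_out <- 1 - degree_dispersion + degree_dispersion * stats::rexp(n)
  w_in <- 1 - degree_dispersion + degree_dispersion * stats::rexp(n)
  in_deg <- pmin(n - 1L, stats::rpois(n, mean_degree * w_in))
  # per-neuron excitatory input share: U-shaped Beta mixing across
  # transmitter classes yields the wide E-I index distribution of
  # reconstructed brains (mean matches the global excitatory share)
  exc_share <- mean(cls %in% c("Cha", "VGlut"))
  p_exc <- stats::rbeta(n, ei_concentration * exc_share,
                        ei_concentration * (1 - exc_share))
  is_exc <- cls %in% c("Cha", "VGlut")
  post_i <- rep(seq_len(n), in_deg)
  pre_i <- unlist(lapply(seq_len(n), function(k) {
    m <- in_deg[k]
    if (m == 0L) return(integer(0))
    p <- w_out * ifelse(is_exc, p_exc[k], 1 - p_exc[k])
    p[k] <- 0
    if (all(p == 0)) p <- w_out * as.numeric(seq_len(n) != k)
    sample(n, m, prob = p)
  }))
  if (length(pre_i)) {
    n_edges <- length(pre_i)
    tail_draw <- runif(n_edges) < pareto_frac
    cnt <- ifelse(tail_draw,
                  ceiling(exp(contact_meanlog) *
                            runif(n_edges)^(-1 / pareto_alpha)),
                  ceiling(rlnorm(n_edges, contact_meanlog, contact_sdlog)))
    contacts <- data.frame(pre = ids[pre_i], post = ids[post_i], n = cnt)
  } else {
    contacts <- data.frame(pre = character(0), post = character(0),
                           n = numeric(0))
  }
  adjacency <- suppressWarnings(
    infer_connections(contacts, criteria, neuron_ids = ids))
  list(neurons = neurons, contacts = contacts, adjacency = adjacency)
}
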