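# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# straight chain along +x with unit spacing (soma at origin)
chain_skeleton <- function(n_nodes = 3, spacing = 1) {
  neuron_skeleton(data.frame(
    id = seq_len(n_nodes), type = 1L,
    x = (seq_len(n_nodes) - 1) * spacing, y = 0, z = 0,
    radius = NA_real_, parent = c(-1L, seq_len(n_nodes - 1L))))
}

# full binary tree of given depth; each child offset so the geometry is
# non-degenerate. Returns the skeleton.
binary_tree_skeleton <- function(depth = 2, seg = 10) {
  nodes <- data.frame(id = 1L, type = 1L, x = 0, y = 0, z = 0,
                      radius = NA_real_, parent = -1L)
  nid <- 1L
  grow <- function(parent, px, py, d, spread) {
    force(parent)
    if (d == 0) return()
    for (s in c(-1, 1)) {
      child <- nid + 1L
      nid <<- child
      nodes[nrow(nodes) + 1L, ] <<- list(child, 0L, px + s * spread,
                                         py + seg, 0, NA_real_, parent)
      grow(child, px + s * spread, py + seg, d - 1L, spread / 2)
    }
  }
  grow(1L, 0, 0, depth, seg)
  neuron_skeleton(nodes)
}

# a single-segment "neurite" from p0 to p1 whose non-root node carries
# the given polarity; returns skeleton + node labels
segment_neuron <- function(p0, p1, label) {
  sk <- neuron_skeleton(data.frame(
    id = 1:2, type = 1L, x = c(p0[1], p1[1]), y = c(p0[2], p1[2]),
    z = c(p0[3], p1[3]), radius = NA_real_, parent = c(-1L, 1L)))
  list(skeleton = sk, labels = c("1" = label, "2" = label))
}

# minimal model builder from explicit tables
toy_model <- function(neurons, synapses, scaling = synaptic_scaling()) {
  mem <- estimate_membrane_params(neurons$length)
  neurons <- cbind(neurons[, c("id", "name", "transmitter", "length")],
                   mem[, setdiff(names(mem), "l")])
  structure(list(neurons = neurons, synapses = synapses,
                 scaling = scaling, criteria = connection_criteria()),
            class = "network_model")
}

# n disconnected neurons of equal size (for noise/dynamics tests)
disconnected_model <- function(n = 1, length_um = 1000, transmitter = "Cha") {
  ids <- sprintf("n%05d", seq_len(n))
  toy_model(data.frame(id = ids, name = ids, transmitter = transmitter,
                       length = length_um),
            data.frame(pre = character(0), post = character(0),
                       n = numeric(0)))
}

# two-neuron model with one synapse of given contact count
two_neuron_model <- function(pre_tx = "Cha", n_contacts = 10,
                             scaling = synaptic_scaling()) {
  pre_name <- paste0(pre_tx, "-F-000001")
  toy_model(
    data.frame(id = c("pre", "post"),
               name = c(pre_name, "Cha-F-000002"),
               transmitter = c(pre_tx, "Cha"), length = 1000),
    data.frame(pre = "pre", post = "post", n = n_contacts),
    scaling = scaling)
}

expect_setequal_int <- function(a, b) expect_setequal(as.integer(a),
                                                      as.integer(b))
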