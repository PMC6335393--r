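#' Assemble a spiking network model
#'
#' Turns a neuron table and a contact matrix into a simulatable model:
#' edges are inferred with [infer_connections()], synapses from "other"
#' (putative modulatory) presynaptic neurons are dropped, isolated
#' neurons (no surviving in- or out-edges) are excluded, and each neuron
#' receives LIF membrane parameters estimated from its skeleton length.
#' Per-synapse conductance scales are `B * k * N_ij` with `B = B_exc`
#' for ACh/AMPA/NMDA and `B_inh` for GABA_A; a glutamatergic synapse
#' instantiates paired AMPA + NMDA receptors sharing the same `N_ij`,
#' `B` and short-term-depression variable.
#'
#' @param neurons data.frame with columns `id`, `name`, `length` (um);
#'   optional `transmitter` (else derived from `name`).
#' @param contacts contact data.frame (`pre`, `post`, `n`).
#' @param criteria a [connection_criteria()].
#' @param scaling a [synaptic_scaling()].
#' @param tau_m,... membrane defaults passed to
#'   [estimate_membrane_params()].
#' @return A `network_model`: list with `neurons` (membrane table),
#'   `synapses` (`pre`, `post`, `n`), `scaling`, `criteria`.
#' @export
assemble_model <- function(neurons, contacts,
                           criteria = connection_criteria(),
                           scaling = synaptic_scaling(), tau_m = 16, ...) {
  stopifnot(all(c("id", "name", "length") %in% names(neurons)))
  if (is.null(criteria)) stop("connection criteria are required")
  neurons$id <- as.character(neurons$id)
  if (!"transmitter" %in% names(neurons))
    neurons$transmitter <- assign_transmitter(neurons$name)
  edges <- suppressWarnings(
    infer_connections(contacts, criteria, neuron_ids = neurons$id))
  # only Cha / VGlut / Gad presynaptic neurons emit synapses
  tx <- setNames(neurons$transmitter, neurons$id)
  edges <- edges[tx[edges$pre] %in% c("Cha", "VGlut", "Gad"), , drop = FALSE]
  connected <- unique(c(edges$pre, edges$post))
  if (length(connected) == 0L)
    stop("no connections survive the criteria; nothing to assemble")
  neurons <- neurons[neurons$id %in% connected, , drop = FALSE]
  mem <- estimate_membrane_params(neurons$length, tau_m = tau_m, ...)
  neurons <- cbind(neurons[, c("id", "name", "transmitter", "length")],
                   mem[, setdiff(names(mem), "l")])
  rownames(neurons) <- NULL
  rownames(edges) <- NULL
  structure(list(neurons = neurons, synapses = edges,
                 scaling = scaling, criteria = criteria),
            class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  cat("<network_model> ", nrow(x$neurons), " neurons, ",
      nrow(x$synapses), " synapses (",
      paste(sprintf("%s:%d", names(table(x$neurons$transmitter)),
                    as.integer(table(x$neurons$transmitter))),
            collapse = " "),
      "); B_exc = ", x$scaling$B_exc,
      ", I/E factor = ", x$scaling$ie_factor, "\n", sep = "")
  invisible(x)
}

#' Per-receptor conductance table of a model
#'
#' Expands the synapse table into receptor components with conductance
#' scales `g = B * k * N` (nS): Cha presynaptic neurons contribute ACh,
#' Gad contribute GABA_A (with `B_inh`), VGlut contribute paired AMPA
#' and NMDA components.
#'
#' @param model a `network_model`.
#' @param ie_factor optional override of the model's I/E factor.
#' @return data.frame: `pre`, `post`, `n`, `receptor`, `g`.
#' @export
synapse_conductances <- function(model, ie_factor = NULL) {
  sc <- model$scaling
  if (!is.null(ie_factor)) sc <- synaptic_scaling(sc$B_exc, ie_factor, sc$k)
  tx <- setNames(model$neurons$transmitter, model$neurons$id)
  s <- model$synapses
  ptx <- tx[s$pre]
  parts <- list()
  add <- function(sel, receptor, B) {
    if (!any(sel)) return()
    parts[[length(parts) + 1L]] <<- data.frame(
      pre = s$pre[sel], post = s$post[sel], n = s$n[sel],
      receptor = receptor, g = B * sc$k[[receptor]] * s$n[sel])
  }
  add(ptx == "Cha", "ACh", sc$B_exc)
  add(ptx == "Gad", "GABA_A", sc$B_inh)
  add(ptx == "VGlut", "AMPA", sc$B_exc)
  add(ptx == "VGlut", "NMDA", sc$B_exc)
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Write/read a network model as a JSON container
#'
#' The container holds the neuron table, the synapse table and the
#' scaling/criteria blocks; plain text, suitable for versioning.
#'
#' @param model a `network_model`.
#' @param path file path.
#' @return The model (read) or `path` invisibly (write).
#' @export
write_model_json <- function(model, path) {
  jsonlite::write_json(
    list(neurons = model$neurons, synapses = model$synapses,
         scaling = list(B_exc = model$scaling$B_exc,
                        ie_factor = model$scaling$ie_factor,
                        k = as.list(model$scaling$k)),
         criteria = unclass(model$criteria)),
    path, digits = NA, auto_unbox = TRUE, dataframe = "columns")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    neurons = as.data.frame(x$neurons),
    synapses = as.data.frame(x$synapses),
    scaling = synaptic_scaling(x$scaling$B_exc, x$scaling$ie_factor,
                               unlist(x$scaling$k)),
    criteria = connection_criteria(x$criteria$max_distance,
                                   x$criteria$min_relative_contacts)),
    class = "network_model")
}
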