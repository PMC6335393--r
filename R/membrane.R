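#' Estimate LIF membrane parameters from skeleton length
#'
#' The membrane area is estimated from the total skeleton length `l`
#' (um) by the empirical relation
#' `A = (l * 2 * pi * 0.147) * 2.38 + 5340` (um^2), i.e. the skeleton is
#' treated as a cylinder of radius 0.147 um whose lateral area is
#' scaled by an empirical factor 2.38 plus a constant offset. The
#' capacitance uses 0.8 uF/cm^2 = 0.008 pF/um^2, so `C_m = 0.008 * A`
#' pF, and the leak conductance follows from the fixed membrane time
#' constant: `g_L = C_m / tau_m` (nS). `C_m = g_L * tau_m` holds exactly
#' for every neuron.
#'
#' @param l skeleton length(s), um (vectorized, >= 0).
#' @param tau_m membrane time constant, ms (default 16).
#' @param V_resting,V_threshold,V_reset fixed potentials, mV (defaults
#'   -70, -45, -55).
#' @param T_refract refractory period, ms (default 2).
#' @param c_per_area specific capacitance, pF/um^2 (default 0.008).
#' @return data.frame with columns `l`, `area` (um^2), `C_m` (pF),
#'   `g_L` (nS), `tau_m`, `V_resting`, `V_threshold`, `V_reset`,
#'   `T_refract`.
#' @export
estimate_membrane_params <- function(l, tau_m = 16,
                                     V_resting = -70, V_threshold = -45,
                                     V_reset = -55, T_refract = 2,
                                     c_per_area = 0.008) {
  if (any(l < 0)) stop("negative skeleton length")
  stopifnot(V_reset < V_threshold)
  area <- (l * 2 * pi * 0.147) * 2.38 + 5340
  C_m <- c_per_area * area
  data.frame(l = l, area = area, C_m = C_m, g_L = C_m / tau_m,
             tau_m = tau_m, V_resting = V_resting,
             V_threshold = V_threshold, V_reset = V_reset,
             T_refract = T_refract)
}

#' Assign a transmitter class from a neuron name
#'
#' The driver prefix (the part of the name before the first `-`) is
#' matched case-insensitively: names starting with `Cha` are
#' cholinergic, `VGlut` glutamatergic, `Gad` GABAergic (so `Gad1-...`
#' matches `Gad`); anything else is "other" (putative modulatory;
#' such neurons emit no synapses in the assembled model).
#'
#' @param name character vector of neuron names (e.g. "VGlut-F-200532").
#' @return Character vector over `{"Cha", "VGlut", "Gad", "other"}`.
#' @export
assign_transmitter <- function(name) {
  stopifnot(all(nzchar(name)))
  prefix <- tolower(sub("-.*$", "", name))
  out <- rep("other", length(name))
  out[startsWith(prefix, "cha")] <- "Cha"
  out[startsWith(prefix, "vglut")] <- "VGlut"
  out[startsWith(prefix, "gad")] <- "Gad"
  out
}

#' Synaptic scaling constants
#'
#' `B` sets the global synaptic strength: `B_exc` for excitatory
#' synapses (ACh, AMPA, NMDA) and `B_inh = ie_factor * B_exc` for
#' inhibitory (GABA_A) ones; the I/E factor is the single knob tuning
#' network balance (at `B_exc = 2.2` and I/E factor 10, `B_inh = 22`).
#' `k` balances receptor classes so that `k * tau` is equal across
#' excitatory receptors (AMPA 1/300, NMDA 1/15000, ACh 1/3000; GABA_A
#' 1/300).
#'
#' @param B_exc excitatory scaling (default 2.2).
#' @param ie_factor inhibitory-to-excitatory ratio (default 10).
#' @param k named per-receptor scale factors.
#' @return A `synaptic_scaling` object (list with `B_exc`, `ie_factor`,
#'   `B_inh`, `k`).
#' @export
synaptic_scaling <- function(B_exc = 2.2, ie_factor = 10,
                             k = c(AMPA = 1 / 300, NMDA = 1 / 15000,
                                   ACh = 1 / 3000, GABA_A = 1 / 300)) {
  stopifnot(B_exc > 0, ie_factor > 0,
            all(c("AMPA", "NMDA", "ACh", "GABA_A") %in% names(k)))
  structure(list(B_exc = B_exc, ie_factor = ie_factor,
                 B_inh = ie_factor * B_exc, k = k),
            class = "synaptic_scaling")
}
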