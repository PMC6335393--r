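#' Receptor kinetics and short-term depression parameters
#'
#' Defaults: single-exponential decay constants tau_AMPA = tau_GABA_A =
#' 2 ms, tau_ACh = 20 ms, NMDA two-variable gating with tau_s = 100 ms
#' and rise tau_x = 2 ms, preserving the receptor time-constant ratios
#' NMDA : ACh : AMPA = 50 : 10 : 1 that the per-receptor `k` factors
#' compensate (`k * tau` equal across excitatory receptors). NMDA
#' activation factor alpha = 0.6332; magnesium block with [Mg2+] = 1 mM,
#' scale 3.57 mM and slope 0.062 /mV. Reversal potentials: 0 mV
#' excitatory, -70 mV GABA_A. Short-term depression: recovery time
#' constant `tau_d` (ms; 0 disables STD so D = 1) and vesicle release
#' probability `p_v` (default 0.5).
#'
#' @param ... overrides of any named default.
#' @return Named list of kinetic constants.
#' @export
receptor_kinetics <- function(...) {
  kin <- list(tau_ampa = 2, tau_gaba = 2, tau_ach = 20,
              tau_nmda_s = 100, tau_nmda_x = 2, alpha = 0.6332,
              mg = 1, mg_scale = 3.57, mg_slope = 0.062,
              v_rev_exc = 0, v_rev_inh = -70,
              tau_d = 0, p_v = 0.5)
  over <- list(...)
  stopifnot(all(names(over) %in% names(kin)))
  modifyList(kin, over)
}

#' Voltage-dependent NMDA magnesium-block factor
#'
#' `1 / (1 + ([Mg2+] / 3.57 mM) * exp(-0.062 * V))`, in (0, 1].
#'
#' @param V membrane potential, mV.
#' @param kinetics a [receptor_kinetics()] list.
#' @return Dimensionless factor(s) in (0, 1].
#' @export
nmda_mg_factor <- function(V, kinetics = receptor_kinetics()) {
  stopifnot(all(is.finite(V)))
  1 / (1 + (kinetics$mg / kinetics$mg_scale) * exp(-kinetics$mg_slope * V))
}

#' One short-term-depression update
#'
#' The depression variable D recovers towards 1 with time constant
#' `tau_d` and jumps to `D * p_v` at each presynaptic spike (the jump is
#' applied at spike arrival, then the recovery step). `tau_d = 0`
#' disables STD (D stays 1).
#'
#' @param D current value(s) in `[0, 1]`.
#' @param p_v vesicle release probability in (0, 1].
#' @param tau_d recovery time constant, ms.
#' @param dt time step, ms.
#' @param spiked logical: did the presynaptic neuron spike this step?
#' @return Updated D.
#' @export
std_update <- function(D, p_v, tau_d, dt, spiked = FALSE) {
  stopifnot(all(D >= 0 & D <= 1), p_v > 0, p_v <= 1)
  if (tau_d <= 0) return(rep(1, length(D)) * 1)
  if (spiked) D <- D * p_v
  1 - (1 - D) * exp(-dt / tau_d)
}

#' Calibrate the per-neuron Gaussian background current
#'
#' At each step and for each neuron an independent membrane current is
#' drawn from `Normal(mu_I, sigma_I)` (pA). With synapses absent the
#' discrete membrane update is a first-order autoregressive process
#' whose stationary mean and SD are matched in closed form to the
#' targets: `mu_I = g_L * (target_mean_V - V_resting)` and
#' `sigma_I = g_L * target_sd_V * sqrt((1 + a) / (1 - a))` with
#' `a = exp(-dt / tau_m)` — the per-step variance scales like `1/dt`, so
#' the stationary Vm statistics are dt-independent. The width scales
#' with `g_L`, i.e. with neuron size, so all neurons share the same
#' resting Vm statistics (defaults: mean -60 mV, SD 3 mV).
#'
#' @param membrane one row of [estimate_membrane_params()] (or any list
#'   with `g_L`, `V_resting`, `V_threshold`).
#' @param dt simulation step, ms.
#' @param target_mean_V,target_sd_V resting-state Vm targets, mV.
#' @return List with `mu_I` and `sigma_I` (pA; vectorized over neurons).
#' @export
calibrate_background_noise <- function(membrane, dt = 0.1,
                                       target_mean_V = -60, target_sd_V = 3) {
  stopifnot(dt > 0, target_sd_V >= 0)
  if (any(target_mean_V >= membrane$V_threshold))
    stop("target mean Vm at or above threshold: neuron would fire continuously")
  tau <- if (!is.null(membrane$tau_m)) membrane$tau_m else
    membrane$C_m / membrane$g_L
  a <- exp(-dt / tau)
  list(mu_I = membrane$g_L * (target_mean_V - membrane$V_resting),
       sigma_I = membrane$g_L * target_sd_V * sqrt((1 + a) / (1 - a)))
}

#' Simulation configuration
#'
#' @param dt step, ms (default 0.1).
#' @param duration simulated time, ms.
#' @param seed integer RNG seed for the simulator's own generator.
#' @param dv_max per-step cap on |dV|, mV. The default is
#'   `V_threshold - V_rev,inh` = -45 - (-70) = 25 mV: a burst of
#'   GABAergic input can push Vm far below the inhibitory reversal,
#'   after which further inhibitory conductance would produce a huge
#'   depolarizing step and a spurious rebound spike; the symmetric cap
#'   removes that artifact.
#' @param record_vm neuron ids whose Vm (and gating, if
#'   `record_gates`) to record.
#' @param record_stride record every this many steps (default 1).
#' @param record_gates also record reduced gating variables.
#' @param threshold_on disable to study subthreshold dynamics.
#' @param rate_bin population-rate bin, ms (default 100).
#' @return A config list.
#' @export
simulation_config <- function(duration, dt = 0.1, seed = 1, dv_max = 25,
                              record_vm = character(0), record_stride = 1L,
                              record_gates = FALSE, threshold_on = TRUE,
                              rate_bin = 100) {
  stopifnot(dt > 0, duration >= 0)
  list(duration = duration, dt = dt, seed = as.integer(seed),
       dv_max = dv_max, record_vm = record_vm,
       record_stride = as.integer(record_stride),
       record_gates = record_gates, threshold_on = threshold_on,
       rate_bin = rate_bin)
}

#' Run a network simulation
#'
#' Integrates the conductance-based LIF network with the first-order
#' exponential-integrator scheme (leak integrated exactly; synaptic and
#' noise currents held constant within each step), reduced fast-receptor
#' gating, per-synapse NMDA gating with magnesium block, short-term
#' depression, calibrated background noise, refractory handling and the
#' per-step |dV| cap. Spikes take effect on their targets at the next
#' step boundary (zero transmission delay). Deterministic given
#' `config$seed`.
#'
#' @param model a `network_model`.
#' @param config a [simulation_config()].
#' @param kinetics a [receptor_kinetics()] list (set `tau_d`/`p_v` here
#'   to enable short-term depression).
#' @param ie_factor optional override of the model's I/E factor.
#' @param noise `"calibrated"` (default), `"off"`, or a list with
#'   vectors `mu_I`, `sigma_I`.
#' @param i_ext constant external current per neuron, pA (scalar or
#'   vector).
#' @param stim_until time (ms) up to which `i_ext` is applied;
#'   `Inf` (default) applies it for the whole run. A finite window
#'   implements the ignition protocol for stability experiments: drive
#'   the network into an active state, release, and observe whether
#'   activity self-sustains.
#' @param V0 initial potentials, mV (default: resting).
#' @param target_mean_V,target_sd_V noise-calibration targets, mV.
#' @return List with `spikes` (data.frame `neuron_id`, `time` ms, sorted
#'   by time), `rate` (population rate trace, Hz), `counts` (named
#'   per-neuron spike counts), `vm` (data.frame of recorded potentials,
#'   or NULL), `gates` (if recorded), `duration`, `n_neurons`.
#' @export
run_simulation <- function(model, config, kinetics = receptor_kinetics(),
                           ie_factor = NULL, noise = "calibrated",
                           i_ext = 0, stim_until = Inf, V0 = NULL,
                           target_mean_V = -60, target_sd_V = 3) {
  neu <- model$neurons
  n <- nrow(neu)
  ids <- neu$id
  if (identical(noise, "calibrated")) {
    cal <- calibrate_background_noise(neu, config$dt, target_mean_V,
                                      target_sd_V)
    mu_I <- rep_len(cal$mu_I, n)
    sigma_I <- rep_len(cal$sigma_I, n)
  } else if (identical(noise, "off")) {
    mu_I <- sigma_I <- rep(0, n)
  } else {
    mu_I <- rep_len(noise$mu_I, n)
    sigma_I <- rep_len(noise$sigma_I, n)
  }
  if (is.null(V0)) V0 <- neu$V_resting
  neu_list <- list(C_m = neu$C_m, g_L = neu$g_L, V_resting = neu$V_resting,
                   V_threshold = neu$V_threshold, V_reset = neu$V_reset,
                   T_refract = neu$T_refract, mu_I = mu_I,
                   sigma_I = sigma_I, I_ext = rep_len(i_ext, n),
                   V0 = rep_len(V0, n))

  syn <- build_synapse_arrays(model, ids, ie_factor)
  kin <- kinetics
  cfg <- list(dt = config$dt, duration = config$duration,
              stim_until = stim_until,
              dv_max = config$dv_max, threshold_on = config$threshold_on,
              seed = config$seed,
              record_idx = match(as.character(config$record_vm), ids) - 1L,
              record_stride = config$record_stride,
              record_gates = config$record_gates)
  if (anyNA(cfg$record_idx)) stop("record_vm contains unknown neuron ids")

  res <- .sim_core_cpp(neu_list, syn, kin, cfg)

  spikes <- data.frame(neuron_id = ids[res$spike_id + 1L],
                       time = res$spike_t)
  spikes <- spikes[order(spikes$time, spikes$neuron_id), , drop = FALSE]
  rownames(spikes) <- NULL
  vm <- NULL
  if (length(cfg$record_idx)) {
    vm <- data.frame(time = res$vm_t, res$vm)
    names(vm) <- c("time", as.character(config$record_vm))
  }
  gates <- if (isTRUE(config$record_gates))
    list(S_ampa = res$S_ampa, S_ach = res$S_ach, S_gaba = res$S_gaba)
  list(spikes = spikes,
       rate = population_rate(spikes, n, config$rate_bin, config$duration),
       counts = setNames(res$counts, ids), vm = vm, gates = gates,
       V_final = setNames(res$V_final, ids),
       duration = config$duration, n_neurons = n)
}

# Expand the model's synapse table into the CSR arrays the C++ core
# consumes (fast receptors + NMDA, sorted by presynaptic index).
build_synapse_arrays <- function(model, ids, ie_factor = NULL) {
  cond <- if (nrow(model$synapses))
    synapse_conductances(model, ie_factor) else NULL
  n <- length(ids)
  csr <- function(pre_idx, ord) {
    counts <- tabulate(pre_idx[ord], nbins = n)
    c(0L, cumsum(counts))
  }
  fast <- if (!is.null(cond)) cond[cond$receptor != "NMDA", , drop = FALSE]
  nmda <- if (!is.null(cond)) cond[cond$receptor == "NMDA", , drop = FALSE]
  cls_code <- c(AMPA = 0L, ACh = 1L, GABA_A = 2L)
  out <- list()
  if (!is.null(fast) && nrow(fast)) {
    pre <- match(fast$pre, ids)
    ord <- order(pre)
    out$fast_ptr <- csr(pre, ord)
    out$fast_post <- match(fast$post, ids)[ord] - 1L
    out$fast_cls <- unname(cls_code[fast$receptor[ord]])
    out$fast_g <- fast$g[ord]
  } else {
    out$fast_ptr <- rep(0L, n + 1L)
    out$fast_post <- integer(0)
    out$fast_cls <- integer(0)
    out$fast_g <- numeric(0)
  }
  if (!is.null(nmda) && nrow(nmda)) {
    pre <- match(nmda$pre, ids)
    ord <- order(pre)
    out$nmda_ptr <- csr(pre, ord)
    out$nmda_post <- match(nmda$post, ids)[ord] - 1L
    out$nmda_g <- nmda$g[ord]
  } else {
    out$nmda_ptr <- rep(0L, n + 1L)
    out$nmda_post <- integer(0)
    out$nmda_g <- numeric(0)
  }
  out
}

#' Binned population firing rate
#'
#' `rate(t) = spike count in bin / (n_neurons * bin)`, in Hz.
#'
#' @param spikes data.frame with a `time` column (ms).
#' @param n_neurons population size.
#' @param bin bin width, ms.
#' @param duration total simulated time, ms.
#' @return data.frame: `time` (bin midpoints, ms), `rate` (Hz).
#' @export
population_rate <- function(spikes, n_neurons, bin = 100, duration) {
  stopifnot(bin > 0, n_neurons > 0)
  if (duration <= 0)
    return(data.frame(time = numeric(0), rate = numeric(0)))
  breaks <- seq(0, duration + bin, by = bin)
  counts <- tabulate(findInterval(spikes$time, breaks,
                                  left.open = TRUE, rightmost.closed = TRUE),
                     nbins = length(breaks) - 1L)
  keep <- breaks[-length(breaks)] < duration
  data.frame(time = (breaks[-length(breaks)] + bin / 2)[keep],
             rate = (counts / (n_neurons * bin / 1000))[keep])
}

#' Reference per-synapse integration of fast-receptor gating
#'
#' Integrates one gating variable `s_ij` per synapse (unit jump per
#' presynaptic spike, exponential decay) and returns the
#' conductance-weighted sum `S_i(t) = sum_j g_ij s_ij(t)` — the
#' aggregate the reduced formulation evolves directly. Used as the
#' independent oracle for the linear-reduction identity.
#'
#' @param spike_steps list (one element per synapse) of integer step
#'   indices at which the presynaptic neuron spikes (spike delivered at
#'   the end of that step).
#' @param g per-synapse conductance weights, nS.
#' @param tau decay constant, ms.
#' @param dt step, ms.
#' @param n_steps number of steps.
#' @return Numeric vector of `S` sampled after each step.
#' @export
gating_per_synapse_trace <- function(spike_steps, g, tau, dt, n_steps) {
  stopifnot(length(spike_steps) == length(g))
  e <- exp(-dt / tau)
  s <- numeric(length(g))
  out <- numeric(n_steps)
  for (step in seq_len(n_steps)) {
    s <- s * e
    sp <- vapply(spike_steps, function(x) step %in% x, logical(1))
    s[sp] <- s[sp] + 1
    out[step] <- sum(g * s)
  }
  out
}

#' Reduced (linear-pooled) fast-receptor gating
#'
#' Evolves the single conductance-weighted variable
#' `dS/dt = -S/tau + sum_jk g_j delta(t - t_jk)` directly: exponential
#' decay each step plus an increment `g_j` per presynaptic spike. For
#' single-exponential receptors this is algebraically identical to
#' summing per-synapse gating variables.
#'
#' @inheritParams gating_per_synapse_trace
#' @return Numeric vector of `S` sampled after each step.
#' @export
gating_reduced_trace <- function(spike_steps, g, tau, dt, n_steps) {
  e <- exp(-dt / tau)
  S <- 0
  out <- numeric(n_steps)
  for (step in seq_len(n_steps)) {
    S <- S * e
    for (j in seq_along(spike_steps))
      if (step %in% spike_steps[[j]]) S <- S + g[j]
    out[step] <- S
  }
  out
}
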