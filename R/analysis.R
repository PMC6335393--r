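#' Excitation-inhibition index per neuron
#'
#' `(N_E - N_I) / (N_E + N_I)`, where `N_E` counts excitatory input
#' (from Cha and VGlut presynaptic partners) and `N_I` inhibitory input
#' (from Gad partners); unweighted counts distinct presynaptic
#' neurons, weighted sums their contact-point numbers. Neurons with no
#' typed input have an undefined index, reported as `NA` and excluded
#' from downstream distributions.
#'
#' @param model a `network_model`.
#' @param neuron_id ids to evaluate (default: all model neurons).
#' @param weighted logical.
#' @return data.frame: `neuron_id`, `n_e`, `n_i`, `index`, `weighted`.
#' @export
ei_index <- function(model, neuron_id = NULL, weighted = FALSE) {
  if (is.null(neuron_id)) neuron_id <- model$neurons$id
  stopifnot(all(neuron_id %in% model$neurons$id))
  tx <- setNames(model$neurons$transmitter, model$neurons$id)
  s <- model$synapses
  pre_tx <- tx[s$pre]
  w <- if (weighted) s$n else rep(1, nrow(s))
  post_f <- factor(s$post, levels = neuron_id)
  n_e <- tapply(w * (pre_tx %in% c("Cha", "VGlut")), post_f, sum)
  n_i <- tapply(w * (pre_tx == "Gad"), post_f, sum)
  n_e <- ifelse(is.na(n_e), 0, n_e)
  n_i <- ifelse(is.na(n_i), 0, n_i)
  idx <- ifelse(n_e + n_i > 0, (n_e - n_i) / (n_e + n_i), NA_real_)
  data.frame(neuron_id = neuron_id, n_e = as.numeric(n_e),
             n_i = as.numeric(n_i), index = as.numeric(idx),
             weighted = weighted, row.names = NULL)
}

#' Degree and contact statistics of a model
#'
#' @param model a `network_model`.
#' @return List with `per_neuron` (data.frame: `neuron_id`, `in_degree`,
#'   `out_degree`, `in_contacts`, `out_contacts`) and `density`
#'   (edges / (N * (N - 1))).
#' @export
degree_stats <- function(model) {
  ids <- model$neurons$id
  s <- model$synapses
  pre_f <- factor(s$pre, levels = ids)
  post_f <- factor(s$post, levels = ids)
  z <- function(x) as.numeric(ifelse(is.na(x), 0, x))
  per <- data.frame(
    neuron_id = ids,
    in_degree = as.integer(table(post_f)),
    out_degree = as.integer(table(pre_f)),
    in_contacts = z(tapply(s$n, post_f, sum)),
    out_contacts = z(tapply(s$n, pre_f, sum)))
  n <- length(ids)
  list(per_neuron = per,
       density = if (n > 1) nrow(s) / (n * (n - 1)) else 0)
}

#' Detect hyperactivity (seizure-like) episodes in a rate trace
#'
#' Hyperactivity is whole-population mean rate above `threshold`
#' (default 1 Hz). Reports the episodes as half-open time intervals,
#' the onset (start of the first episode) and the prevalence (total
#' episode duration divided by the trace duration, so prevalence plus
#' the below-threshold fraction is exactly 1).
#'
#' @param rate_trace data.frame (`time`, `rate`) as returned by
#'   [population_rate()]; bins assumed contiguous and equal-width.
#' @param threshold Hz (default 1.0).
#' @return A `hyperactivity_report`: list with `threshold`, `intervals`
#'   (data.frame `start`, `end`, ms), `onset` (ms or `NA`), `prevalence`.
#' @export
detect_hyperactivity <- function(rate_trace, threshold = 1.0) {
  stopifnot(all(c("time", "rate") %in% names(rate_trace)))
  n <- nrow(rate_trace)
  if (n == 0L)
    return(structure(list(threshold = threshold,
                          intervals = data.frame(start = numeric(0),
                                                 end = numeric(0)),
                          onset = NA_real_, prevalence = 0),
                     class = "hyperactivity_report"))
  bin <- if (n > 1) diff(rate_trace$time[1:2]) else
    2 * rate_trace$time[1]
  hot <- rate_trace$rate > threshold
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hi <- which(r$values)
  intervals <- data.frame(
    start = rate_trace$time[starts[hi]] - bin / 2,
    end = rate_trace$time[ends[hi]] + bin / 2)
  structure(list(threshold = threshold, intervals = intervals,
                 onset = if (nrow(intervals)) intervals$start[1] else NA_real_,
                 prevalence = sum(hot) / n),
            class = "hyperactivity_report")
}

#' Fano factor of per-trial spike counts
#'
#' Variance-to-mean ratio of spike counts across repeated observation
#' windows; 1 for Poisson firing. Neurons with zero total count have an
#' undefined Fano factor (`NA`); the exclusion count is reported.
#'
#' @param spikes data.frame (`neuron_id`, `time`).
#' @param trials data.frame (`start`, `end`) of at least two windows, ms.
#' @param neuron_ids neurons to evaluate (default: all appearing).
#' @return List with `per_neuron` (data.frame: `neuron_id`, `mean_count`,
#'   `fano`), `n_excluded` (silent neurons).
#' @export
fano_factor <- function(spikes, trials, neuron_ids = NULL) {
  stopifnot(nrow(trials) >= 2, all(trials$end > trials$start))
  if (is.null(neuron_ids)) neuron_ids <- sort(unique(spikes$neuron_id))
  counts <- vapply(seq_len(nrow(trials)), function(t) {
    sel <- spikes$time > trials$start[t] & spikes$time <= trials$end[t]
    as.integer(table(factor(spikes$neuron_id[sel], levels = neuron_ids)))
  }, integer(length(neuron_ids)))
  counts <- matrix(counts, nrow = length(neuron_ids))
  m <- rowMeans(counts)
  v <- apply(counts, 1, var)
  fano <- ifelse(m > 0, v / m, NA_real_)
  list(per_neuron = data.frame(neuron_id = neuron_ids, mean_count = m,
                               fano = fano),
       n_excluded = sum(m == 0))
}

#' Probability-density histogram of neuron sizes per class
#'
#' Density in each bin is the neuron count divided by the total count
#' and by the bin width, so `sum(density * binwidth) = 1` per class.
#'
#' @param lengths skeleton lengths, um (> 0).
#' @param class_labels one class label per neuron (e.g. projection vs
#'   local); a single class if omitted.
#' @param breaks bin breaks, or a bin count (log-spaced bins are used
#'   when a count is given).
#' @return Named list (per class) of data.frames: `mid`, `width`,
#'   `density`, `count`. Empty classes give empty data.frames.
#' @export
size_distribution <- function(lengths, class_labels = NULL, breaks = 20) {
  stopifnot(all(lengths > 0))
  if (is.null(class_labels)) class_labels <- rep("all", length(lengths))
  if (length(breaks) == 1L)
    breaks <- exp(seq(log(min(lengths)) - 1e-9, log(max(lengths)) + 1e-9,
                      length.out = breaks + 1L))
  lapply(split(lengths, class_labels), function(x) {
    if (!length(x))
      return(data.frame(mid = numeric(0), width = numeric(0),
                        density = numeric(0), count = integer(0)))
    cnt <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
                    nbins = length(breaks) - 1L)
    w <- diff(breaks)
    data.frame(mid = (head(breaks, -1) + tail(breaks, -1)) / 2, width = w,
               density = cnt / (sum(cnt) * w), count = cnt)
  })
}
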