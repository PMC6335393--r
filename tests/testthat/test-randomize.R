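test_that("rewiring conserves exactly what it must conserve", {
  cn <- synth_connectome(600, seed = 31)
  m <- suppressWarnings(assemble_model(cn$neurons, cn$contacts))
  expect_gt(nrow(m$synapses), 10000)
  r <- rewire_network(m, seed = 5)
  expect_equal(nrow(r$synapses), nrow(m$synapses))
  # conductance (contact-count) multiset preserved exactly
  expect_equal(sort(r$synapses$n), sort(m$synapses$n))
  # per-presynaptic out-degree vector identical
  expect_equal(table(factor(r$synapses$pre, levels = m$neurons$id)),
               table(factor(m$synapses$pre, levels = m$neurons$id)))
  # per-presynaptic conductance multisets preserved too
  pre_set <- function(s) lapply(split(s$n, s$pre), sort)
  expect_equal(pre_set(r$synapses), pre_set(m$synapses))
  # no self loops, no duplicate directed pairs under resample policy
  expect_true(all(r$synapses$pre != r$synapses$post))
  expect_equal(anyDuplicated(paste(r$synapses$pre, r$synapses$post)), 0L)
  # posts actually moved
  expect_gt(mean(r$synapses$post != m$synapses$post), 0.9)
})

test_that("rewired in-degrees concentrate like a binomial draw", {
  cn <- synth_connectome(600, seed = 31)
  m <- suppressWarnings(assemble_model(cn$neurons, cn$contacts))
  r <- rewire_network(m, seed = 7)
  ind <- table(factor(r$synapses$post, levels = r$neurons$id))
  lambda <- nrow(r$synapses) / nrow(r$neurons)
  expect_lt(abs(mean(ind) - lambda) / lambda, 0.01)
  # variance/mean ~ 1 for a uniform random assignment (Poisson limit);
  # the original assortative network is far more dispersed
  expect_lt(var(ind) / mean(ind), 1.5)
  ind0 <- table(factor(m$synapses$post, levels = m$neurons$id))
  expect_gt(var(ind0) / mean(ind0), 3)
})

test_that("rewiring policies and eligibility behave as configured", {
  neurons <- data.frame(id = sprintf("Cha-F-%02d", 1:6),
                        name = sprintf("Cha-F-%02d", 1:6),
                        transmitter = "Cha", length = 1000)
  syn <- data.frame(pre = rep("Cha-F-01", 3),
                    post = c("Cha-F-02", "Cha-F-03", "Cha-F-04"),
                    n = c(5, 7, 11))
  m <- toy_model(neurons, syn)
  # merge_sum may collapse duplicates but conserves total contacts
  rm <- rewire_network(m, seed = 2, duplicate_policy = "merge_sum")
  expect_equal(sum(rm$synapses$n), 23)
  # extra targets (previously isolated neurons) become eligible
  extra <- data.frame(id = "Gad-F-99", name = "Gad-F-99", length = 500)
  hits <- vapply(1:200, function(s) {
    rr <- rewire_network(m, seed = s, extra_targets = extra)
    any(rr$synapses$post == "Gad-F-99")
  }, logical(1))
  expect_gt(mean(hits), 0.1)  # 3 draws from 6 targets; ~ 42% expected
  rr <- rewire_network(m, seed = 3, extra_targets = extra)
  expect_equal(nrow(rr$neurons), 7L)
})

test_that("the random reference network matches its binomial expectation", {
  m0 <- make_random_reference(c(Cha = 50, VGlut = 50, Gad = 50),
                              connectivity = 0, seed = 1)
  expect_equal(nrow(m0$synapses), 0L)
  m <- make_random_reference(c(Cha = 300, VGlut = 300, Gad = 400),
                             connectivity = 0.003, seed = 2)
  n <- 1000
  mean_total_degree <- 2 * nrow(m$synapses) / n
  expect_lt(abs(mean_total_degree - 2 * 0.003 * (n - 1)) /
              (2 * 0.003 * (n - 1)), 0.1)
  expect_true(all(m$synapses$pre != m$synapses$post))
})

test_that("synthetic skeletons are deterministic with planted polarity", {
  a <- synth_skeletons(3, seed = 77)
  b <- synth_skeletons(3, seed = 77)
  expect_identical(lapply(a, `[[`, "nodes"), lapply(b, `[[`, "nodes"))
  # planted axons have longer mean path to soma than dendrites
  for (sk in a) {
    truth <- attr(sk, "truth_nodes")
    d <- flybrainsim:::path_dist_to_soma(sk)
    names(d) <- sk$nodes$id
    expect_gt(mean(d[names(truth)[truth == "axon"]]),
              mean(d[names(truth)[truth == "dendrite"]]))
  }
})

test_that("synthetic connectomes are self-consistent and heavy-tailed", {
  cn <- synth_connectome(400, seed = 5)
  cn2 <- synth_connectome(400, seed = 5)
  expect_identical(cn$contacts, cn2$contacts)
  # ground-truth adjacency reproduces infer_connections at the criteria
  redo <- suppressWarnings(infer_connections(cn$contacts,
                                             connection_criteria(13, 0.01),
                                             neuron_ids = cn$neurons$id))
  expect_equal(cn$adjacency, redo)
  # Hill estimator over the top order statistics recovers a planted
  # pure-Pareto contact law within +-0.3
  big <- synth_connectome(1200, seed = 9, pareto_frac = 1,
                          pareto_alpha = 1.5)
  x <- sort(big$contacts$n, decreasing = TRUE)
  k <- floor(0.1 * length(x))
  hill <- 1 / mean(log(x[1:k] / x[k + 1]))
  expect_lt(abs(hill - 1.5), 0.3)
  # transmitter shares follow the configured fractions
  sh <- table(cn$neurons$transmitter) / 400
  expect_lt(abs(sh[["Gad"]] - 0.39), 0.08)
})

test_that("subsampling a random network does not widen the E-I spread", {
  sds <- vapply(1:20, function(s) {
    m <- make_random_reference(c(Cha = 250, VGlut = 400, Gad = 550),
                               connectivity = 0.01, seed = s)
    idx <- ei_index(m)$index
    sub <- subsample_neurons(m, fraction = 0.15, seed = s + 100)
    idx_sub <- ei_index(m, neuron_id = sub)$index
    c(full = sd(idx, na.rm = TRUE), sub = sd(idx_sub, na.rm = TRUE))
  }, numeric(2))
  # mean over seeds: the subsampled spread stays within Monte-Carlo
  # tolerance of the full network's spread
  expect_lt(mean(sds["sub", ]), mean(sds["full", ]) * 1.1)
})
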